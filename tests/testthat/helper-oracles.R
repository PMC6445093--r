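# Independent brute-force oracles. Everything here is deliberately naive
# (loops, Floyd-Warshall, union-find, enumeration) and never calls the
# package code paths it is used to check.

# ---- differential rules ------------------------------------------------

# Paired-t p-value by the textbook formula with the degenerate conventions
# (constant nonzero difference -> smallest representable p; all-zero -> 1).
bf_paired_p <- function(x, y) {
  d <- x - y
  if (length(d) < 2) return(NA_real_)
  if (sd(d) == 0) {
    if (mean(d) == 0) return(1)
    return(.Machine$double.xmin)
  }
  tt <- mean(d) / (sd(d) / sqrt(length(d)))
  2 * stats::pt(-abs(tt), length(d) - 1)
}

# Row-by-row re-evaluation of the within-cohort selection rules.
# Returns one data.frame per cohort with fc, p, usable, candidate.
bf_per_cohort <- function(peptides, fc_cutoff = 1.25, p_cutoff = 0.05,
                          score_cutoff = 6.0) {
  out <- list()
  for (cid in sort(unique(peptides$cohort_id))) {
    sub <- peptides[peptides$cohort_id == cid, ]
    rows <- list()
    for (sym in sort(unique(sub$protein_symbol))) {
      pp <- sub[sub$protein_symbol == sym, ]
      fc <- mean(pp$abundance_M) / mean(pp$abundance_nonM)
      if (nrow(pp) == 1) {
        usable <- pp$n_mapped_proteins == 1 &&
          pp$peptide_score >= score_cutoff
        p <- NA_real_
        cand <- usable && (fc > fc_cutoff || fc < 1 / fc_cutoff)
      } else {
        usable <- TRUE
        p <- bf_paired_p(log2(pp$abundance_M), log2(pp$abundance_nonM))
        cand <- (fc > fc_cutoff || fc < 1 / fc_cutoff) && p < p_cutoff
      }
      rows[[sym]] <- data.frame(
        cohort_id = cid, protein_symbol = sym, fc = fc, p = p,
        log2_m = log2(mean(pp$abundance_M)),
        log2_nonm = log2(mean(pp$abundance_nonM)),
        usable = usable, candidate = cand)
    }
    out[[cid]] <- do.call(rbind, rows)
  }
  out
}

# Cross-cohort concordance rule on the bf_per_cohort output (raw log2
# values, no normalization).
bf_concordant <- function(bf_cohorts, fc_cutoff = 1.25, min_cohorts = 3,
                          combined_p_cutoff = 0.1) {
  usable <- lapply(bf_cohorts, function(d) d[d$usable, ])
  syms <- sort(unique(unlist(lapply(usable, `[[`, "protein_symbol"))))
  up <- character(); down <- character()
  n_conc <- stats::setNames(integer(), character())
  for (sym in syms) {
    fcs <- sapply(usable, function(d) {
      i <- match(sym, d$protein_symbol)
      if (is.na(i)) NA_real_ else d$fc[i]
    })
    diffs <- unlist(lapply(usable, function(d) {
      i <- match(sym, d$protein_symbol)
      if (is.na(i)) NULL else d$log2_m[i] - d$log2_nonm[i]
    }))
    n_up <- sum(fcs > fc_cutoff, na.rm = TRUE)
    n_down <- sum(fcs < 1 / fc_cutoff, na.rm = TRUE)
    if (length(diffs) < 2) next
    p <- bf_paired_p(diffs, rep(0, length(diffs)))
    tpos <- mean(diffs) > 0
    if (n_up >= min_cohorts && n_down == 0 && p < combined_p_cutoff &&
        tpos) {
      up <- c(up, sym); n_conc[sym] <- n_up
    } else if (n_down >= min_cohorts && n_up == 0 &&
               p < combined_p_cutoff && !tpos) {
      down <- c(down, sym); n_conc[sym] <- n_down
    }
  }
  list(up = up, down = down, n_concordant = n_conc)
}

# Random toy peptide table with a realistic mix of rule-relevant features.
make_toy_peptides <- function(n_proteins, seed) {
  set.seed(seed)
  syms <- sprintf("TP%04d", seq_len(n_proteins))
  k <- sample(1:4, n_proteins, replace = TRUE)
  rows <- list()
  for (cid in paste0("C", 1:4)) {
    # random per-(protein, cohort) true effect creates fc spread
    eff <- exp(stats::rnorm(n_proteins, 0, 0.5))
    keep <- stats::runif(n_proteins) > 0.05 # some proteins miss a cohort
    for (i in which(keep)) {
      base <- stats::rlnorm(k[i], log(1e4), 1)
      rows[[length(rows) + 1]] <- data.frame(
        peptide_id = sprintf("%s_p%d", syms[i], seq_len(k[i])),
        protein_symbol = syms[i],
        n_mapped_proteins = sample(c(1L, 1L, 1L, 2L), k[i],
                                   replace = TRUE),
        peptide_score = stats::runif(k[i], 3, 12),
        abundance_M = base * eff[i] *
          stats::rlnorm(k[i], 0, 0.2),
        abundance_nonM = base * stats::rlnorm(k[i], 0, 0.2),
        cohort_id = cid)
    }
  }
  tibble::as_tibble(do.call(rbind, rows))
}

# ---- graph oracles -----------------------------------------------------

bf_adjacency <- function(graph) {
  n <- length(graph$nodes)
  a <- matrix(0L, n, n, dimnames = list(graph$nodes, graph$nodes))
  for (i in seq_len(nrow(graph$edges))) {
    a[graph$edges$protein1[i], graph$edges$protein2[i]] <- 1L
    a[graph$edges$protein2[i], graph$edges$protein1[i]] <- 1L
  }
  a
}

bf_floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n, dimnames = dimnames(adj))
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

bf_local_clustering <- function(adj) {
  n <- nrow(adj)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) { out[i] <- 0; next }
    links <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        links <- links + adj[nb[a], nb[b]]
      }
    }
    out[i] <- links / (k * (k - 1) / 2)
  }
  out
}

bf_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find2 <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (adj[i, j] == 1) {
        ri <- find2(i); rj <- find2(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find2, integer(1))
  match(roots, unique(roots))
}

# Random scored graph on n nodes (some isolated) for oracle suites.
random_test_graph <- function(n, seed, p = 0.25) {
  set.seed(seed)
  syms <- sprintf("N%02d", seq_len(n))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p
  edges <- data.frame(
    protein1 = syms[pairs[keep, 1]],
    protein2 = syms[pairs[keep, 2]],
    confidence = sample(1:1000, sum(keep), replace = TRUE))
  interaction_graph(edges, nodes = syms)
}

# ---- survival oracles --------------------------------------------------

# Hand-computed product-limit values for the 6-patient toy used in tests:
# times 1, 2+, 3, 4, 5+, 6 (+ = censored).
km_toy <- list(
  time = c(1, 2, 3, 4, 5, 6),
  event = c(1, 0, 1, 1, 0, 1),
  event_times = c(1, 3, 4, 6),
  survival = c(5 / 6, 5 / 8, 5 / 12, 0)
)

# Cox partial log-likelihood (no ties) and grid-search maximizer.
bf_cox_grid <- function(time, event, x, grid = seq(-3, 3, by = 1e-4)) {
  loglik <- function(beta) {
    s <- 0
    for (i in which(event == 1)) {
      risk <- which(time >= time[i])
      s <- s + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    s
  }
  ll <- vapply(grid, loglik, numeric(1))
  grid[which.max(ll)]
}
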