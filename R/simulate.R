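#' Simulation settings for the synthetic study
#'
#' Bundles every tunable of the synthetic-data generators: the pooled-plasma
#' cohort tables, the mouse longitudinal series, the cell-line spectral-count
#' panel, the secretome ratio tables, the scored interaction graph, and the
#' survival cohort. Defaults reproduce the study scale the package is designed
#' around: 1618 quantified plasma proteins, four matched cohorts (pre/post
#' menopause crossed with stage II/III), a planted metastasis fold change of
#' 1.6 against a 1.25 selection cutoff, and a 210-patient evaluation cohort
#' with a planted hazard ratio of 1.8 for the high-risk group.
#'
#' Measurement noise is multiplicative lognormal on peptide abundances
#' (positive-only intensities; log fold changes are then normal and unbiased).
#' Planted progression effects are always carried by multi-peptide proteins:
#' with zero noise the downstream selection rules then recover the planted
#' truth exactly, while single-peptide, low-score and multi-mapped peptide
#' realism is carried by the null proteins.
#'
#' @param n_proteins Number of quantified plasma proteins.
#' @param n_cohorts Number of matched cohorts (menopause x stage design).
#' @param n_up,n_down Number of planted up-/down-regulated (M vs non-M)
#'   proteins.
#' @param effect_fc Planted linear fold change (M/non-M); must be > 1.
#' @param n_effect_cohorts Number of cohorts (out of `n_cohorts`) in which a
#'   planted protein carries its effect; at least 3 so planted proteins meet
#'   the concordance rule by construction.
#' @param noise_cv Coefficient of variation of the lognormal peptide
#'   measurement noise in the human cohorts.
#' @param peptides_per_protein Mean peptide count of multi-peptide proteins
#'   (must be >= 2; counts are `2 + Poisson(mean - 2)`).
#' @param fraction_single_peptide Fraction of null proteins quantified by a
#'   single peptide.
#' @param fraction_low_score Fraction of peptides drawn with an
#'   identification score below 6.0 (the single-peptide retention cutoff).
#' @param fraction_multi_mapped Fraction of peptides flagged as mapping to
#'   more than one protein.
#' @param ionization_sdlog Spread (sdlog) of per-peptide ionization
#'   efficiency around its protein's base abundance.
#' @param base_abundance_sdlog Spread (sdlog) of protein base abundances.
#' @param mouse_effect_fc Planted prediagnostic-2/baseline ratio (F20) of
#'   mouse fast-progressor proteins; must exceed the 1.3 selection cutoff.
#' @param mouse_noise_cv Lognormal noise CV of the mouse pooled measurements.
#' @param n_mouse_fast Number of proteins planted with a fast-group F20
#'   effect.
#' @param n_common_up,n_common_down How many of the planted human up/down
#'   proteins are also planted in the mouse fast set (the human-mouse common
#'   set has `n_common_up + n_common_down` members).
#' @param n_signature Number of concordantly-up, cell-line-detected signature
#'   genes (a subset of the `n_common_up` proteins).
#' @param n_undetected_up Number of the common up proteins left undetected in
#'   the cell-line panel (they drop out of the tumor-intrinsic set).
#' @param n_patients Survival-cohort size.
#' @param true_hr Planted hazard ratio of the high-risk group (top quartile
#'   of the mean signature-gene score); must be > 0.
#' @param censor_rate Target fraction of censored patients (independent
#'   exponential censoring); 0 means every patient has an event.
#' @param baseline_hazard Baseline exponential event rate (per year).
#' @param n_extra_genes Number of non-signature genes in the expression
#'   table (plus a `TGFB1` column correlated with the signature score).
#' @param seed Integer master seed; every generator draws from a
#'   deterministically derived child seed.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_proteins = 1618L,
                       n_cohorts = 4L,
                       n_up = 40L,
                       n_down = 40L,
                       effect_fc = 1.6,
                       n_effect_cohorts = 4L,
                       noise_cv = 0.2,
                       peptides_per_protein = 4.5,
                       fraction_single_peptide = 0.10,
                       fraction_low_score = 0.25,
                       fraction_multi_mapped = 0.03,
                       ionization_sdlog = 0.3,
                       base_abundance_sdlog = 1.2,
                       mouse_effect_fc = 1.6,
                       mouse_noise_cv = 0.1,
                       n_mouse_fast = 40L,
                       n_common_up = 6L,
                       n_common_down = 7L,
                       n_signature = 3L,
                       n_undetected_up = 3L,
                       n_patients = 210L,
                       true_hr = 1.8,
                       censor_rate = 0.3,
                       baseline_hazard = 0.08,
                       n_extra_genes = 20L,
                       seed = 1L) {
  n_proteins <- assert_count(n_proteins, "n_proteins", 10L)
  n_cohorts <- assert_count(n_cohorts, "n_cohorts", 2L)
  n_up <- assert_count(n_up, "n_up", 0L)
  n_down <- assert_count(n_down, "n_down", 0L)
  if (!is.numeric(effect_fc) || effect_fc <= 1) {
    abort("`effect_fc` must be > 1 (planted M/non-M fold change)")
  }
  n_effect_cohorts <- assert_count(n_effect_cohorts, "n_effect_cohorts", 1L)
  if (n_effect_cohorts > n_cohorts) {
    abort("`n_effect_cohorts` cannot exceed `n_cohorts`")
  }
  assert_pos(noise_cv, "noise_cv", strict = FALSE)
  if (peptides_per_protein < 2) {
    abort("`peptides_per_protein` must be >= 2 (mean of multi-peptide counts)")
  }
  assert_prob(fraction_single_peptide, "fraction_single_peptide")
  assert_prob(fraction_low_score, "fraction_low_score")
  assert_prob(fraction_multi_mapped, "fraction_multi_mapped")
  assert_pos(ionization_sdlog, "ionization_sdlog", strict = FALSE)
  assert_pos(base_abundance_sdlog, "base_abundance_sdlog", strict = FALSE)
  if (!is.numeric(mouse_effect_fc) || mouse_effect_fc <= 1) {
    abort("`mouse_effect_fc` must be > 1")
  }
  assert_pos(mouse_noise_cv, "mouse_noise_cv", strict = FALSE)
  n_mouse_fast <- assert_count(n_mouse_fast, "n_mouse_fast", 1L)
  n_common_up <- assert_count(n_common_up, "n_common_up", 0L)
  n_common_down <- assert_count(n_common_down, "n_common_down", 0L)
  n_signature <- assert_count(n_signature, "n_signature", 1L)
  n_undetected_up <- assert_count(n_undetected_up, "n_undetected_up", 0L)
  if (n_up + n_down > n_proteins) {
    abort("planted up/down sets do not fit within `n_proteins`")
  }
  if (n_common_up > n_up || n_common_down > n_down) {
    abort("human-mouse common counts cannot exceed the planted human sets")
  }
  if (n_signature + n_undetected_up > n_common_up) {
    abort("`n_signature` + `n_undetected_up` cannot exceed `n_common_up`")
  }
  if (n_common_up + n_common_down > n_mouse_fast) {
    abort("`n_mouse_fast` must cover the human-mouse common set")
  }
  n_patients <- assert_count(n_patients, "n_patients", 4L)
  if (!is.numeric(true_hr) || true_hr <= 0) abort("`true_hr` must be > 0")
  assert_prob(censor_rate, "censor_rate")
  assert_pos(baseline_hazard, "baseline_hazard")
  n_extra_genes <- assert_count(n_extra_genes, "n_extra_genes", 0L)
  seed <- assert_count(abs(seed), "seed", 0L)

  structure(
    list(
      n_proteins = n_proteins, n_cohorts = n_cohorts,
      n_up = n_up, n_down = n_down,
      effect_fc = effect_fc, n_effect_cohorts = n_effect_cohorts,
      noise_cv = noise_cv,
      peptides_per_protein = peptides_per_protein,
      fraction_single_peptide = fraction_single_peptide,
      fraction_low_score = fraction_low_score,
      fraction_multi_mapped = fraction_multi_mapped,
      ionization_sdlog = ionization_sdlog,
      base_abundance_sdlog = base_abundance_sdlog,
      mouse_effect_fc = mouse_effect_fc, mouse_noise_cv = mouse_noise_cv,
      n_mouse_fast = n_mouse_fast,
      n_common_up = n_common_up, n_common_down = n_common_down,
      n_signature = n_signature, n_undetected_up = n_undetected_up,
      n_patients = n_patients, true_hr = true_hr,
      censor_rate = censor_rate, baseline_hazard = baseline_hazard,
      n_extra_genes = n_extra_genes, seed = seed
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d proteins, %d cohorts; planted %d up + %d down at FC %.3g (CV %.3g)\n",
              x$n_proteins, x$n_cohorts, x$n_up, x$n_down, x$effect_fc,
              x$noise_cv))
  cat(sprintf("  mouse: %d fast proteins at F20 %.3g (CV %.3g)\n",
              x$n_mouse_fast, x$mouse_effect_fc, x$mouse_noise_cv))
  cat(sprintf("  survival: n = %d, true HR %.3g, censor rate %.3g\n",
              x$n_patients, x$true_hr, x$censor_rate))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

protein_symbols <- function(n) sprintf("PROT%04d", seq_len(n))

#' Planted ground truth of a synthetic study
#'
#' Draws the disjoint planted protein sets that thread through all generators:
#' human up/down/null sets, the mouse fast-progressor set (overlapping the
#' human sets in `n_common_up + n_common_down` symbols), the cell-line
#' undetected set, secretome up/down sets, and the final signature genes
#' (concordantly up in human and mouse and detected in the cell-line panel).
#'
#' @param config A [sim_config()].
#' @return An object of class `ground_truth`: a list with character-vector
#'   fields `up_proteins`, `down_proteins`, `null_proteins`,
#'   `mouse_fast_proteins`, `panel_undetected`, `secretome_up`,
#'   `secretome_down`, `signature_genes`, `all_proteins` and the `seed`.
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "truth"))
  syms <- protein_symbols(config$n_proteins)

  planted <- sample(syms, config$n_up + config$n_down)
  up <- sort(planted[seq_len(config$n_up)])
  down <- sort(planted[config$n_up + seq_len(config$n_down)])
  null <- setdiff(syms, planted)

  signature <- sort(sample(up, config$n_signature))
  undetected_up <- sort(sample(setdiff(up, signature), config$n_undetected_up))
  common_up <- sort(c(
    signature, undetected_up,
    sample(setdiff(up, c(signature, undetected_up)),
           config$n_common_up - config$n_signature - config$n_undetected_up)
  ))
  common_down <- sort(sample(down, config$n_common_down))
  n_fast_extra <- config$n_mouse_fast - length(common_up) - length(common_down)
  fast_extra <- sample(null, n_fast_extra)
  mouse_fast <- sort(c(common_up, common_down, fast_extra))

  # One common-down protein is also undetected, so the tumor-intrinsic set
  # is |common| - (n_undetected_up + 1).
  panel_undetected <- sort(c(undetected_up,
                             if (length(common_down)) common_down[1]))

  secretome_up <- sort(unique(c(signature,
                                sample(syms, min(60L, config$n_proteins)))))
  secretome_down <- sort(sample(setdiff(syms, secretome_up),
                                min(40L, length(setdiff(syms, secretome_up)))))

  structure(
    list(
      up_proteins = up, down_proteins = down, null_proteins = sort(null),
      mouse_fast_proteins = mouse_fast,
      common_up = common_up, common_down = common_down,
      panel_undetected = panel_undetected,
      secretome_up = secretome_up, secretome_down = secretome_down,
      signature_genes = signature,
      all_proteins = syms,
      seed = config$seed
    ),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>\n")
  cat(sprintf("  %d proteins: %d up, %d down, %d null\n",
              length(x$all_proteins), length(x$up_proteins),
              length(x$down_proteins), length(x$null_proteins)))
  cat(sprintf("  mouse fast: %d (%d common with human)\n",
              length(x$mouse_fast_proteins),
              length(x$common_up) + length(x$common_down)))
  cat(sprintf("  signature: %s\n", paste(x$signature_genes, collapse = ", ")))
  invisible(x)
}

#' Query the planted status of protein symbols
#'
#' @param truth A [ground_truth()].
#' @param symbols Character vector of protein symbols.
#' @return A tibble with one row per symbol: its planted human direction
#'   (`up`, `down`, `null`, or `absent`), and logical flags for the mouse
#'   fast set, cell-line detection and signature membership.
#' @export
truth_labels <- function(truth, symbols = truth$all_proteins) {
  stopifnot(inherits(truth, "ground_truth"))
  tibble(
    protein_symbol = symbols,
    human_direction = dplyr::case_when(
      symbols %in% truth$up_proteins ~ "up",
      symbols %in% truth$down_proteins ~ "down",
      symbols %in% truth$null_proteins ~ "null",
      TRUE ~ "absent"
    ),
    mouse_fast = symbols %in% truth$mouse_fast_proteins,
    panel_detected = !(symbols %in% truth$panel_undetected),
    signature = symbols %in% truth$signature_genes
  )
}

cohort_design <- function(n_cohorts) {
  base <- tibble(
    cohort_id = paste0("C", seq_len(n_cohorts)),
    menopause = rep(c("pre", "post"), length.out = n_cohorts),
    stage = rep(c("II", "II", "III", "III"), length.out = n_cohorts)
  )
  base
}

#' Simulate peptide-level pooled-plasma cohort tables
#'
#' Generates peptide-level M vs non-M abundances for each matched cohort.
#' Each protein has a lognormal base abundance; each peptide a lognormal
#' ionization efficiency; observed abundances are the true pooled values
#' under the planted effect times multiplicative lognormal noise. Planted
#' proteins carry fold change `effect_fc` (up) or `1/effect_fc` (down) in
#' `n_effect_cohorts` cohorts and 1 elsewhere. Null proteins may be
#' single-peptide, carry low identification scores, or map to multiple
#' proteins, exercising the peptide retention rules downstream.
#'
#' @param config A [sim_config()].
#' @param truth Optional [ground_truth()]; generated from `config` if absent.
#' @return A list with `peptides` (tibble: `peptide_id`, `protein_symbol`,
#'   `n_mapped_proteins`, `peptide_score`, `abundance_M`, `abundance_nonM`,
#'   `cohort_id`), `design` (cohort metadata) and `truth`.
#' @export
simulate_plasma_cohorts <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  truth <- truth %||% ground_truth(config)
  set.seed(child_seed(config$seed, "plasma"))

  syms <- truth$all_proteins
  n <- length(syms)
  planted <- syms %in% c(truth$up_proteins, truth$down_proteins)

  # Peptide counts: planted proteins are always multi-peptide (see vignette);
  # a fraction of null proteins is single-peptide.
  single <- !planted & runif(n) < config$fraction_single_peptide
  k <- ifelse(single, 1L,
              2L + rpois(n, config$peptides_per_protein - 2))

  base_abund <- rlnorm(n, meanlog = log(1e5),
                       sdlog = config$base_abundance_sdlog)

  pep <- tibble(
    protein_symbol = rep(syms, k),
    peptide_index = sequence(k),
    base = rep(base_abund, k) *
      rlnorm(sum(k), 0, config$ionization_sdlog)
  ) |>
    mutate(
      peptide_id = sprintf("%s_pep%02d", .data$protein_symbol,
                           .data$peptide_index),
      n_mapped_proteins = ifelse(
        runif(dplyr::n()) < config$fraction_multi_mapped,
        sample(2:4, dplyr::n(), replace = TRUE), 1L),
      peptide_score = ifelse(
        runif(dplyr::n()) < config$fraction_low_score,
        runif(dplyr::n(), 2, 5.99), runif(dplyr::n(), 6.01, 12))
    )

  # Which cohorts carry each planted protein's effect.
  design <- cohort_design(config$n_cohorts)
  effect_cohorts <- matrix(FALSE, n, config$n_cohorts,
                           dimnames = list(syms, design$cohort_id))
  for (i in which(planted)) {
    effect_cohorts[i, sample.int(config$n_cohorts,
                                 config$n_effect_cohorts)] <- TRUE
  }

  log_effect <- ifelse(syms %in% truth$up_proteins, log(config$effect_fc),
                       ifelse(syms %in% truth$down_proteins,
                              -log(config$effect_fc), 0))
  names(log_effect) <- syms

  per_cohort <- function(cid) {
    eff <- ifelse(effect_cohorts[pep$protein_symbol, cid],
                  exp(log_effect[pep$protein_symbol]), 1)
    m <- pep$base * eff * lnoise(nrow(pep), config$noise_cv)
    nm <- pep$base * lnoise(nrow(pep), config$noise_cv)
    tibble(
      peptide_id = pep$peptide_id,
      protein_symbol = pep$protein_symbol,
      n_mapped_proteins = pep$n_mapped_proteins,
      peptide_score = pep$peptide_score,
      abundance_M = m,
      abundance_nonM = nm,
      cohort_id = cid
    )
  }
  peptides <- map_dfr(design$cohort_id, per_cohort)

  list(peptides = peptides, design = design, truth = truth)
}

#' Simulate the mouse longitudinal pooled-plasma series
#'
#' Produces per-protein pooled abundances at baseline, prediagnostic 1 and
#' prediagnostic 2 for the fast- and slow-progressor groups. Proteins in the
#' planted mouse fast set ramp to `planted_ratio` times baseline by
#' prediagnostic 2 in the fast group (halfway on the log scale at
#' prediagnostic 1); all other trajectories are flat. Each pooled
#' measurement gets independent lognormal noise with CV `config$mouse_noise_cv`.
#'
#' @param config A [sim_config()].
#' @param truth Optional [ground_truth()].
#' @param planted_ratio A single ratio, or a named vector over the planted
#'   fast proteins; defaults to `config$mouse_effect_fc`.
#' @return A list with `series` (tibble: `protein_symbol`, `group`,
#'   `baseline`, `p1`, `p2`) and `truth`.
#' @export
simulate_mouse_series <- function(config, truth = NULL,
                                  planted_ratio = config$mouse_effect_fc) {
  stopifnot(inherits(config, "sim_config"))
  truth <- truth %||% ground_truth(config)
  set.seed(child_seed(config$seed, "mouse"))

  syms <- truth$all_proteins
  n <- length(syms)
  ratio <- setNames(rep(1, n), syms)
  if (is.null(names(planted_ratio))) {
    ratio[truth$mouse_fast_proteins] <- planted_ratio
  } else {
    ratio[names(planted_ratio)] <- planted_ratio
  }
  if (any(ratio <= 0)) abort("planted mouse ratios must be positive")

  base <- rlnorm(n, log(1e5), config$base_abundance_sdlog)
  cv <- config$mouse_noise_cv

  series <- map_dfr(c("fast", "slow"), function(grp) {
    r2 <- if (grp == "fast") unname(ratio[syms]) else rep(1, n)
    r1 <- sqrt(r2) # halfway on the log scale
    tibble(
      protein_symbol = syms,
      group = grp,
      baseline = base * lnoise(n, cv),
      p1 = base * r1 * lnoise(n, cv),
      p2 = base * r2 * lnoise(n, cv)
    )
  })
  list(series = series, truth = truth)
}

#' Simulate a scored protein interaction graph
#'
#' Random undirected graphs with STRING-style integer confidence scores in
#' 1..1000. The `scale_free` model is preferential attachment (power-law-ish
#' degree sequence, matching the observed character of curated interactomes);
#' `gnp` is an Erdos-Renyi graph and `complete` the complete graph.
#'
#' @param n_nodes Number of nodes (>= 2).
#' @param model One of `"scale_free"`, `"gnp"`, `"complete"`.
#' @param symbols Optional node labels (defaults to `PROTxxxx` symbols).
#'   For the `scale_free` model, earlier symbols preferentially become hubs.
#' @param power Preferential-attachment power (scale-free model).
#' @param m Edges added per node (scale-free model).
#' @param p_edge Edge probability (gnp model).
#' @param seed Integer seed.
#' @return An [interaction_graph()] with `provenance = "database"` edges.
#' @export
simulate_interaction_graph <- function(n_nodes,
                                       model = c("scale_free", "gnp",
                                                 "complete"),
                                       symbols = NULL, power = 1, m = 2,
                                       p_edge = 0.05, seed = 1L) {
  n_nodes <- assert_count(n_nodes, "n_nodes", 2L)
  model <- match.arg(model)
  symbols <- symbols %||% protein_symbols(n_nodes)
  if (length(symbols) != n_nodes) {
    abort("`symbols` must have length `n_nodes`")
  }
  set.seed(child_seed(seed, "graph"))
  g <- switch(model,
    scale_free = igraph::sample_pa(n_nodes, power = power, m = m,
                                   directed = FALSE),
    gnp = igraph::sample_gnp(n_nodes, p_edge),
    complete = igraph::make_full_graph(n_nodes)
  )
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- tibble(
    protein1 = symbols[el[, 1]],
    protein2 = symbols[el[, 2]],
    confidence = sample.int(1000L, nrow(el), replace = TRUE),
    provenance = "database"
  )
  interaction_graph(edges, nodes = symbols)
}

#' Simulate the cell-line spectral-count panel
#'
#' Seventeen breast-cancer cell lines with nonnegative integer spectral
#' counts per protein in total-extract and conditioned-media compartments.
#' Proteins in the truth's `panel_undetected` set get zero counts everywhere;
#' every other protein is detected (count >= 1) in at least one line.
#'
#' @param config A [sim_config()].
#' @param truth Optional [ground_truth()].
#' @return A list with `panel` (tibble: `line_id`, `compartment`,
#'   `protein_symbol`, `count`) and `truth`.
#' @export
simulate_cell_panel <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  truth <- truth %||% ground_truth(config)
  set.seed(child_seed(config$seed, "panel"))

  lines <- c(sprintf("TNBC%02d", 1:13),
             "HMLER2", "HMLER3", "BPLER2", "BPLER3")
  detected <- setdiff(truth$all_proteins, truth$panel_undetected)

  per_protein <- map_dfr(detected, function(sym) {
    n_lines <- sample.int(length(lines), 1)
    in_lines <- sample(lines, n_lines)
    tibble(
      line_id = in_lines,
      compartment = sample(c("total", "media"), n_lines, replace = TRUE),
      protein_symbol = sym,
      count = rpois(n_lines, 8) + 1L
    )
  })
  # undetected proteins appear with explicit zero counts in one line so the
  # panel records their absence rather than omitting them silently
  zeros <- tibble(
    line_id = lines[1], compartment = "total",
    protein_symbol = truth$panel_undetected, count = 0L
  )
  list(panel = bind_rows(per_protein, zeros), truth = truth)
}

#' Simulate secretome ratio tables for two metastatic/non-metastatic pairs
#'
#' Conditioned-media abundance ratios (metastatic BPLER over non-metastatic
#' HMLER) for two independent cell-line pairs on the shared protein
#' namespace. Planted secretome-up proteins center on ratio 2.2, planted
#' down proteins on 0.45, the rest on 1.
#'
#' @param config A [sim_config()].
#' @param truth Optional [ground_truth()].
#' @param noise_sdlog Lognormal spread of the ratios around their center.
#' @return A list with `pairs` (list of two tibbles `protein_symbol`,
#'   `ratio`) and `truth`.
#' @export
simulate_secretome_pairs <- function(config, truth = NULL,
                                     noise_sdlog = 0.12) {
  stopifnot(inherits(config, "sim_config"))
  truth <- truth %||% ground_truth(config)
  set.seed(child_seed(config$seed, "secretome"))

  syms <- truth$all_proteins
  center <- ifelse(syms %in% truth$secretome_up, 2.2,
                   ifelse(syms %in% truth$secretome_down, 0.45, 1))
  mk <- function() {
    tibble(protein_symbol = syms,
           ratio = center * rlnorm(length(syms), 0, noise_sdlog))
  }
  list(pairs = list(BPLER3_vs_HMLER3 = mk(), BPLER2_vs_HMLER2 = mk()),
       truth = truth)
}

# Shared high/low split rule: |high| = ceiling(frac * N); ties at the
# threshold score all fall in the high group.
high_split <- function(scores, high_fraction) {
  n_high <- ceiling(high_fraction * length(scores))
  threshold <- sort(scores, decreasing = TRUE)[n_high]
  list(threshold = threshold, high = scores >= threshold)
}

#' Simulate the survival evaluation cohort
#'
#' Per-patient gene expression, follow-up and clinical covariates generated
#' under proportional hazards: signature-gene expression is standard normal,
#' the risk score is the mean across signature genes, and patients in the
#' top quartile of the score (the same stratification rule used by
#' [stratify_risk()]) have their exponential event hazard multiplied by
#' `true_hr`. Censoring is independent exponential, tuned so roughly
#' `censor_rate` of patients are censored. A `TGFB1` column correlated with
#' the signature score and unrelated extra genes are included. Binary
#' covariates follow the usual clinical dichotomies: stage 2-4 vs 0-1,
#' post- vs pre-menopause, grade 3 vs 1-2, tumor size >= 31 mm.
#'
#' @param config A [sim_config()].
#' @param signature_genes Character vector of signature genes (non-empty).
#' @param truth Optional [ground_truth()].
#' @return A list with `cohort` (tibble: `patient_id`, one column per gene,
#'   `time` (years), `event`, `stage_high`, `post_menopause`, `grade_3`,
#'   `size_ge_31mm`), `high_risk` (logical planted group), and `truth`.
#' @export
simulate_survival_cohort <- function(config,
                                     signature_genes = NULL,
                                     truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  truth <- truth %||% ground_truth(config)
  signature_genes <- signature_genes %||% truth$signature_genes
  if (length(signature_genes) == 0) abort("`signature_genes` is empty")
  if (config$true_hr <= 0) abort("`true_hr` must be > 0")
  set.seed(child_seed(config$seed, "survival"))

  n <- config$n_patients
  expr <- matrix(rnorm(n * length(signature_genes)), nrow = n,
                 dimnames = list(NULL, signature_genes))
  score <- rowMeans(expr)
  split <- high_split(score, 0.25)
  high <- split$high

  rate <- config$baseline_hazard * ifelse(high, config$true_hr, 1)
  t_event <- rexp(n, rate)
  if (config$censor_rate > 0) {
    c_rate <- mean(rate) * config$censor_rate / (1 - config$censor_rate)
    t_cens <- rexp(n, c_rate)
  } else {
    t_cens <- rep(Inf, n)
  }
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  score_z <- as.numeric(scale(score))
  tgfb1 <- 0.6 * score_z + sqrt(1 - 0.36) * rnorm(n)
  extra <- matrix(rnorm(n * config$n_extra_genes), nrow = n,
                  dimnames = list(NULL, sprintf("GENE%02d",
                                                seq_len(config$n_extra_genes))))

  cohort <- bind_cols(
    tibble(patient_id = sprintf("PT%03d", seq_len(n))),
    as_tibble(expr), tibble(TGFB1 = tgfb1), as_tibble(extra),
    tibble(
      time = time, event = event,
      stage_high = rbinom(n, 1, 0.55),
      post_menopause = rbinom(n, 1, 0.5),
      grade_3 = rbinom(n, 1, 0.6),
      size_ge_31mm = rbinom(n, 1, 0.45)
    )
  )
  list(cohort = cohort, high_risk = high, truth = truth)
}

#' Simulate every input of the full study
#'
#' Convenience wrapper drawing one [ground_truth()] and running every
#' generator against it: plasma cohorts, mouse series, interaction graph
#' (with `TGFB1` and `TNF` placed as early, hub-prone nodes), cell-line
#' panel, secretome pairs, and the survival cohort.
#'
#' @param config A [sim_config()].
#' @return A list with elements `plasma`, `mouse`, `graph`, `panel`,
#'   `secretome`, `survival`, `truth`, `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  truth <- ground_truth(config)
  graph_symbols <- c("TGFB1", "TNF", truth$all_proteins)
  list(
    plasma = simulate_plasma_cohorts(config, truth),
    mouse = simulate_mouse_series(config, truth),
    graph = simulate_interaction_graph(length(graph_symbols),
                                       model = "scale_free",
                                       symbols = graph_symbols,
                                       seed = child_seed(config$seed,
                                                         "studygraph")),
    panel = simulate_cell_panel(config, truth),
    secretome = simulate_secretome_pairs(config, truth),
    survival = simulate_survival_cohort(config, truth = truth),
    truth = truth,
    config = config
  )
}
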