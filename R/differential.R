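#' Paired t-test with explicit degenerate handling
#'
#' Classical paired Student t-test: `t = mean(d) / (sd(d) / sqrt(n))` with
#' `d = x - y`, two-sided p from the t distribution on `n - 1` degrees of
#' freedom. Two degenerate cases that matter for pooled zero-noise data are
#' resolved deterministically instead of erroring: all differences exactly
#' zero gives `t = 0, p = 1`; a nonzero constant difference (zero variance)
#' is flagged `degenerate` and reported with the smallest representable
#' two-sided p so that a perfectly consistent shift always passes a p-value
#' screen.
#'
#' @param x,y Paired numeric vectors (length >= 2).
#' @return A one-row tibble: `t`, `df`, `p_value`, `degenerate`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 2) abort("need at least 2 pairs")
  if (anyNA(x) || anyNA(y)) abort("paired values must not be missing")
  d <- x - y
  n <- length(d)
  s <- sd(d)
  m <- mean(d)
  if (s == 0) {
    if (m == 0) {
      return(tibble(t = 0, df = n - 1, p_value = 1, degenerate = FALSE))
    }
    return(tibble(t = sign(m) * Inf, df = n - 1,
                  p_value = .Machine$double.xmin, degenerate = TRUE))
  }
  t <- m / (s / sqrt(n))
  tibble(t = t, df = n - 1, p_value = 2 * pt(-abs(t), n - 1),
         degenerate = FALSE)
}

# Vectorized version of the paired_t decision rule, for grouped summaries.
# Returns p-values following the same degenerate conventions.
paired_t_p <- function(d_mean, d_sd, n) {
  p <- ifelse(
    d_sd == 0,
    ifelse(d_mean == 0, 1, .Machine$double.xmin),
    2 * pt(-abs(d_mean / (d_sd / sqrt(n))), n - 1)
  )
  ifelse(n < 2, NA_real_, p)
}

#' Per-cohort differential protein candidates
#'
#' Applies the within-cohort selection rules to a peptide-level table.
#' Multi-peptide proteins are tested with a paired t-test across their
#' peptides (log2 M vs log2 non-M) and become candidates when `p <
#' p_cutoff` and the protein fold change passes `fc_cutoff` in either
#' direction (strict). Single-peptide proteins are retained on the fold
#' change criterion alone, but only when the peptide maps to a single
#' protein and its identification score is at least `score_cutoff`
#' (natural-log likelihood scale); otherwise they are ineligible
#' (`usable = FALSE`). The protein fold change is the ratio of peptide
#' abundance means (or medians).
#'
#' @param peptides Peptide tibble with columns `peptide_id`,
#'   `protein_symbol`, `n_mapped_proteins`, `peptide_score`, `abundance_M`,
#'   `abundance_nonM`, `cohort_id` (one or more cohorts).
#' @param fc_cutoff Linear fold-change cutoff (strict, both directions).
#' @param p_cutoff Per-cohort paired-test p cutoff for multi-peptide
#'   proteins.
#' @param score_cutoff Minimum peptide score for single-peptide proteins.
#' @param fc_summary `"mean"` (default) or `"median"` peptide summary.
#' @param quiet Suppress the ineligible-protein message.
#' @return A tibble with one row per (cohort, protein): fold change, log2
#'   group means, t statistic and p (multi-peptide only), eligibility
#'   (`usable` and `reason`), the `candidate` flag and its `direction`.
#' @export
per_cohort_candidates <- function(peptides, fc_cutoff = 1.25,
                                  p_cutoff = 0.05, score_cutoff = 6.0,
                                  fc_summary = c("mean", "median"),
                                  quiet = FALSE) {
  fc_summary <- match.arg(fc_summary)
  assert_cols(peptides,
              c("peptide_id", "protein_symbol", "n_mapped_proteins",
                "peptide_score", "abundance_M", "abundance_nonM",
                "cohort_id"),
              "peptide table")
  if (fc_cutoff <= 1) abort("`fc_cutoff` must be > 1")
  if (any(peptides$abundance_M <= 0 | peptides$abundance_nonM <= 0)) {
    abort("abundances must be strictly positive")
  }
  smry <- if (fc_summary == "mean") mean else median

  res <- peptides |>
    mutate(ld = log2(.data$abundance_M) - log2(.data$abundance_nonM)) |>
    group_by(.data$cohort_id, .data$protein_symbol) |>
    summarise(
      n_peptides = dplyr::n(),
      fc = smry(.data$abundance_M) / smry(.data$abundance_nonM),
      log2_m = log2(smry(.data$abundance_M)),
      log2_nonm = log2(smry(.data$abundance_nonM)),
      d_mean = mean(.data$ld),
      d_sd = ifelse(dplyr::n() > 1, sd(.data$ld), NA_real_),
      n_mapped_max = max(.data$n_mapped_proteins),
      min_score = min(.data$peptide_score),
      .groups = "drop"
    ) |>
    mutate(
      single_peptide = .data$n_peptides == 1L,
      t = ifelse(.data$single_peptide, NA_real_,
                 ifelse(.data$d_sd == 0,
                        sign(.data$d_mean) * Inf,
                        .data$d_mean / (.data$d_sd /
                                          sqrt(.data$n_peptides)))),
      degenerate = !.data$single_peptide & .data$d_sd == 0 &
        .data$d_mean != 0,
      p_value = ifelse(.data$single_peptide, NA_real_,
                       paired_t_p(.data$d_mean, .data$d_sd,
                                  .data$n_peptides)),
      usable = !.data$single_peptide |
        (.data$n_mapped_max == 1L & .data$min_score >= score_cutoff),
      reason = dplyr::case_when(
        .data$usable ~ NA_character_,
        .data$n_mapped_max > 1L ~ "single peptide with multiple protein hits",
        TRUE ~ "single peptide score below cutoff"
      ),
      fc_pass = .data$fc > fc_cutoff | .data$fc < 1 / fc_cutoff,
      candidate = .data$usable & .data$fc_pass &
        (.data$single_peptide | .data$p_value < p_cutoff),
      direction = ifelse(.data$candidate,
                         ifelse(.data$fc > 1, "up", "down"),
                         NA_character_)
    ) |>
    select(-"d_mean", -"d_sd")

  n_dropped <- sum(!res$usable)
  if (!quiet && n_dropped > 0) {
    inform(sprintf(
      "%d (cohort, protein) entries ineligible under the peptide rules",
      n_dropped))
  }
  res
}

#' Four-cohort concordant progression proteins
#'
#' The cross-cohort selection rule: a protein is reported up when its
#' fold change exceeds `fc_cutoff` (strict) in at least `min_cohorts`
#' cohorts, no cohort shows it beyond the cutoff in the opposite
#' direction, and a paired t-test across cohorts (per-cohort protein-level
#' log2 M vs non-M values, loess-normalized by default) has
#' `p < combined_p_cutoff`. The symmetric rule defines the down set; the
#' two sets are disjoint by construction.
#'
#' A protein that is absent (or peptide-rule ineligible) in a cohort is
#' simply non-concordant there; proteins eligible in fewer than two
#' cohorts cannot be paired-tested and are never reported.
#'
#' @param per_cohort Output of [per_cohort_candidates()] covering exactly
#'   four cohorts.
#' @param fc_cutoff Linear fold-change cutoff (strict).
#' @param min_cohorts Minimum concordant cohorts.
#' @param combined_p_cutoff Cross-cohort paired-test p cutoff.
#' @param normalize Loess-normalize the protein-level log2 matrix before
#'   the combined test.
#' @param span Loess span passed to [loess_normalize()].
#' @param quiet Suppress the missing-protein message.
#' @return A tibble of reported proteins: `protein_symbol`, `direction`,
#'   `n_concordant`, wide per-cohort `fc_*` and `p_*` columns, `combined_t`,
#'   `combined_p`, `combined_degenerate`.
#' @export
concordant_progression_proteins <- function(per_cohort, fc_cutoff = 1.25,
                                            min_cohorts = 3,
                                            combined_p_cutoff = 0.1,
                                            normalize = TRUE, span = 0.3,
                                            quiet = FALSE) {
  assert_cols(per_cohort, c("cohort_id", "protein_symbol", "fc", "p_value",
                            "log2_m", "log2_nonm", "usable"),
              "per-cohort candidate table")
  cohorts <- sort(unique(per_cohort$cohort_id))
  if (length(cohorts) != 4) {
    abort(sprintf("expected exactly 4 cohorts, got %d", length(cohorts)))
  }
  u <- filter(per_cohort, .data$usable)

  fc_w <- u |>
    select("protein_symbol", "cohort_id", "fc") |>
    tidyr::pivot_wider(names_from = "cohort_id", values_from = "fc",
                       names_prefix = "fc_")
  p_w <- u |>
    select("protein_symbol", "cohort_id", "p_value") |>
    tidyr::pivot_wider(names_from = "cohort_id", values_from = "p_value",
                       names_prefix = "p_")

  # protein-level log2 matrix (M and non-M per cohort) for the combined test
  lm_w <- u |>
    select("protein_symbol", "cohort_id", "log2_m", "log2_nonm") |>
    tidyr::pivot_wider(names_from = "cohort_id",
                       values_from = c("log2_m", "log2_nonm"))
  if (normalize && nrow(lm_w) >= 10) {
    lm_w <- loess_normalize(lm_w, span = span)
  }

  m_cols <- paste0("log2_m_", cohorts)
  n_cols <- paste0("log2_nonm_", cohorts)
  mm <- as.matrix(lm_w[m_cols])
  nn <- as.matrix(lm_w[n_cols])
  diffs <- mm - nn
  n_pairs <- rowSums(!is.na(diffs))
  d_mean <- rowMeans(diffs, na.rm = TRUE)
  d_sd <- apply(diffs, 1, sd, na.rm = TRUE)
  combined_p <- paired_t_p(d_mean, d_sd, n_pairs)
  combined_t <- ifelse(n_pairs < 2, NA_real_,
                       ifelse(d_sd == 0, sign(d_mean) * Inf,
                              d_mean / (d_sd / sqrt(n_pairs))))

  combined <- tibble(
    protein_symbol = lm_w$protein_symbol,
    combined_t = combined_t,
    combined_p = combined_p,
    combined_degenerate = !is.na(d_sd) & d_sd == 0 & d_mean != 0 &
      n_pairs >= 2
  )

  fcm <- as.matrix(fc_w[paste0("fc_", cohorts)])
  n_up <- rowSums(fcm > fc_cutoff, na.rm = TRUE)
  n_down <- rowSums(fcm < 1 / fc_cutoff, na.rm = TRUE)
  n_present <- rowSums(!is.na(fcm))

  if (!quiet) {
    n_missing <- sum(n_present < 4)
    if (n_missing > 0) {
      inform(sprintf(
        "%d proteins missing or ineligible in at least one cohort", n_missing))
    }
  }

  res <- fc_w |>
    mutate(n_up_concordant = n_up, n_down_concordant = n_down) |>
    left_join(p_w, by = "protein_symbol") |>
    left_join(combined, by = "protein_symbol") |>
    mutate(
      direction = dplyr::case_when(
        n_up >= min_cohorts & n_down == 0 &
          !is.na(.data$combined_p) &
          .data$combined_p < combined_p_cutoff &
          .data$combined_t > 0 ~ "up",
        n_down >= min_cohorts & n_up == 0 &
          !is.na(.data$combined_p) &
          .data$combined_p < combined_p_cutoff &
          .data$combined_t < 0 ~ "down",
        TRUE ~ NA_character_
      ),
      n_concordant = ifelse(.data$direction == "up",
                            .data$n_up_concordant,
                            .data$n_down_concordant)
    ) |>
    filter(!is.na(.data$direction)) |>
    select("protein_symbol", "direction", "n_concordant",
           dplyr::starts_with("fc_"), dplyr::starts_with("p_"),
           "combined_t", "combined_p", "combined_degenerate") |>
    arrange(.data$direction, .data$protein_symbol)
  res
}
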