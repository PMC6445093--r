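#' Mouse prediagnostic fold changes and progression proteins
#'
#' Computes F10/F20 (fast group, prediagnostic 1/2 over baseline) and
#' S10/S20 (slow group) per protein and selects proteins with
#' `F20 > f20_cutoff` (strict). Proteins with a non-positive or missing
#' fast-group baseline are skipped with a message.
#'
#' @param series Mouse tibble with columns `protein_symbol`, `group`
#'   (`fast`/`slow`), `baseline`, `p1`, `p2`.
#' @param f20_cutoff Strict selection cutoff on the fast-group
#'   prediagnostic-2 fold change.
#' @param quiet Suppress the skipped-protein message.
#' @return A tibble: `protein_symbol`, `F10`, `F20`, `S10`, `S20`,
#'   `selected`.
#' @export
mouse_progression_proteins <- function(series, f20_cutoff = 1.3,
                                       quiet = FALSE) {
  assert_cols(series, c("protein_symbol", "group", "baseline", "p1", "p2"),
              "mouse series")
  wide <- series |>
    tidyr::pivot_wider(id_cols = "protein_symbol",
                       names_from = "group",
                       values_from = c("baseline", "p1", "p2"))
  bad <- is.na(wide$baseline_fast) | wide$baseline_fast <= 0
  if (any(bad) && !quiet) {
    inform(sprintf("skipping %d proteins with non-positive fast baseline",
                   sum(bad)))
  }
  wide <- wide[!bad, ]
  res <- wide |>
    transmute(
      protein_symbol = .data$protein_symbol,
      F10 = .data$p1_fast / .data$baseline_fast,
      F20 = .data$p2_fast / .data$baseline_fast,
      S10 = ifelse(.data$baseline_slow > 0,
                   .data$p1_slow / .data$baseline_slow, NA_real_),
      S20 = ifelse(.data$baseline_slow > 0,
                   .data$p2_slow / .data$baseline_slow, NA_real_),
      selected = .data$F20 > f20_cutoff
    )
  arrange(res, .data$protein_symbol)
}

#' Intersect human and mouse progression sets
#'
#' Case-insensitive symbol intersection of the human concordant
#' progression proteins with the selected mouse progression proteins.
#' Each common protein keeps its human direction and mouse fold changes.
#'
#' @param human Tibble from [concordant_progression_proteins()] (needs
#'   `protein_symbol`, `direction`).
#' @param mouse Tibble from [mouse_progression_proteins()].
#' @return A tibble: `protein_symbol` (human casing), `direction`, `F10`,
#'   `F20`, `S10`, `S20`.
#' @export
intersect_species <- function(human, mouse) {
  assert_cols(human, c("protein_symbol", "direction"), "human set")
  assert_cols(mouse, c("protein_symbol", "F20", "selected"), "mouse set")
  h <- human |>
    select("protein_symbol", "direction") |>
    mutate(.key = toupper(.data$protein_symbol))
  m <- mouse |>
    filter(.data$selected) |>
    mutate(.key = toupper(.data$protein_symbol)) |>
    select(".key", "F10", "F20", "S10", "S20")
  inner_join(h, m, by = ".key") |>
    select(-".key") |>
    arrange(.data$protein_symbol)
}

#' Tumor-intrinsic filter against a cell-line panel
#'
#' A candidate plasma protein is retained when it is detected (spectral
#' count >= `min_count`) in at least `min_lines` cell lines in any
#' compartment, i.e. tumor cells can plausibly contribute it to plasma.
#'
#' @param symbols Character vector of candidate symbols.
#' @param panel Cell-line tibble with `line_id`, `compartment`,
#'   `protein_symbol`, `count`.
#' @param min_lines Minimum number of distinct detecting lines.
#' @param min_count Minimum spectral count that counts as detection.
#' @param quiet Suppress the removed-protein message.
#' @return A tibble: `protein_symbol`, `n_lines_detected`, `retained`.
#' @export
tumor_intrinsic_filter <- function(symbols, panel, min_lines = 1,
                                   min_count = 1, quiet = FALSE) {
  assert_cols(panel, c("line_id", "protein_symbol", "count"),
              "cell-line panel")
  if (nrow(panel) == 0) abort("`panel` must be non-empty")
  det <- panel |>
    filter(.data$count >= min_count) |>
    mutate(.key = toupper(.data$protein_symbol)) |>
    distinct(.data$.key, .data$line_id) |>
    count(.data$.key, name = "n_lines_detected")
  res <- tibble(protein_symbol = symbols,
                .key = toupper(symbols)) |>
    left_join(det, by = ".key") |>
    mutate(n_lines_detected = tidyr::replace_na(.data$n_lines_detected, 0L),
           retained = .data$n_lines_detected >= min_lines) |>
    select(-".key")
  if (!quiet && any(!res$retained)) {
    inform(sprintf("removed (not detected in cell lines): %s",
                   paste(res$protein_symbol[!res$retained],
                         collapse = ", ")))
  }
  res
}

#' Secretome differential sets across two cell-line pairs
#'
#' Proteins commonly elevated (ratio >= `up_cutoff` in BOTH
#' metastatic/non-metastatic media pairs, inclusive) or commonly
#' down-regulated (ratio <= `down_cutoff` in both, inclusive). Proteins
#' missing from either pair are excluded from both sets and logged.
#'
#' @param pair1,pair2 Tibbles with `protein_symbol` and `ratio`
#'   (metastatic over non-metastatic media abundance).
#' @param up_cutoff Inclusive common-elevation cutoff.
#' @param down_cutoff Inclusive common-reduction cutoff.
#' @param signature Optional symbol list; the overlap of the up/down sets
#'   with it is attached as attribute `"signature_overlap"`.
#' @param quiet Suppress the missing-protein message.
#' @return A tibble: `protein_symbol`, `ratio_1`, `ratio_2`, `class`
#'   (`up`/`down`/`none`).
#' @export
secretome_differential <- function(pair1, pair2, up_cutoff = 1.5,
                                   down_cutoff = 0.67, signature = NULL,
                                   quiet = FALSE) {
  assert_cols(pair1, c("protein_symbol", "ratio"), "pair 1")
  assert_cols(pair2, c("protein_symbol", "ratio"), "pair 2")
  joined <- full_join(
    rename(pair1, ratio_1 = "ratio"),
    rename(pair2, ratio_2 = "ratio"),
    by = "protein_symbol"
  )
  missing <- !complete.cases(joined[c("ratio_1", "ratio_2")])
  if (any(missing) && !quiet) {
    inform(sprintf("%d proteins missing from one pair; excluded",
                   sum(missing)))
  }
  res <- joined[!missing, ] |>
    mutate(class = dplyr::case_when(
      .data$ratio_1 >= up_cutoff & .data$ratio_2 >= up_cutoff ~ "up",
      .data$ratio_1 <= down_cutoff & .data$ratio_2 <= down_cutoff ~ "down",
      TRUE ~ "none"
    )) |>
    arrange(.data$protein_symbol)
  if (!is.null(signature)) {
    attr(res, "signature_overlap") <- list(
      up = intersect(res$protein_symbol[res$class == "up"], signature),
      down = intersect(res$protein_symbol[res$class == "down"], signature)
    )
  }
  res
}

#' Refine the progression signature
#'
#' Final cross-species rule: keep proteins concordantly UP in the human
#' metastatic contrast whose mouse fast-group F20 exceeds the cutoff and
#' which survive the tumor-intrinsic cell-line filter. The result is the
#' deterministically ordered (alphabetical) signature gene list.
#'
#' @param common Tibble from [intersect_species()].
#' @param intrinsic Tibble from [tumor_intrinsic_filter()] or a character
#'   vector of retained symbols.
#' @param f20_cutoff Strict mouse F20 cutoff.
#' @return Sorted character vector of signature genes (possibly empty,
#'   with a warning).
#' @export
refine_signature <- function(common, intrinsic, f20_cutoff = 1.3) {
  assert_cols(common, c("protein_symbol", "direction", "F20"),
              "common set")
  retained <- if (is.data.frame(intrinsic)) {
    intrinsic$protein_symbol[intrinsic$retained]
  } else {
    intrinsic
  }
  out <- common |>
    filter(.data$direction == "up",
           .data$F20 > f20_cutoff,
           toupper(.data$protein_symbol) %in% toupper(retained)) |>
    pull("protein_symbol") |>
    unique() |>
    sort()
  if (length(out) == 0) {
    warn("refined signature is empty")
  }
  out
}
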