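#' Loess normalization of a protein-by-sample abundance table
#'
#' Removes smooth intensity-dependent bias from each sample on the log
#' scale. For every sample the deviation from the row-wise reference
#' profile (the per-protein median across samples) is regressed on the
#' MA-style mean abundance `(sample + reference) / 2` with a loess smoother,
#' and the fitted bias curve is subtracted. Each normalized sample is then
#' re-centred so its median equals the reference median exactly.
#'
#' A constant log offset between samples is removed entirely; a table that
#' already sits on its reference profile is returned unchanged.
#'
#' @param data A data frame whose first column is a protein identifier and
#'   whose remaining columns are numeric per-sample log abundances (use
#'   `log_transform = TRUE` to pass raw positive abundances instead).
#' @param span Loess span; must lie in (0, 1].
#' @param log_transform If `TRUE`, abundances are checked to be strictly
#'   positive and log2-transformed first.
#' @return A tibble of the same shape with normalized (log-scale) values.
#' @export
loess_normalize <- function(data, span = 0.3, log_transform = FALSE) {
  if (!is.numeric(span) || length(span) != 1 || is.na(span) ||
      span <= 0 || span > 1) {
    abort("`span` must lie in (0, 1]")
  }
  data <- as_tibble(data)
  if (ncol(data) < 3) abort("need an id column plus at least two samples")
  id_col <- names(data)[1]
  num_cols <- names(data)[-1]
  if (!all(vapply(data[num_cols], is.numeric, logical(1)))) {
    abort("all sample columns must be numeric")
  }
  m <- as.matrix(data[num_cols])
  if (nrow(m) < 10) abort("need at least 10 proteins to fit a bias curve")

  if (log_transform) {
    bad <- which(rowSums(!is.na(m) & m <= 0) > 0)
    if (length(bad)) {
      abort(sprintf(
        "non-positive abundance in row(s): %s",
        paste(head(data[[id_col]][bad], 5), collapse = ", ")))
    }
    m <- log2(m)
  }
  if (any(!is.finite(m[!is.na(m)]))) {
    abort("log abundances must be finite")
  }

  ref <- apply(m, 1, median, na.rm = TRUE)
  out <- m
  for (j in seq_along(num_cols)) {
    ok <- !is.na(m[, j]) & !is.na(ref)
    a <- (m[ok, j] + ref[ok]) / 2
    d <- m[ok, j] - ref[ok]
    fitted <- if (sd(d) == 0 || length(unique(a)) < 4) {
      rep(mean(d), length(d))
    } else {
      fit <- loess(d ~ a, span = span, degree = 1, family = "gaussian",
                   surface = "direct")
      predict(fit, a)
    }
    v <- m[ok, j] - fitted
    v <- v + (median(ref[ok]) - median(v))
    out[ok, j] <- v
  }
  bind_cols(data[id_col], as_tibble(out))
}
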