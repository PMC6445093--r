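#' Per-patient signature risk score
#'
#' The risk score is the arithmetic mean of the signature genes' expression
#' values. By default each gene is standardized (centered and scaled across
#' patients) first, so genes measured on different scales contribute
#' equally; set `standardize = FALSE` for the literal mean of raw values.
#'
#' @param data Data frame with a `patient_id` column and one numeric
#'   column per gene.
#' @param genes Character vector of signature genes; every gene must be
#'   present.
#' @param standardize Standardize each gene across patients before
#'   averaging (default `TRUE`).
#' @return A tibble: `patient_id`, `risk_score`.
#' @export
risk_score <- function(data, genes, standardize = TRUE) {
  assert_cols(data, "patient_id", "expression table")
  missing <- setdiff(genes, names(data))
  if (length(missing)) {
    abort(sprintf("signature gene not present: %s",
                  paste(missing, collapse = ", ")))
  }
  m <- as.matrix(data[genes])
  if (!is.numeric(m)) abort("gene columns must be numeric")
  if (standardize) {
    sds <- apply(m, 2, sd)
    if (any(sds == 0)) {
      abort(sprintf("cannot standardize constant gene: %s",
                    genes[which(sds == 0)[1]]))
    }
    m <- scale(m)
  }
  tibble(patient_id = data$patient_id, risk_score = rowMeans(m))
}

#' Stratify patients into high- and low-risk groups
#'
#' High risk is the top `high_fraction` of risk scores: the threshold is
#' the `ceiling(high_fraction * N)`-th largest score and every patient at
#' or above it is high risk (so score ties at the threshold all fall into
#' the high group; the realized group sizes are recorded in attributes).
#'
#' @param scores Tibble from [risk_score()] (columns `patient_id`,
#'   `risk_score`), N >= 4.
#' @param high_fraction Target fraction of high-risk patients.
#' @return A tibble `patient_id`, `risk_score`, `risk_group` (factor
#'   `low`/`high`) with attributes `threshold`, `n_high`, `n_low`.
#' @export
stratify_risk <- function(scores, high_fraction = 0.25) {
  assert_cols(scores, c("patient_id", "risk_score"), "score table")
  assert_prob(high_fraction, "high_fraction")
  s <- scores$risk_score
  if (length(s) < 4) abort("need at least 4 patients to stratify")
  if (length(unique(s)) == 1) {
    abort("all risk scores identical: no quantile split exists")
  }
  split <- high_split(s, high_fraction)
  out <- scores |>
    mutate(risk_group = factor(ifelse(split$high, "high", "low"),
                               levels = c("low", "high")))
  attr(out, "threshold") <- split$threshold
  attr(out, "n_high") <- sum(split$high)
  attr(out, "n_low") <- sum(!split$high)
  out
}

surv_inputs <- function(data, time, event, group) {
  assert_cols(data, c(time, event), "survival table")
  tt <- data[[time]]
  ev <- data[[event]]
  if (any(tt < 0)) abort("negative follow-up time")
  if (!all(ev %in% c(0, 1))) abort("`event` must be 0/1")
  g <- if (is.null(group)) factor(rep("all", nrow(data)))
       else factor(data[[group]])
  list(time = tt, event = ev, group = g)
}

#' Kaplan-Meier survival curves
#'
#' Product-limit estimator per group; censored subjects leave the risk set
#' after their censoring time. Each curve starts at `S(0) = 1`.
#'
#' @param data Data frame with follow-up columns.
#' @param time,event,group Column names (group `NULL` for a single curve).
#' @return A tibble: `group`, `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`, including a `time = 0` row per group.
#' @export
km_estimate <- function(data, time = "time", event = "event",
                        group = NULL) {
  si <- surv_inputs(data, time, event, group)
  if (any(table(si$group) == 0)) abort("every group must be non-empty")
  fit <- survfit(Surv(si$time, si$event) ~ si$group)
  strata <- if (is.null(fit$strata)) {
    rep(levels(si$group)[1], length(fit$time))
  } else {
    rep(sub("^si\\$group=", "", names(fit$strata)), fit$strata)
  }
  curves <- tibble(
    group = strata, time = fit$time, n_risk = fit$n.risk,
    n_event = fit$n.event, n_censor = fit$n.censor, survival = fit$surv
  )
  zero <- curves |>
    group_by(.data$group) |>
    summarise(time = 0, n_risk = max(.data$n_risk), n_event = 0L,
              n_censor = 0L, survival = 1, .groups = "drop")
  bind_rows(zero, curves) |>
    arrange(.data$group, .data$time)
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic: observed vs expected events summed over the
#' distinct event times with the hypergeometric variance; p from chi-square
#' with 1 degree of freedom.
#'
#' @param data Data frame with follow-up and group columns.
#' @param time,event,group Column names; `group` must have exactly two
#'   non-empty levels.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(data, time = "time", event = "event",
                         group = "risk_group") {
  si <- surv_inputs(data, time, event, group)
  si$group <- droplevels(si$group)
  if (nlevels(si$group) != 2) abort("`group` must have exactly two levels")
  if (sum(si$event) == 0) abort("no events observed: log-rank undefined")
  sd <- survdiff(Surv(si$time, si$event) ~ si$group)
  tibble(statistic = sd$chisq, df = 1,
         p_value = pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional hazards fits, uni- or multivariate
#'
#' Wraps [survival::coxph()] (Efron tie handling by default). In
#' `"multivariate"` mode all covariates enter one model; in `"univariate"`
#' mode each covariate is fit alone. Coefficients are reported with hazard
#' ratios, Wald 95% confidence intervals and p-values, broom-style via
#' [tidy()] and [glance()].
#'
#' @param data Data frame containing follow-up and covariate columns.
#' @param covariates Character vector of covariate column names; none may
#'   be constant.
#' @param time,event Column names.
#' @param mode `"multivariate"` or `"univariate"`.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return An object of class `plasmasig_cox`.
#' @export
cox_fit <- function(data, covariates, time = "time", event = "event",
                    mode = c("multivariate", "univariate"),
                    ties = c("efron", "breslow")) {
  mode <- match.arg(mode)
  ties <- match.arg(ties)
  assert_cols(data, c(time, event, covariates), "survival table")
  if (any(data[[time]] < 0)) abort("negative follow-up time")
  for (cv in covariates) {
    v <- data[[cv]]
    if (is.factor(v)) v <- as.integer(v)
    if (!all(is.finite(as.numeric(v)))) {
      abort(sprintf("covariate `%s` has non-finite values", cv))
    }
    if (length(unique(v)) == 1) {
      abort(sprintf("covariate `%s` is constant", cv))
    }
  }
  fit_one <- function(covs, label) {
    f <- as.formula(paste0("Surv(", time, ", ", event, ") ~ ",
                           paste(covs, collapse = " + ")))
    flags <- character()
    fit <- withCallingHandlers(
      coxph(f, data = data, ties = ties),
      warning = function(w) {
        flags <<- c(flags, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    s <- summary(fit)
    tb <- tibble(
      model = label,
      term = rownames(s$coefficients),
      beta = s$coefficients[, "coef"],
      hr = s$conf.int[, "exp(coef)"],
      ci_lower = s$conf.int[, "lower .95"],
      ci_upper = s$conf.int[, "upper .95"],
      p_value = s$coefficients[, "Pr(>|z|)"],
      flagged = length(flags) > 0
    )
    list(table = tb, fit = fit, flags = flags)
  }
  fits <- if (mode == "multivariate") {
    list(multivariate = fit_one(covariates, "multivariate"))
  } else {
    setNames(lapply(covariates, function(cv) fit_one(cv, cv)), covariates)
  }
  structure(
    list(
      table = map_dfr(fits, "table"),
      fits = lapply(fits, `[[`, "fit"),
      flags = unlist(lapply(fits, `[[`, "flags")),
      mode = mode, ties = ties,
      n = nrow(data), n_events = sum(data[[event]])
    ),
    class = "plasmasig_cox"
  )
}

#' @export
print.plasmasig_cox <- function(x, ...) {
  cat(sprintf("<plasmasig_cox> %s Cox model (%s ties), %d subjects, %d events\n",
              x$mode, x$ties, x$n, x$n_events))
  print(as.data.frame(x$table), digits = 4)
  if (length(x$flags)) {
    cat("flags:", paste(unique(x$flags), collapse = "; "), "\n")
  }
  invisible(x)
}

#' @rdname cox_fit
#' @param x A `plasmasig_cox` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.plasmasig_cox <- function(x, ...) x$table

#' @rdname cox_fit
#' @exportS3Method generics::glance
glance.plasmasig_cox <- function(x, ...) {
  conc <- if (x$mode == "multivariate") {
    unname(summary(x$fits[[1]])$concordance["C"])
  } else {
    NA_real_
  }
  tibble(n = x$n, n_events = x$n_events, mode = x$mode, ties = x$ties,
         n_models = length(x$fits), concordance = conc,
         flagged = length(x$flags) > 0)
}

#' Pearson correlation of signature genes with a reference gene
#'
#' Per-gene Pearson correlation against a reference expression column
#' (typically `TGFB1`) with the two-sided t-approximation p-value. Genes
#' with zero variance (or a zero-variance reference) are flagged and get
#' `r = NA`.
#'
#' @param data Expression data frame (samples in rows, genes in columns).
#' @param genes Genes to correlate.
#' @param reference Reference gene column (default `"TGFB1"`).
#' @return A tibble: `gene`, `r`, `p_value`, `n`, `degenerate`.
#' @export
tgfb_correlation <- function(data, genes, reference = "TGFB1") {
  assert_cols(data, c(genes, reference), "expression table")
  y <- data[[reference]]
  if (length(y) < 3) abort("need at least 3 samples")
  map_dfr(genes, function(g) {
    x <- data[[g]]
    if (sd(x) == 0 || sd(y) == 0) {
      return(tibble(gene = g, r = NA_real_, p_value = NA_real_,
                    n = length(x), degenerate = TRUE))
    }
    ct <- cor.test(x, y, method = "pearson")
    tibble(gene = g, r = unname(ct$estimate), p_value = ct$p.value,
           n = length(x), degenerate = FALSE)
  })
}
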