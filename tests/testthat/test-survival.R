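toy_surv <- function() {
  tibble::tibble(time = km_toy$time, event = km_toy$event)
}

test_that("risk score averages genes, optionally standardized", {
  d <- tibble::tibble(patient_id = "p1", g1 = 1, g2 = 2, g3 = 3)
  expect_equal(risk_score(d, c("g1", "g2", "g3"),
                          standardize = FALSE)$risk_score, 2)
  set.seed(1)
  dd <- tibble::tibble(patient_id = sprintf("p%02d", 1:50),
                       a = rnorm(50, 10, 2), b = rnorm(50, 0, 1),
                       c = rnorm(50, -5, 4))
  rs <- risk_score(dd, c("a", "b", "c"))
  oracle <- rowMeans(scale(as.matrix(dd[c("a", "b", "c")])))
  expect_equal(rs$risk_score, unname(oracle), tolerance = 1e-12)
  # one-gene signature: score is that gene standardized
  one <- risk_score(dd, "a")
  expect_equal(one$risk_score, as.numeric(scale(dd$a)), tolerance = 1e-12)
  expect_error(risk_score(dd, c("a", "zz")), "zz")
  expect_error(risk_score(dplyr::mutate(dd, a = 1), c("a", "b")),
               "constant")
})

test_that("stratification takes the top quantile with recorded ties", {
  s8 <- tibble::tibble(patient_id = paste0("p", 1:8),
                       risk_score = c(8, 1, 5, 3, 7, 2, 6, 4))
  st <- stratify_risk(s8, 0.25)
  expect_equal(attr(st, "n_high"), 2)
  expect_setequal(st$patient_id[st$risk_group == "high"],
                  c("p1", "p5")) # scores 8 and 7

  s4 <- tibble::tibble(patient_id = paste0("q", 1:4),
                       risk_score = 1:4)
  st4 <- stratify_risk(s4, 0.25)
  expect_equal(st4$patient_id[st4$risk_group == "high"], "q4")

  set.seed(2)
  s210 <- tibble::tibble(patient_id = sprintf("r%03d", 1:210),
                         risk_score = rnorm(210))
  st210 <- stratify_risk(s210, 0.25)
  # independent sort-and-slice oracle
  n_high <- ceiling(0.25 * 210)
  oracle_high <- s210$patient_id[order(-s210$risk_score)][1:n_high]
  expect_setequal(st210$patient_id[st210$risk_group == "high"],
                  oracle_high)
  expect_equal(attr(st210, "n_high") + attr(st210, "n_low"), 210)

  expect_error(stratify_risk(tibble::tibble(patient_id = "x",
                                            risk_score = 1)), "at least 4")
  expect_error(stratify_risk(tibble::tibble(patient_id = paste0("t", 1:5),
                                            risk_score = rep(2, 5))),
               "identical")
})

test_that("Kaplan-Meier estimates equal the hand-computed product limit", {
  km <- km_estimate(toy_surv())
  ev <- km[km$n_event > 0, ]
  expect_equal(ev$time, km_toy$event_times)
  expect_equal(ev$survival, km_toy$survival, tolerance = 1e-12)
  # starts at 1, nonincreasing
  expect_equal(km$survival[km$time == 0], 1)
  expect_true(all(diff(km$survival) <= 1e-12))
})

test_that("without censoring KM equals the empirical survival function", {
  set.seed(3)
  d <- tibble::tibble(time = sort(rexp(40)), event = 1)
  km <- km_estimate(d)
  at_events <- km[km$n_event > 0, ]
  emp <- sapply(at_events$time, function(t) mean(d$time > t))
  expect_equal(at_events$survival, emp, tolerance = 1e-12)

  allc <- km_estimate(tibble::tibble(time = 1:5, event = 0))
  expect_true(all(allc$survival == 1))
  expect_error(km_estimate(tibble::tibble(time = c(-1, 2),
                                          event = c(1, 1))), "negative")
})

test_that("log-rank is zero for duplicated groups and matches the
           single-event-time closed form", {
  base <- toy_surv()
  dup <- dplyr::bind_rows(dplyr::mutate(base, grp = "a"),
                          dplyr::mutate(base, grp = "b"))
  lr <- logrank_test(dup, group = "grp")
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1, tolerance = 1e-12)

  # one event at t=1 in group A; equal risk sets of 2 at that time:
  # E_A = 0.5, V = 0.25, chi-square = (1 - 0.5)^2 / 0.25 = 1
  one <- tibble::tibble(time = c(1, 2, 1.5, 2), event = c(1, 0, 0, 0),
                        grp = c("A", "A", "B", "B"))
  lr1 <- logrank_test(one, group = "grp")
  expect_equal(lr1$statistic, 1, tolerance = 1e-12)
  expect_equal(lr1$p_value, pchisq(1, 1, lower.tail = FALSE),
               tolerance = 1e-12)

  # label swap invariance
  sw <- dplyr::mutate(one, grp = ifelse(grp == "A", "B", "A"))
  expect_equal(logrank_test(sw, group = "grp")$statistic, lr1$statistic,
               tolerance = 1e-12)
  expect_error(logrank_test(dplyr::mutate(one, event = 0), group = "grp"),
               "no events")
})

test_that("Cox coefficients maximize the partial likelihood (grid oracle)", {
  d <- tibble::tibble(
    time = c(1.1, 2.3, 3.7, 4.2, 5.5, 6.1, 7.8, 9.4),
    event = c(1, 1, 0, 1, 1, 0, 1, 1),
    x = c(1, 0, 1, 1, 0, 0, 1, 0))
  fit <- cox_fit(d, "x")
  beta_grid <- bf_cox_grid(d$time, d$event, d$x)
  expect_equal(tidy(fit)$beta, beta_grid, tolerance = 1e-3)
  expect_equal(tidy(fit)$hr, exp(tidy(fit)$beta), tolerance = 1e-12)
  # CI brackets the HR
  expect_lt(tidy(fit)$ci_lower, tidy(fit)$hr)
  expect_gt(tidy(fit)$ci_upper, tidy(fit)$hr)
})

test_that("Cox HR inverts under covariate sign flip", {
  set.seed(5)
  d <- tibble::tibble(time = rexp(100), event = rbinom(100, 1, 0.8),
                      x = rbinom(100, 1, 0.5))
  f1 <- tidy(cox_fit(d, "x"))
  f2 <- tidy(cox_fit(dplyr::mutate(d, x = 1 - x), "x"))
  expect_equal(f1$hr, 1 / f2$hr, tolerance = 1e-8)
})

test_that("univariate and multivariate modes fit the requested models", {
  set.seed(6)
  d <- tibble::tibble(time = rexp(120), event = rbinom(120, 1, 0.7),
                      a = rbinom(120, 1, 0.5), b = rnorm(120))
  uni <- cox_fit(d, c("a", "b"), mode = "univariate")
  expect_equal(nrow(tidy(uni)), 2)
  expect_setequal(tidy(uni)$model, c("a", "b"))
  multi <- cox_fit(d, c("a", "b"), mode = "multivariate")
  expect_true(all(tidy(multi)$model == "multivariate"))
  g <- glance(multi)
  expect_equal(g$n, 120)
  expect_false(is.na(g$concordance))
  expect_error(cox_fit(d, "zz"), "zz")
  expect_error(cox_fit(dplyr::mutate(d, a = 1), "a"), "constant")
})

test_that("null-hazard simulations give near-zero mean coefficient", {
  set.seed(8)
  betas <- replicate(30, {
    d <- tibble::tibble(time = rexp(100), event = 1,
                        x = rbinom(100, 1, 0.5))
    tidy(cox_fit(d, "x"))$beta
  })
  expect_lt(abs(mean(betas)), 0.1)
})

test_that("reference-gene correlation matches the covariance formula", {
  set.seed(9)
  d <- tibble::tibble(TGFB1 = rnorm(30), g1 = rnorm(30), g2 = rnorm(30))
  d$copy <- d$TGFB1
  d$neg <- -d$TGFB1
  d$flat <- 1
  res <- tgfb_correlation(d, c("copy", "neg", "g1", "g2", "flat"))
  expect_equal(res$r[res$gene == "copy"], 1, tolerance = 1e-12)
  expect_equal(res$r[res$gene == "neg"], -1, tolerance = 1e-12)
  expect_true(res$degenerate[res$gene == "flat"])
  for (g in c("g1", "g2")) {
    x <- d[[g]]; y <- d$TGFB1
    oracle <- sum((x - mean(x)) * (y - mean(y))) /
      ((length(x) - 1) * sd(x) * sd(y))
    expect_equal(res$r[res$gene == g], oracle, tolerance = 1e-12)
  }
  expect_error(tgfb_correlation(d[1:2, ], "g1"), "3 samples")
})
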