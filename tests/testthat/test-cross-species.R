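mouse_rows <- function(sym, fast_base, fast_p1, fast_p2,
                       slow_base = fast_base, slow_p1 = fast_base,
                       slow_p2 = fast_base) {
  tibble::tibble(
    protein_symbol = sym,
    group = c("fast", "slow"),
    baseline = c(fast_base, slow_base),
    p1 = c(fast_p1, slow_p1),
    p2 = c(fast_p2, slow_p2))
}

test_that("mouse F20 selection is strict at the 1.3 boundary", {
  series <- dplyr::bind_rows(
    mouse_rows("SEL", 10, 12, 14),   # F20 = 1.4 -> selected
    mouse_rows("EDGE", 10, 11, 13),  # F20 = 1.3 exactly -> not selected
    mouse_rows("FLAT", 10, 10, 10))
  mp <- mouse_progression_proteins(series, quiet = TRUE)
  expect_equal(mp$F20[mp$protein_symbol == "SEL"], 1.4)
  expect_true(mp$selected[mp$protein_symbol == "SEL"])
  expect_equal(mp$F20[mp$protein_symbol == "EDGE"], 1.3)
  expect_false(mp$selected[mp$protein_symbol == "EDGE"])
  expect_false(mp$selected[mp$protein_symbol == "FLAT"])
  # F10/S20 recomputable from the inputs
  expect_equal(mp$F10[mp$protein_symbol == "SEL"], 1.2, tolerance = 1e-12)
  expect_equal(mp$S20[mp$protein_symbol == "SEL"], 1, tolerance = 1e-12)
})

test_that("mouse selection equals row-by-row enumeration on a toy table", {
  set.seed(17)
  series <- purrr::map_dfr(sprintf("M%02d", 1:50), function(s) {
    mouse_rows(s, runif(1, 5, 20), runif(1, 5, 25), runif(1, 5, 30))
  })
  mp <- mouse_progression_proteins(series, quiet = TRUE)
  fast <- series[series$group == "fast", ]
  oracle <- fast$protein_symbol[fast$p2 / fast$baseline > 1.3]
  expect_setequal(mp$protein_symbol[mp$selected], oracle)
})

test_that("species intersection keeps direction and mouse fold changes", {
  human <- tibble::tibble(protein_symbol = c("Aa", "Bb", "Cc"),
                          direction = c("up", "down", "up"))
  mouse <- tibble::tibble(protein_symbol = c("AA", "CC", "DD"),
                          F10 = 1.1, F20 = c(1.5, 1.6, 1.7),
                          S10 = 1, S20 = 1,
                          selected = c(TRUE, TRUE, TRUE))
  common <- intersect_species(human, mouse)
  expect_setequal(common$protein_symbol, c("Aa", "Cc")) # case-insensitive
  expect_equal(common$direction[common$protein_symbol == "Aa"], "up")
  expect_equal(common$F20[common$protein_symbol == "Cc"], 1.6)

  none <- intersect_species(human,
                            dplyr::mutate(mouse, selected = FALSE))
  expect_equal(nrow(none), 0)
  all_same <- intersect_species(
    tibble::tibble(protein_symbol = "AA", direction = "up"), mouse)
  expect_equal(all_same$protein_symbol, "AA")
})

test_that("tumor-intrinsic filter counts detecting lines correctly", {
  panel <- tibble::tibble(
    line_id = c("L1", "L1", "L2", "L3", "L1"),
    compartment = c("total", "media", "total", "total", "total"),
    protein_symbol = c("A", "A", "A", "B", "C"),
    count = c(5L, 2L, 1L, 1L, 0L))
  res <- tumor_intrinsic_filter(c("A", "B", "C", "D"), panel,
                                quiet = TRUE)
  expect_equal(res$n_lines_detected, c(2L, 1L, 0L, 0L))
  expect_equal(res$retained, c(TRUE, TRUE, FALSE, FALSE))
  # tightening min_lines can only remove
  res2 <- tumor_intrinsic_filter(c("A", "B", "C", "D"), panel,
                                 min_lines = 2, quiet = TRUE)
  expect_true(all(res2$retained <= res$retained))
  # enumeration oracle on a random panel
  set.seed(4)
  rp <- tibble::tibble(
    line_id = sample(paste0("L", 1:6), 200, replace = TRUE),
    compartment = "total",
    protein_symbol = sample(paste0("P", 1:40), 200, replace = TRUE),
    count = rpois(200, 1))
  syms <- paste0("P", 1:40)
  got <- tumor_intrinsic_filter(syms, rp, min_lines = 2, min_count = 2,
                                quiet = TRUE)
  oracle <- vapply(syms, function(s) {
    sub <- rp[rp$protein_symbol == s & rp$count >= 2, ]
    length(unique(sub$line_id)) >= 2
  }, logical(1))
  expect_equal(got$retained, unname(oracle))
})

test_that("secretome cutoffs are inclusive and require both pairs", {
  p1 <- tibble::tibble(protein_symbol = c("A", "B", "C", "D", "E"),
                       ratio = c(1.5, 1.6, 0.67, 0.5, 1.0))
  p2 <- tibble::tibble(protein_symbol = c("A", "B", "C", "D"),
                       ratio = c(1.5, 1.4, 0.67, 0.67))
  res <- secretome_differential(p1, p2, quiet = TRUE,
                                signature = c("A", "C"))
  cls <- function(s) res$class[res$protein_symbol == s]
  expect_equal(cls("A"), "up")    # exactly 1.5 in both: inclusive
  expect_equal(cls("B"), "none")  # (1.6, 1.4): fails one pair
  expect_equal(cls("C"), "down")  # exactly 0.67 in both: inclusive
  expect_equal(cls("D"), "down")
  expect_false("E" %in% res$protein_symbol) # missing from pair 2
  ov <- attr(res, "signature_overlap")
  expect_equal(ov$up, "A")
  expect_equal(ov$down, "C")
})

test_that("secretome sets match an enumeration oracle on random tables", {
  set.seed(11)
  syms <- sprintf("S%03d", 1:300)
  r1 <- tibble::tibble(protein_symbol = syms,
                       ratio = exp(rnorm(300, 0, 0.5)))
  r2 <- tibble::tibble(protein_symbol = syms,
                       ratio = exp(rnorm(300, 0, 0.5)))
  res <- secretome_differential(r1, r2, quiet = TRUE)
  up_oracle <- syms[r1$ratio >= 1.5 & r2$ratio >= 1.5]
  down_oracle <- syms[r1$ratio <= 0.67 & r2$ratio <= 0.67]
  expect_setequal(res$protein_symbol[res$class == "up"], up_oracle)
  expect_setequal(res$protein_symbol[res$class == "down"], down_oracle)
})

test_that("signature refinement applies direction, F20 and detection", {
  common <- tibble::tibble(
    protein_symbol = c("UPOK", "UPLOW", "DOWN", "UPGONE"),
    direction = c("up", "up", "down", "up"),
    F10 = 1, F20 = c(1.5, 1.2, 1.6, 1.5), S10 = 1, S20 = 1)
  intrinsic <- tibble::tibble(
    protein_symbol = c("UPOK", "UPLOW", "DOWN", "UPGONE"),
    n_lines_detected = c(3L, 3L, 3L, 0L),
    retained = c(TRUE, TRUE, TRUE, FALSE))
  sig <- refine_signature(common, intrinsic)
  expect_equal(sig, "UPOK") # UPLOW fails F20, DOWN wrong direction,
                            # UPGONE not tumor-intrinsic
  expect_warning(refine_signature(common[3, ], intrinsic), "empty")
})

test_that("refined signature equals planted truth end to end (zero noise)", {
  cfg <- sim_config(n_proteins = 300L, n_up = 15L, n_down = 15L,
                    n_mouse_fast = 25L, noise_cv = 0, mouse_noise_cv = 0,
                    seed = 77)
  study <- simulate_study(cfg)
  pc <- per_cohort_candidates(study$plasma$peptides, quiet = TRUE)
  prog <- concordant_progression_proteins(pc, quiet = TRUE)
  mp <- mouse_progression_proteins(study$mouse$series, quiet = TRUE)
  common <- intersect_species(prog, mp)
  intr <- tumor_intrinsic_filter(common$protein_symbol,
                                 study$panel$panel, quiet = TRUE)
  sig <- refine_signature(common, intr)
  expect_identical(sig, study$truth$signature_genes)
  # containment invariants
  expect_true(all(common$protein_symbol %in% prog$protein_symbol))
  expect_true(all(sig %in% common$protein_symbol))
  expect_equal(nrow(common),
               length(study$truth$common_up) +
                 length(study$truth$common_down))
})
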