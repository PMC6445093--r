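# Constructed per-cohort candidate rows (schema of per_cohort_candidates
# output) for concordance-rule and boundary fixtures.

pc_row <- function(cohort, sym, fc, log2_nonm = 10, usable = TRUE,
                   p_value = NA_real_) {
  tibble::tibble(cohort_id = cohort, protein_symbol = sym, fc = fc,
                 p_value = p_value, log2_m = log2_nonm + log2(fc),
                 log2_nonm = log2_nonm, usable = usable)
}

pc_table <- function(sym, fcs, usable = rep(TRUE, 4)) {
  purrr::map_dfr(1:4, function(i) {
    pc_row(paste0("C", i), sym, fcs[i], usable = usable[i])
  })
}
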