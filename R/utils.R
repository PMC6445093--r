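# Internal validation and seeding helpers.

# Deterministic child seed for a named simulation sub-stream. Keeps every
# derived seed well below 2^31 - 1 so set.seed() always accepts it.
child_seed <- function(seed, tag) {
  stopifnot(length(seed) == 1, is.finite(seed))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag))) %% 104729L
  as.integer((abs(as.integer(seed)) %% 1000003L) * 2011L + h)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single proportion in [0, 1], got %s",
                  name, format(x)))
  }
  invisible(x)
}

assert_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) abort(sprintf("`%s` must be a single %s number",
                         name, if (strict) "positive" else "nonnegative"))
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    x == as.integer(x) && x >= min
  if (!ok) abort(sprintf("`%s` must be a single integer >= %d", name, min))
  invisible(as.integer(x))
}

assert_cols <- function(data, cols, what = "input table") {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(data)
}

# Coefficient of variation -> sdlog of the matching lognormal noise term.
cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

# Multiplicative lognormal noise with mean-zero log (so log fold changes
# are unbiased); cv = 0 returns exactly 1.
lnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  rlnorm(n, meanlog = 0, sdlog = cv_to_sdlog(cv))
}
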