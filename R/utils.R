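# Internal helpers shared across modules.

# round() in R rounds half to even; allele counts use half away from zero.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Evaluate `expr` under a local RNG state seeded with `seed`; when seed is
# NULL the global stream is used (and advanced) as-is.
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

assert_columns <- function(data, cols, what = deparse(substitute(data))) {
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  what, paste0("'", miss, "'", collapse = ", ")))
  }
  invisible(data)
}

assert_prob <- function(x, what) {
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (any(bad)) {
    abort(sprintf("`%s` must lie in [0, 1]; offending value(s): %s",
                  what, paste(head(x[bad], 3), collapse = ", ")))
  }
  invisible(x)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)
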