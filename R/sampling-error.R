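#' Exact sampling-error bounds for a bulk allele frequency
#'
#' A bulk of `n_individuals` diploid individuals carries
#' `n = 2 * n_individuals * n_replicates` sampled gametes. Given an observed
#' allele-B frequency, the implied allele count is `x = round(freq * n)`
#' (half away from zero) and the `conf`-level Clopper-Pearson interval is
#' returned: `lower = qbeta((1 - conf)/2, x, n - x + 1)` (0 when x = 0) and
#' `upper = qbeta(1 - (1 - conf)/2, x + 1, n - x)` (1 when x = n). Two
#' replicates are modeled as pooled gametes (n doubles).
#'
#' @param freq Observed/true allele-B frequency (vectorized, in `[0, 1]`).
#' @param n_individuals Diploid individuals sampled per replicate.
#' @param n_replicates Independent biological replicates pooled (default 1).
#' @param conf Confidence level (default 0.95).
#' @return Tibble `freq`, `n_individuals`, `n_replicates`, `x`, `n`,
#'   `lower`, `upper`.
#' @export
#' @examples
#' sampling_confidence_interval(0.5, n_individuals = 15) # (0.313, 0.687)
sampling_confidence_interval <- function(freq, n_individuals,
                                         n_replicates = 1, conf = 0.95) {
  assert_prob(freq, "freq")
  if (anyNA(freq)) abort("`freq` must not be missing")
  if (any(n_individuals < 1) || any(n_replicates < 1)) {
    abort("`n_individuals` and `n_replicates` must be positive integers")
  }
  if (conf <= 0 || conf >= 1) abort("`conf` must lie strictly in (0, 1)")
  len <- max(length(freq), length(n_individuals), length(n_replicates))
  freq <- rep_len(freq, len)
  n_individuals <- rep_len(n_individuals, len)
  n_replicates <- rep_len(n_replicates, len)
  n <- 2 * n_individuals * n_replicates
  x <- round_half_away(freq * n)
  a <- (1 - conf) / 2
  tibble(
    freq = freq, n_individuals = n_individuals, n_replicates = n_replicates,
    x = x, n = n,
    lower = ifelse(x == 0, 0, qbeta(a, x, n - x + 1)),
    upper = ifelse(x == n, 1, qbeta(1 - a, x + 1, n - x))
  )
}

#' Sampling-error table over a grid of frequencies and designs
#'
#' Evaluates [sampling_confidence_interval()] on the Cartesian product of
#' frequencies, individuals-per-bulk and replicate counts. The defaults
#' regenerate the published reference grid: frequencies
#' `{0, 0.03, 0.1, ..., 1}` by `{15, 100}` individuals by `{1, 2}`
#' replicates.
#'
#' @param freqs Allele-B frequencies.
#' @param n_individuals Individuals-per-bulk values.
#' @param n_replicates Replicate counts.
#' @param conf Confidence level.
#' @return Tibble, one row per grid combination, as in
#'   [sampling_confidence_interval()].
#' @export
sampling_table <- function(freqs = c(0, 0.03, seq(0.1, 1, by = 0.1)),
                           n_individuals = c(15, 100),
                           n_replicates = c(1, 2), conf = 0.95) {
  grid <- tidyr::expand_grid(freq = freqs, n_individuals = n_individuals,
                             n_replicates = n_replicates)
  sampling_confidence_interval(grid$freq, grid$n_individuals,
                               grid$n_replicates, conf = conf)
}
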