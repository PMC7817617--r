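#' Two-step allele-frequency estimation for DNA bulks
#'
#' The end-to-end estimator: for every quality-filtered SNP and every bulk,
#' first test allele fixation against the homozygous reference clusters
#' ([classify_fixation()]); bulks fixed for A get frequency 0 and bulks
#' fixed for B frequency 1, both with provenance `fixed_by_test`. Bulks
#' declared polymorphic get the calibration-curve prediction
#' ([predict_frequency()]), provenance `logistic`. Ambiguous or missing
#' observations yield a missing frequency. The fixation test runs before
#' prediction and the two estimates are never blended; this ordering is what
#' protects against false detection of polymorphism in nearly fixed bulks.
#'
#' @param bulk_fir Long tibble `snp_id`, `population_id`, `fir`.
#' @param stats Per-SNP cluster statistics ([cluster_stats()]).
#' @param fit Converged `pool_calibration` from [fit_calibration()].
#' @param kept_snps Optional character vector of SNP ids that passed the wd
#'   filter; defaults to all SNPs in `bulk_fir`.
#' @param alpha Nominal type-I level of each membership test.
#' @return Tibble `snp_id`, `population_id`, `fir`, `freq_b`, `source`
#'   (`fixed_by_test`, `logistic`, `ambiguous`, `missing`), `call`, `p_a`,
#'   `p_b`. SNPs lacking cluster statistics are skipped with one warning.
#' @export
estimate_frequencies <- function(bulk_fir, stats, fit, kept_snps = NULL,
                                 alpha = 0.05) {
  assert_columns(bulk_fir, c("snp_id", "population_id", "fir"), "bulk_fir")
  if (!inherits(fit, "pool_calibration") || !fit$converged) {
    abort("`fit` must be a converged pool_calibration")
  }
  if (!is.null(kept_snps)) {
    extra <- setdiff(kept_snps, bulk_fir$snp_id)
    if (length(extra) > 0) {
      abort("`kept_snps` contains SNPs absent from `bulk_fir`")
    }
    bulk_fir <- filter(bulk_fir, .data$snp_id %in% kept_snps)
  }
  no_stats <- setdiff(unique(bulk_fir$snp_id), stats$snp_id)
  if (length(no_stats) > 0) {
    warn(sprintf("%d SNP(s) lack cluster statistics and were skipped",
                 length(no_stats)))
  }
  calls <- classify_fixation(bulk_fir, stats, alpha = alpha)
  calls |>
    mutate(
      freq_b = case_when(
        .data$call == "fixed_A" ~ 0,
        .data$call == "fixed_B" ~ 1,
        .data$call == "polymorphic" ~ predict_frequency(fit, .data$fir),
        TRUE ~ NA_real_
      ),
      source = case_when(
        .data$call %in% c("fixed_A", "fixed_B") ~ "fixed_by_test",
        .data$call == "polymorphic" ~ "logistic",
        .data$call == "ambiguous" ~ "ambiguous",
        TRUE ~ "missing"
      )
    ) |>
    select("snp_id", "population_id", "fir", "freq_b", "source",
           "call", "p_a", "p_b")
}
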