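#' Single-observation Student membership test against a FIR cluster
#'
#' Tests whether one observed bulk FIR value could have been drawn from the
#' Gaussian FIR distribution of a homozygous reference cluster with
#' estimated mean `mu`, standard deviation `sd` and size `n`. The statistic
#' uses the prediction-interval form for a single new observation,
#' \eqn{t = (fir - \mu) / (\sigma\sqrt{1 + 1/n})}, referred to a Student t
#' with `n - 1` degrees of freedom, two-sided. Membership is declared when
#' the p-value is at least `alpha`.
#'
#' When `sd` is zero the Gaussian is degenerate and membership holds iff the
#' observation equals the mean exactly.
#'
#' @param fir_obs Observed FIR value(s) in `[0, 1]`.
#' @param mu,sd,n Cluster mean, standard deviation and line count (recycled).
#' @param alpha Nominal per-test type-I level (default 0.05).
#' @return Tibble with columns `t`, `p`, `member`.
#' @export
#' @examples
#' membership_test(0.16, mu = 0.10, sd = 0.02, n = 100)
membership_test <- function(fir_obs, mu, sd, n, alpha = 0.05) {
  len <- max(length(fir_obs), length(mu), length(sd), length(n))
  fir_obs <- rep_len(fir_obs, len); mu <- rep_len(mu, len)
  sd <- rep_len(sd, len); n <- rep_len(as.numeric(n), len)
  degen <- !is.na(sd) & sd == 0
  se <- sd * sqrt(1 + 1 / n)
  t_stat <- ifelse(degen, ifelse(fir_obs == mu, 0, Inf * sign(fir_obs - mu)),
                   (fir_obs - mu) / se)
  p <- ifelse(degen, as.numeric(fir_obs == mu),
              2 * pt(-abs(t_stat), df = n - 1))
  # the boundary case p == alpha is a member; tiny slack guards against
  # floating-point loss in p at the exact quantile
  tibble(t = t_stat, p = p, member = !is.na(p) & p >= alpha - 1e-12)
}

#' Classify allele fixation of a bulk at each SNP (step 1 of the estimator)
#'
#' For each (SNP, bulk) FIR observation, runs the membership test against
#' the AA cluster and against the BB cluster of the reference panel.
#' Membership in exactly one cluster declares the corresponding allele fixed
#' in the bulk; membership in neither declares the bulk polymorphic (to be
#' quantified by the calibration curve); membership in both is ambiguous
#' and yields no frequency.
#'
#' For SNPs monomorphic in the panel, the absent cluster is tested with the
#' assumed mean (0 for a missing AA cluster, 1 for a missing BB cluster)
#' together with the observed cluster's standard deviation and degrees of
#' freedom.
#'
#' @param bulk_fir Long tibble `snp_id`, `population_id`, `fir` of bulk FIR
#'   observations.
#' @param stats Per-SNP cluster statistics from [cluster_stats()]; only SNPs
#'   present in `stats` are classified.
#' @param alpha Nominal type-I level per membership test.
#' @return Tibble `snp_id`, `population_id`, `fir`, `call` (one of
#'   `fixed_A`, `fixed_B`, `polymorphic`, `ambiguous`, `missing`), `t_a`,
#'   `p_a`, `t_b`, `p_b`.
#' @export
classify_fixation <- function(bulk_fir, stats, alpha = 0.05) {
  assert_columns(bulk_fir, c("snp_id", "population_id", "fir"), "bulk_fir")
  data <- inner_join(bulk_fir, stats, by = "snp_id")
  # substitution for panel-monomorphic SNPs: assumed mean, observed side's
  # sd and df
  mu_a <- ifelse(data$n_aa == 0, 0, data$mu_aa)
  sd_a <- ifelse(data$n_aa == 0, data$sd_bb, data$sd_aa)
  n_a <- ifelse(data$n_aa == 0, data$n_bb, data$n_aa)
  mu_b <- ifelse(data$n_bb == 0, 1, data$mu_bb)
  sd_b <- ifelse(data$n_bb == 0, data$sd_aa, data$sd_bb)
  n_b <- ifelse(data$n_bb == 0, data$n_aa, data$n_bb)
  ta <- membership_test(data$fir, mu_a, sd_a, n_a, alpha)
  tb <- membership_test(data$fir, mu_b, sd_b, n_b, alpha)
  tibble(
    snp_id = data$snp_id,
    population_id = data$population_id,
    fir = data$fir,
    call = case_when(
      is.na(data$fir) ~ "missing",
      is.na(ta$p) | is.na(tb$p) ~ "ambiguous",
      ta$member & !tb$member ~ "fixed_A",
      tb$member & !ta$member ~ "fixed_B",
      !ta$member & !tb$member ~ "polymorphic",
      TRUE ~ "ambiguous"
    ),
    t_a = ta$t, p_a = ta$p, t_b = tb$t, p_b = tb$p
  )
}
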