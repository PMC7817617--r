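#' Homozygous-cluster FIR statistics per SNP
#'
#' For every SNP shared between the FIR table and the reference-panel
#' genotype calls, computes the mean, sample standard deviation (n-1
#' denominator) and count of the FIR values of lines called `AA` and of
#' lines called `BB`. Heterozygous (`AB`) and missing calls are excluded;
#' a cluster with a single observation keeps `sd = NA` (undefined).
#'
#' @param fir Long tibble `snp_id`, `sample_id`, `fir` (reference panel).
#' @param calls Long tibble `snp_id`, `sample_id`, `call` with calls in
#'   `AA`, `AB`, `BB`, `NA`.
#' @return A tibble with one row per SNP: `snp_id`, `mu_aa`, `sd_aa`, `n_aa`,
#'   `mu_bb`, `sd_bb`, `n_bb`.
#' @export
cluster_stats <- function(fir, calls) {
  assert_columns(fir, c("snp_id", "sample_id", "fir"), "fir")
  assert_columns(calls, c("snp_id", "sample_id", "call"), "calls")
  joined <- inner_join(fir, calls, by = c("snp_id", "sample_id"))
  if (nrow(joined) == 0) {
    abort("`fir` and `calls` share no (SNP, sample) combinations")
  }
  one_side <- function(data, geno) {
    data |>
      filter(.data$call == geno, !is.na(.data$fir)) |>
      group_by(.data$snp_id) |>
      summarise(mu = mean(.data$fir),
                sd = if (n() > 1) stats::sd(.data$fir) else NA_real_,
                n = n(), .groups = "drop")
  }
  aa <- one_side(joined, "AA")
  bb <- one_side(joined, "BB")
  tibble(snp_id = unique(joined$snp_id)) |>
    left_join(rename(aa, mu_aa = "mu", sd_aa = "sd", n_aa = "n"), by = "snp_id") |>
    left_join(rename(bb, mu_bb = "mu", sd_bb = "sd", n_bb = "n"), by = "snp_id") |>
    mutate(n_aa = ifelse(is.na(.data$n_aa), 0L, .data$n_aa),
           n_bb = ifelse(is.na(.data$n_bb), 0L, .data$n_bb))
}

#' Weighted-deviation (wd) SNP quality score
#'
#' The wd score ranks SNPs by the separation of their homozygous FIR
#' clusters:
#' \deqn{wd = \frac{|\mu_{AA} - \mu_{BB}|}{\sqrt{(N_{AA}\sigma_{AA}^2 +
#'   N_{BB}\sigma_{BB}^2)/(N_{AA}+N_{BB})}}}
#' SNPs monomorphic in the reference panel are scored with the assumed
#' values \eqn{\mu_{AA}=0,\sigma_{AA}=0} (no AA lines) or
#' \eqn{\mu_{BB}=1,\sigma_{BB}=0} (no BB lines), so that they are not
#' systematically discarded. A zero pooled deviation with distinct means
#' yields `wd = Inf`; wd is undefined (`NA`) when both clusters are empty,
#' when a non-empty cluster has a single observation (sd not estimable), or
#' when the means coincide with zero deviation.
#'
#' @param stats Tibble from [cluster_stats()].
#' @return `stats` with columns `wd` and `monomorphic_side`
#'   (`"none"`, `"AA_only"`, `"BB_only"`) appended.
#' @export
#' @examples
#' weighted_deviation(tibble::tibble(
#'   snp_id = "s1", mu_aa = 0.10, sd_aa = 0.02, n_aa = 50,
#'   mu_bb = 0.90, sd_bb = 0.03, n_bb = 50))
weighted_deviation <- function(stats) {
  assert_columns(stats, c("snp_id", "mu_aa", "sd_aa", "n_aa",
                          "mu_bb", "sd_bb", "n_bb"), "stats")
  stats |>
    mutate(
      monomorphic_side = case_when(
        .data$n_aa > 0 & .data$n_bb == 0 ~ "AA_only",
        .data$n_bb > 0 & .data$n_aa == 0 ~ "BB_only",
        TRUE ~ "none"
      ),
      .mu_aa = ifelse(.data$n_aa == 0, 0, .data$mu_aa),
      .sd_aa = ifelse(.data$n_aa == 0, 0, .data$sd_aa),
      .mu_bb = ifelse(.data$n_bb == 0, 1, .data$mu_bb),
      .sd_bb = ifelse(.data$n_bb == 0, 0, .data$sd_bb),
      .pooled = sqrt((.data$n_aa * .data$.sd_aa^2 + .data$n_bb * .data$.sd_bb^2) /
                       (.data$n_aa + .data$n_bb)),
      .delta = abs(.data$.mu_aa - .data$.mu_bb),
      wd = case_when(
        .data$n_aa + .data$n_bb == 0 ~ NA_real_,
        is.na(.data$.pooled) ~ NA_real_,
        .data$.pooled > 0 ~ .data$.delta / .data$.pooled,
        .data$.delta > 0 ~ Inf,
        TRUE ~ NA_real_
      )
    ) |>
    select(-dplyr::starts_with("."))
}

#' Filter SNPs on wd score and calibration-parent heterozygosity
#'
#' Keeps SNPs whose wd score is strictly above `threshold` (an infinite wd
#' passes; an undefined wd fails) and which are not heterozygous in any
#' parental line of the controlled pools.
#'
#' @param wd_scores Tibble with columns `snp_id` and `wd`, e.g. from
#'   [weighted_deviation()].
#' @param threshold Positive wd cutoff (default 50).
#' @param het_parent_snps Character vector of SNP ids heterozygous in at
#'   least one calibration parent; always removed.
#' @return Character vector of kept SNP ids (input order).
#' @export
filter_snps <- function(wd_scores, threshold = 50, het_parent_snps = character()) {
  assert_columns(wd_scores, c("snp_id", "wd"), "wd_scores")
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    abort("`threshold` must be a single positive number")
  }
  keep <- !is.na(wd_scores$wd) & wd_scores$wd > threshold &
    !(wd_scores$snp_id %in% het_parent_snps)
  wd_scores$snp_id[keep]
}
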