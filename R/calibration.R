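#' Canonical controlled-pool mixing design
#'
#' Nine controlled pools per parental trio, obtained by varying the
#' leaf-mass proportion of parent line L1 while L2 and L3 vary jointly.
#' Pool 9 mixes the three parents in exact thirds.
#'
#' @param series_id Optional identifier(s) of the parental trio; when given,
#'   the nine-pool design is replicated per series with a `series_id`
#'   column.
#' @return Tibble `pool_id`, `p1`, `p2`, `p3` (proportions summing to 1),
#'   optionally preceded by `series_id`.
#' @export
controlled_pool_design <- function(series_id = NULL) {
  base <- tibble(
    pool_id = paste0("pool", 1:9),
    p1 = c(0.01, 0.02, 0.03, 0.05, 0.07, 0.10, 0.15, 0.20, 1 / 3)
  ) |>
    mutate(p2 = (1 - .data$p1) / 2, p3 = .data$p2)
  if (is.null(series_id)) return(base)
  tidyr::expand_grid(series_id = series_id, base)
}

#' Expected allele-B frequency of a controlled pool
#'
#' The expected frequency is the leaf-mass-weighted sum of the parental
#' allele-B dosages: \eqn{f = \sum_i w_i d_i} with homozygous-parent dosages
#' \eqn{d_i \in \{0, 1\}}. Parents heterozygous at a SNP must be filtered
#' out upstream.
#'
#' @param genotypes Vector of parental allele-B dosages (0 = AA, 1 = BB).
#' @param proportions Leaf-mass proportions of the parents, same length,
#'   summing to 1 (within 1e-9).
#' @return Expected allele-B frequency in `[0, 1]`.
#' @export
#' @examples
#' expected_pool_frequency(c(1, 0, 1), c(0.15, 0.425, 0.425)) # 0.575
expected_pool_frequency <- function(genotypes, proportions) {
  if (length(genotypes) != length(proportions)) {
    abort("`genotypes` and `proportions` must have the same length")
  }
  if (!all(genotypes %in% c(0, 1))) {
    abort("parental dosages must be 0 or 1 (heterozygous parents must be pre-filtered)")
  }
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-9) {
    abort("`proportions` must be non-negative and sum to 1")
  }
  sum(proportions * genotypes)
}

#' Configuration class of a SNP within one controlled-pool series
#'
#' The three parental dosages determine which expected-frequency range the
#' nine pools span: `mono_A` (all 0) and `mono_B` (all 1) are monomorphic;
#' `R1` (1,0,0) spans 1-33%, `R2` ((0,0,1) or (0,1,0)) 33-50%, `R3` ((1,0,1)
#' or (1,1,0)) 51-67%, `R4` (0,1,1) 67-99%.
#'
#' @param g1,g2,g3 Parental allele-B dosages (vectors, recycled together).
#' @return Character vector of configuration classes.
#' @export
#' @examples
#' classify_configuration(1, 0, 0) # "R1"
classify_configuration <- function(g1, g2, g3) {
  len <- max(length(g1), length(g2), length(g3))
  g1 <- rep_len(g1, len); g2 <- rep_len(g2, len); g3 <- rep_len(g3, len)
  if (!all(c(g1, g2, g3) %in% c(0, 1))) {
    abort("parental dosages must be 0 or 1 (heterozygous parents must be pre-filtered)")
  }
  key <- paste0(g1, g2, g3)
  unname(c(`000` = "mono_A", `100` = "R1", `001` = "R2", `010` = "R2",
           `101` = "R3", `110` = "R3", `011` = "R4", `111` = "mono_B")[key])
}

#' Select the calibration SNP sample across configuration classes
#'
#' Draws `n_per_class` SNPs uniformly without replacement from each of the
#' four polymorphic configuration classes R1-R4. A SNP exhibiting different
#' classes in different series is assigned to a single class by the priority
#' order R1, R4, R2, R3, which favours SNPs covering the extreme frequency
#' ranges and so maximizes the frequency span of the calibration sample.
#' Candidates are shuffled from a lexicographically sorted id list so that a
#' given seed reproduces the selection exactly.
#'
#' @param configs Tibble `snp_id`, `series_id`, `configuration` (from
#'   [classify_configuration()] applied per series).
#' @param n_per_class SNPs drawn per class (default 250, i.e. 1000 total).
#' @param seed Optional integer seed for reproducible sampling.
#' @return Tibble `snp_id`, `configuration` with `4 * n_per_class` rows.
#' @export
select_calibration_snps <- function(configs, n_per_class = 250, seed = NULL) {
  assert_columns(configs, c("snp_id", "series_id", "configuration"), "configs")
  priority <- c("R1", "R4", "R2", "R3")
  assigned <- configs |>
    filter(.data$configuration %in% priority) |>
    distinct(.data$snp_id, .data$configuration) |>
    mutate(rank = match(.data$configuration, priority)) |>
    group_by(.data$snp_id) |>
    summarise(configuration = .data$configuration[which.min(.data$rank)],
              .groups = "drop")
  with_seed_maybe(seed, {
    picked <- lapply(priority, function(cl) {
      ids <- sort(assigned$snp_id[assigned$configuration == cl])
      if (length(ids) < n_per_class) {
        abort(sprintf("class %s has only %d eligible SNP(s); %d required",
                      cl, length(ids), n_per_class))
      }
      tibble(snp_id = sample(ids, n_per_class), configuration = cl)
    })
    bind_rows(picked)
  })
}

#' Fit the common logit-link calibration curve on controlled pools
#'
#' Fits \eqn{logit(f_B) = \alpha + \beta \cdot FIR} by quasi-binomial
#' maximum quasi-likelihood (iteratively reweighted least squares with
#' fractional responses and unit weights), pooling all calibration SNPs into
#' one curve. Convergence requires a relative deviance change below 1e-10
#' within 50 iterations.
#'
#' @param data Data frame holding the calibration observations.
#' @param fir,freq Columns of `data` (tidy-eval) with the observed FIR and
#'   the known expected allele-B frequency of each (SNP, pool) observation.
#' @return An object of class `pool_calibration` with elements `alpha`,
#'   `beta`, `n_obs`, `deviance`, `converged`, `iter` and the underlying
#'   `glm` fit. Supports [tidy()], [glance()], [predict()] and [autoplot()].
#' @export
#' @examples
#' d <- tibble::tibble(r = seq(0.05, 0.95, 0.05),
#'                     f = stats::plogis(-5 + 10 * r))
#' fit <- fit_calibration(d, fir = r, freq = f)
#' glance(fit)
fit_calibration <- function(data, fir = fir, freq = expected_freq) {
  fir_v <- rlang::eval_tidy(rlang::enquo(fir), data)
  freq_v <- rlang::eval_tidy(rlang::enquo(freq), data)
  if (length(fir_v) != length(freq_v) || length(fir_v) < 2) {
    abort("need at least two (FIR, frequency) observations of equal length")
  }
  if (anyNA(fir_v)) abort("`fir` must not contain missing values")
  assert_prob(freq_v, "freq")
  if (length(unique(freq_v)) < 2) {
    abort("all expected frequencies are identical; the slope is not identifiable")
  }
  df <- data.frame(.f = freq_v, .r = fir_v)
  fit <- suppressWarnings(glm(.f ~ .r, family = quasibinomial("logit"),
                              data = df,
                              control = glm.control(epsilon = 1e-10, maxit = 50)))
  structure(
    list(alpha = unname(coef(fit)[1]), beta = unname(coef(fit)[2]),
         n_obs = length(fir_v), deviance = fit$deviance,
         converged = isTRUE(fit$converged) && all(is.finite(coef(fit))),
         iter = fit$iter, model = fit),
    class = "pool_calibration"
  )
}

#' Predict allele-B frequency from FIR with a fitted calibration curve
#'
#' Applies the inverse-logit calibration \eqn{f_B = logit^{-1}(\alpha +
#' \beta \cdot FIR)}; predictions are strictly inside (0, 1) for finite FIR.
#'
#' @param fit A `pool_calibration` object from [fit_calibration()].
#' @param fir_obs FIR value(s).
#' @return Numeric vector of predicted allele-B frequencies.
#' @export
predict_frequency <- function(fit, fir_obs) {
  if (!inherits(fit, "pool_calibration")) abort("`fit` must be a pool_calibration")
  if (!fit$converged) abort("calibration fit did not converge")
  plogis(fit$alpha + fit$beta * fir_obs)
}

#' @export
predict.pool_calibration <- function(object, fir_obs, ...) {
  predict_frequency(object, fir_obs)
}

#' @export
print.pool_calibration <- function(x, ...) {
  cat("Pooled logit-link FIR calibration\n")
  cat(sprintf("  alpha = %.6g, beta = %.6g\n", x$alpha, x$beta))
  cat(sprintf("  n_obs = %d, deviance = %.6g, converged: %s (%d IRLS iterations)\n",
              x$n_obs, x$deviance, x$converged, x$iter))
  invisible(x)
}

#' @export
tidy.pool_calibration <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble(term = c("alpha", "beta"), estimate = c(x$alpha, x$beta),
         std.error = unname(s[, "Std. Error"]),
         statistic = unname(s[, "t value"]))
}

#' @export
glance.pool_calibration <- function(x, ...) {
  tibble(alpha = x$alpha, beta = x$beta, n_obs = x$n_obs,
         deviance = x$deviance, iter = x$iter, converged = x$converged)
}
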