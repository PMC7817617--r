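#' Mean absolute error of predicted allele frequencies
#'
#' Compares predicted and expected allele-B frequencies cell by cell
#' (matching on SNP and population, missing cells dropped pairwise) and
#' reports the mean absolute error, its standard deviation, and a breakdown
#' of MAE by expected-frequency bin.
#'
#' @param predicted,expected Data frames with columns `snp_id`,
#'   `population_id`, `freq_b`.
#' @param bins Breakpoints partitioning `[0, 1]` for the expected-frequency
#'   breakdown; default 21 equal bins.
#' @return An object of class `mae_report`: list with `mae`, `sd`,
#'   `n_cells` and a `breakdown` tibble (`bin`, `n`, `mae`).
#' @export
mean_absolute_error <- function(predicted, expected,
                                bins = seq(0, 1, length.out = 22)) {
  assert_columns(predicted, c("snp_id", "population_id", "freq_b"), "predicted")
  assert_columns(expected, c("snp_id", "population_id", "freq_b"), "expected")
  joined <- inner_join(
    rename(predicted, pred = "freq_b"),
    rename(select(expected, "snp_id", "population_id", "freq_b"), exp = "freq_b"),
    by = c("snp_id", "population_id")
  ) |>
    filter(!is.na(.data$pred), !is.na(.data$exp))
  if (nrow(joined) == 0) abort("no overlapping non-missing cells to compare")
  err <- abs(joined$pred - joined$exp)
  bin <- cut(joined$exp, breaks = bins, include.lowest = TRUE)
  breakdown <- tibble(bin = bin, err = err) |>
    group_by(.data$bin) |>
    summarise(n = n(), mae = mean(.data$err), .groups = "drop")
  structure(list(mae = mean(err), sd = stats::sd(err), n_cells = length(err),
                 breakdown = breakdown),
            class = "mae_report")
}

#' @export
print.mae_report <- function(x, ...) {
  cat(sprintf("MAE = %.4g (sd %.4g) over %d cells\n", x$mae, x$sd, x$n_cells))
  invisible(x)
}

#' @export
glance.mae_report <- function(x, ...) {
  tibble(mae = x$mae, sd = x$sd, n_cells = x$n_cells)
}

#' SNP k-fold cross-validation of the calibration curve
#'
#' Repeatedly splits the calibration SNPs into a training set (`train_n`
#' SNPs, on whose (FIR, expected frequency) pairs the curve is refitted) and
#' a disjoint validation set (`test_n` SNPs, whose pool observations are
#' predicted with the refitted curve), reporting the validation MAE per
#' repeat.
#'
#' @param data Calibration observations: tibble `snp_id`, `sample_id`,
#'   `fir`, `expected_freq`.
#' @param train_n,test_n Training / validation SNP counts (defaults 800 /
#'   200).
#' @param repeats Number of random splits (default 5).
#' @param seed Optional integer seed.
#' @param stats,alpha Optional cluster statistics; when supplied, validation
#'   predictions use the full two-step estimator (fixation test at level
#'   `alpha`, then prediction) instead of the curve alone.
#' @return Tibble `repeat_id`, `mae`, `sd`, `n_cells`.
#' @export
snp_kfold_cv <- function(data, train_n = 800, test_n = 200, repeats = 5,
                         seed = NULL, stats = NULL, alpha = 0.05) {
  assert_columns(data, c("snp_id", "sample_id", "fir", "expected_freq"), "data")
  snps <- unique(data$snp_id)
  if (train_n + test_n > length(snps)) {
    abort(sprintf("train_n + test_n = %d exceeds the %d available SNPs",
                  train_n + test_n, length(snps)))
  }
  with_seed_maybe(seed, {
    purrr::map_dfr(seq_len(repeats), function(r) {
      train <- sample(snps, train_n)
      test <- sample(setdiff(snps, train), test_n)
      fit <- fit_calibration(filter(data, .data$snp_id %in% train),
                             fir = fir, freq = expected_freq)
      held <- filter(data, .data$snp_id %in% test)
      pred <- cv_predict(held, fit, stats, alpha)
      rep <- mean_absolute_error(pred, cv_expected(held))
      tibble(repeat_id = r, mae = rep$mae, sd = rep$sd, n_cells = rep$n_cells)
    })
  })
}

#' Sample-removal cross-validation of the calibration curve
#'
#' Repeatedly removes `k_removed` controlled-pool samples at random from the
#' calibration set, refits the curve on the remaining samples, predicts the
#' removed samples' frequencies, and accumulates the absolute errors. This
#' measures how the accuracy of the common curve degrades as the calibration
#' design loses frequency coverage.
#'
#' @param data Calibration observations: tibble `snp_id`, `sample_id`,
#'   `fir`, `expected_freq`, and logical `is_pool` marking controlled-pool
#'   samples (parental-line samples, if present, always stay in the
#'   training set).
#' @param k_removed Number of pool samples removed per repeat (must be less
#'   than the number of pool samples).
#' @param repeats Number of repeats (default 1000).
#' @param seed Optional integer seed.
#' @inheritParams snp_kfold_cv
#' @return One-row tibble `k_removed`, `repeats`, `mean_mae`, `sd_mae`.
#' @export
sample_removal_cv <- function(data, k_removed, repeats = 1000, seed = NULL,
                              stats = NULL, alpha = 0.05) {
  assert_columns(data, c("snp_id", "sample_id", "fir", "expected_freq"), "data")
  if (!"is_pool" %in% names(data)) data$is_pool <- TRUE
  pool_samples <- unique(data$sample_id[data$is_pool])
  if (k_removed >= length(pool_samples)) {
    abort(sprintf("k_removed = %d must be below the %d pool samples",
                  k_removed, length(pool_samples)))
  }
  maes <- with_seed_maybe(seed, {
    purrr::map_dbl(seq_len(repeats), function(r) {
      if (k_removed == 0) {
        train <- data
        held <- filter(data, .data$is_pool)
      } else {
        removed <- sample(pool_samples, k_removed)
        train <- filter(data, !.data$sample_id %in% removed)
        held <- filter(data, .data$sample_id %in% removed)
      }
      fit <- fit_calibration(train, fir = fir, freq = expected_freq)
      pred <- cv_predict(held, fit, stats, alpha)
      mean_absolute_error(pred, cv_expected(held))$mae
    })
  })
  tibble(k_removed = k_removed, repeats = repeats,
         mean_mae = mean(maes), sd_mae = stats::sd(maes))
}

cv_expected <- function(held) {
  tibble(snp_id = held$snp_id, population_id = held$sample_id,
         freq_b = held$expected_freq)
}

cv_predict <- function(held, fit, stats, alpha) {
  if (is.null(stats)) {
    tibble(snp_id = held$snp_id, population_id = held$sample_id,
           freq_b = predict_frequency(fit, held$fir))
  } else {
    bulk <- tibble(snp_id = held$snp_id, population_id = held$sample_id,
                   fir = held$fir)
    select(estimate_frequencies(bulk, stats, fit, alpha = alpha),
           "snp_id", "population_id", "freq_b")
  }
}

#' Concordance of two biological replicates under sampling error alone
#'
#' For each SNP, with pooled point estimate `m = (f1 + f2) / 2`, the two
#' replicate frequencies are two independent binomial draws of
#' `2 * n_individuals` gametes each if only individual sampling acts. The
#' acceptance region for their difference is the normal approximation
#' `|f1 - f2| <= z * sqrt(2 m (1 - m) / (2 n_individuals))` with
#' `z = qnorm(1 - (1 - conf) / 2)`. Returns the fraction of SNPs whose pair
#' falls inside; values near `conf` indicate that bulk construction and
#' frequency estimation add little error beyond sampling.
#'
#' @param f1,f2 Equal-length vectors of replicate allele-B frequencies
#'   (pairs with a missing value are dropped).
#' @param n_individuals Individuals per bulk (default 15).
#' @param conf Confidence level of the region (default 0.95).
#' @return Fraction in `[0, 1]`.
#' @export
replicate_concordance <- function(f1, f2, n_individuals = 15, conf = 0.95) {
  if (length(f1) != length(f2)) abort("`f1` and `f2` must have the same length")
  ok <- !is.na(f1) & !is.na(f2)
  f1 <- f1[ok]; f2 <- f2[ok]
  m <- (f1 + f2) / 2
  gametes <- 2 * n_individuals
  half <- qnorm(1 - (1 - conf) / 2) * sqrt(2 * m * (1 - m) / gametes)
  mean(abs(f1 - f2) <= half + 1e-12)
}
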