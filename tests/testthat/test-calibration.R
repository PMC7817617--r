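test_that("the pool design has nine pools with proportions summing to one", {
  design <- controlled_pool_design()
  expect_equal(nrow(design), 9)
  expect_equal(design$p1 + design$p2 + design$p3, rep(1, 9), tolerance = 1e-12)
  expect_equal(design$p2, design$p3)
  two <- controlled_pool_design(series_id = c("flint", "tropical"))
  expect_equal(nrow(two), 18)
})

test_that("expected pool frequencies are mass-weighted parental dosages", {
  expect_equal(expected_pool_frequency(c(1, 0, 1), c(0.15, 0.425, 0.425)), 0.575)
  expect_equal(expected_pool_frequency(c(1, 0, 0), c(0.2, 0.4, 0.4)), 0.2)
  expect_equal(expected_pool_frequency(c(0, 0, 0), c(0.1, 0.45, 0.45)), 0)
  expect_error(expected_pool_frequency(c(1, 0), c(0.5, 0.4)), "sum to 1")
  expect_error(expected_pool_frequency(c(0.5, 0, 1), c(0.2, 0.4, 0.4)),
               "pre-filtered")
})

test_that("configuration classes follow the parental-genotype mapping", {
  expect_equal(classify_configuration(0, 0, 0), "mono_A")
  expect_equal(classify_configuration(1, 1, 1), "mono_B")
  expect_equal(classify_configuration(1, 0, 0), "R1")
  expect_equal(classify_configuration(c(0, 0), c(0, 1), c(1, 0)), c("R2", "R2"))
  expect_equal(classify_configuration(c(1, 1), c(0, 1), c(1, 0)), c("R3", "R3"))
  expect_equal(classify_configuration(0, 1, 1), "R4")
  expect_error(classify_configuration(0.5, 0, 1), "pre-filtered")
})

make_configs <- function(n_per_class = 30) {
  dosages <- list(R1 = c(1, 0, 0), R2 = c(0, 0, 1), R3 = c(1, 0, 1),
                  R4 = c(0, 1, 1))
  purrr::map_dfr(names(dosages), function(cl) {
    tibble::tibble(
      snp_id = sprintf("%s_%03d", cl, seq_len(n_per_class)),
      series_id = "series1",
      configuration = classify_configuration(dosages[[cl]][1], dosages[[cl]][2],
                                             dosages[[cl]][3])
    )
  })
}

test_that("calibration-SNP selection draws the requested class counts", {
  configs <- make_configs(30)
  sel <- select_calibration_snps(configs, n_per_class = 25, seed = 5)
  expect_equal(nrow(sel), 100)
  expect_equal(as.vector(table(sel$configuration)), rep(25L, 4))
  expect_equal(anyDuplicated(sel$snp_id), 0L)
  # deterministic under a seed, different under another
  sel2 <- select_calibration_snps(configs, n_per_class = 25, seed = 5)
  expect_identical(sel, sel2)
  sel3 <- select_calibration_snps(configs, n_per_class = 25, seed = 6)
  expect_false(identical(sel$snp_id, sel3$snp_id))
  expect_error(select_calibration_snps(configs, n_per_class = 31), "class R1")
})

test_that("dual-configuration SNPs land in exactly one class by priority", {
  configs <- dplyr::bind_rows(
    make_configs(30),
    tibble::tibble(snp_id = "R1_001", series_id = "series2",
                   configuration = "R4"),
    tibble::tibble(snp_id = "R2_001", series_id = "series2",
                   configuration = "R3")
  )
  sel <- select_calibration_snps(configs, n_per_class = 5, seed = 1)
  expect_equal(anyDuplicated(sel$snp_id), 0L)
  assigned <- select_calibration_snps(configs, n_per_class = 29, seed = 1)
  # R1 beats R4, R2 beats R3 in the priority order
  expect_false("R1_001" %in% assigned$snp_id[assigned$configuration == "R4"])
  expect_false("R2_001" %in% assigned$snp_id[assigned$configuration == "R3"])
})

test_that("a noise-free logistic relationship is recovered exactly", {
  grid <- tibble::tibble(fir = seq(0.02, 0.98, by = 0.02))
  grid$f <- plogis(-5 + 10 * grid$fir)
  fit <- fit_calibration(grid, fir = fir, freq = f)
  expect_true(fit$converged)
  expect_equal(fit$alpha, -5, tolerance = 1e-6)
  expect_equal(fit$beta, 10, tolerance = 1e-6)
  expect_lt(fit$deviance, 1e-12)
})

test_that("a two-point fit solves the logit equations in closed form", {
  d <- tibble::tibble(fir = c(0.2, 0.8), f = c(0.25, 0.75))
  fit <- fit_calibration(d, fir = fir, freq = f)
  beta <- (qlogis(0.75) - qlogis(0.25)) / 0.6
  expect_equal(fit$beta, beta, tolerance = 1e-6)
  expect_equal(fit$alpha, qlogis(0.25) - beta * 0.2, tolerance = 1e-6)
})

test_that("degenerate calibration designs are rejected", {
  flat <- tibble::tibble(fir = c(0.2, 0.5, 0.8), f = 0.4)
  expect_error(fit_calibration(flat, fir = fir, freq = f), "identifiable")
  expect_error(fit_calibration(tibble::tibble(fir = 0.5, f = 0.5),
                               fir = fir, freq = f), "at least two")
  withna <- tibble::tibble(fir = c(0.2, NA), f = c(0.2, 0.8))
  expect_error(fit_calibration(withna, fir = fir, freq = f), "missing")
})

test_that("fitting is equivariant under allele relabeling", {
  set.seed(3)
  d <- tibble::tibble(fir = runif(60, 0.05, 0.95))
  d$f <- pmin(pmax(plogis(-4.2 + 8.4 * d$fir) + rnorm(60, 0, 0.03),
                   0.001), 0.999)
  fwd <- fit_calibration(d, fir = fir, freq = f)
  rev <- fit_calibration(dplyr::transmute(d, fir = 1 - fir, f = 1 - f),
                         fir = fir, freq = f)
  expect_equal(rev$beta, fwd$beta, tolerance = 1e-8)
  expect_equal(rev$alpha, -fwd$alpha - fwd$beta, tolerance = 1e-8)
})

test_that("predictions are strictly inside (0,1) and increasing in FIR", {
  fir <- seq(0, 1, by = 0.01)
  pred <- predict_frequency(exact_fit, fir)
  expect_true(all(pred > 0 & pred < 1))
  expect_true(all(diff(pred) > 0))
  expect_equal(predict_frequency(exact_fit, -exact_fit$alpha / exact_fit$beta),
               0.5, tolerance = 1e-9)
  expect_equal(predict_frequency(exact_fit, 0.92), plogis(4.2), tolerance = 1e-6)
  expect_equal(plogis(4.2), 0.9852, tolerance = 1e-4)
})

test_that("tidiers expose the fit as tibbles", {
  expect_equal(tidy(exact_fit)$term, c("alpha", "beta"))
  g <- glance(exact_fit)
  expect_true(g$converged)
  expect_equal(g$n_obs, 19)
  expect_s3_class(autoplot(exact_fit), "ggplot")
})
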