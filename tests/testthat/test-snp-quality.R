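test_that("cluster statistics summarise homozygous FIR per SNP", {
  fir <- tibble::tibble(
    snp_id = "s1",
    sample_id = sprintf("l%d", 1:8),
    fir = c(0.08, 0.10, 0.12, 0.9, 0.5, NA, 0.91, 0.89)
  )
  calls <- tibble::tibble(
    snp_id = "s1", sample_id = sprintf("l%d", 1:8),
    call = c("AA", "AA", "AA", "BB", "AB", "AA", "BB", "BB")
  )
  cs <- cluster_stats(fir, calls)
  expect_equal(cs$mu_aa, 0.10)
  expect_equal(cs$sd_aa, 0.02)  # sample sd, n - 1 denominator
  expect_equal(cs$n_aa, 3L)
  expect_equal(cs$n_bb, 3L)
  expect_equal(cs$mu_bb, 0.9)
})

test_that("constant clusters and absent clusters are summarised correctly", {
  fir <- tibble::tibble(snp_id = "s1", sample_id = sprintf("l%d", 1:3),
                        fir = c(0.1, 0.1, 0.1))
  calls <- tibble::tibble(snp_id = "s1", sample_id = sprintf("l%d", 1:3),
                          call = "AA")
  cs <- cluster_stats(fir, calls)
  expect_equal(c(cs$mu_aa, cs$sd_aa, cs$n_aa), c(0.1, 0, 3))
  expect_equal(cs$n_bb, 0L)
  expect_error(
    cluster_stats(fir, dplyr::mutate(calls, sample_id = paste0("x", sample_id))),
    "no \\(SNP, sample\\)")
})

test_that("wd evaluates the pooled-deviation separation score", {
  wd <- weighted_deviation(make_stats(mu_aa = 0.10, sd_aa = 0.02, n_aa = 50,
                                      mu_bb = 0.90, sd_bb = 0.03, n_bb = 50))
  expect_equal(wd$wd, 0.8 / sqrt((50 * 4e-4 + 50 * 9e-4) / 100),
               tolerance = 1e-12)
  expect_equal(wd$monomorphic_side, "none")
})

test_that("panel-monomorphic SNPs are scored with the assumed fixed cluster", {
  bb_only <- weighted_deviation(make_stats(
    mu_aa = NA, sd_aa = NA, n_aa = 0, mu_bb = 0.95, sd_bb = 0.01, n_bb = 100))
  expect_equal(bb_only$wd, 0.95 / 0.01)
  expect_equal(bb_only$monomorphic_side, "BB_only")
  aa_only <- weighted_deviation(make_stats(
    mu_aa = 0.05, sd_aa = 0.01, n_aa = 100, mu_bb = NA, sd_bb = NA, n_bb = 0))
  expect_equal(aa_only$wd, 0.95 / 0.01)  # |0.05 - 1| / 0.01
  expect_equal(aa_only$monomorphic_side, "AA_only")
})

test_that("degenerate cluster configurations yield Inf or undefined wd", {
  zero_var <- weighted_deviation(make_stats(sd_aa = 0, sd_bb = 0))
  expect_identical(zero_var$wd, Inf)
  empty <- weighted_deviation(make_stats(mu_aa = NA, sd_aa = NA, n_aa = 0,
                                         mu_bb = NA, sd_bb = NA, n_bb = 0))
  expect_true(is.na(empty$wd))
  singleton <- weighted_deviation(make_stats(sd_aa = NA, n_aa = 1))
  expect_true(is.na(singleton$wd))
})

test_that("wd is scale-equivariant, shift-invariant and allele-symmetric", {
  base <- make_stats(sprintf("s%d", 1:20),
                     mu_aa = runif(20, 0.05, 0.2), sd_aa = runif(20, 0.01, 0.05),
                     n_aa = 30, mu_bb = runif(20, 0.8, 0.95),
                     sd_bb = runif(20, 0.01, 0.05), n_bb = 70)
  wd0 <- weighted_deviation(base)$wd
  halved <- dplyr::mutate(base, sd_aa = sd_aa / 2, sd_bb = sd_bb / 2)
  expect_equal(weighted_deviation(halved)$wd, 2 * wd0)
  shifted <- dplyr::mutate(base, mu_aa = mu_aa + 0.03, mu_bb = mu_bb + 0.03)
  expect_equal(weighted_deviation(shifted)$wd, wd0)
  relabeled <- tibble::tibble(snp_id = base$snp_id,
                              mu_aa = 1 - base$mu_bb, sd_aa = base$sd_bb,
                              n_aa = base$n_bb, mu_bb = 1 - base$mu_aa,
                              sd_bb = base$sd_aa, n_bb = base$n_aa)
  expect_equal(weighted_deviation(relabeled)$wd, wd0)
})

test_that("the wd filter applies strict threshold and parent-het removal", {
  wds <- tibble::tibble(snp_id = c("a", "b", "c", "d", "e"),
                        wd = c(49.9, 50.1, 80, Inf, NA))
  expect_equal(filter_snps(wds), c("b", "c", "d"))
  expect_equal(filter_snps(wds, het_parent_snps = "c"), c("b", "d"))
  expect_error(filter_snps(wds, threshold = -1), "positive")
})

test_that("filtering is monotone in the threshold", {
  wds <- tibble::tibble(snp_id = sprintf("s%d", 1:50),
                        wd = runif(50, 0, 120))
  kept <- lapply(c(20, 50, 80), function(th) filter_snps(wds, th))
  expect_true(all(kept[[2]] %in% kept[[1]]))
  expect_true(all(kept[[3]] %in% kept[[2]]))
})

test_that("a constructed panel splits exactly at the designed separation", {
  # 60 SNPs with tight, well-separated clusters; 40 with overlapping clusters
  good <- make_stats(sprintf("good%02d", 1:60), mu_aa = 0.1, sd_aa = 0.005,
                     n_aa = 50, mu_bb = 0.9, sd_bb = 0.005, n_bb = 50)
  bad <- make_stats(sprintf("bad%02d", 1:40), mu_aa = 0.45, sd_aa = 0.2,
                    n_aa = 50, mu_bb = 0.55, sd_bb = 0.2, n_bb = 50)
  kept <- filter_snps(weighted_deviation(dplyr::bind_rows(good, bad)))
  expect_setequal(kept, good$snp_id)
})
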