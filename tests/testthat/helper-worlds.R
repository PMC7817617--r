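# Shared fixtures, all generated in code.

zero_noise_model <- function() {
  signal_model(sd_aa = 0, sd_bb = 0, noise_sd = 0, mean_jitter_sd = 0)
}

# Small noise-free world reused by identity-style tests.
world0 <- simulate_world(n_snps = 80, n_lines = 40, n_pops = 4,
                         model = zero_noise_model(), seed = 101)
world0_stats <- cluster_stats(world0$panel_fir, world0$panel_calls)
world0_kept <- filter_snps(weighted_deviation(world0_stats), threshold = 30)
world0_fit <- fit_calibration(
  dplyr::filter(world0$calibration, is_pool, expected_freq > 0, expected_freq < 1),
  fir = fir, freq = expected_freq
)

# Small noisy world at the default signal model.
world1 <- simulate_world(n_snps = 120, n_lines = 60, n_pops = 5, seed = 202)
world1_stats <- cluster_stats(world1$panel_fir, world1$panel_calls)

# Cluster-stat row constructor for hand-built scenarios.
make_stats <- function(snp_id = "s1", mu_aa = 0.08, sd_aa = 0.01, n_aa = 100,
                       mu_bb = 0.92, sd_bb = 0.01, n_bb = 100) {
  tibble::tibble(snp_id = snp_id, mu_aa = mu_aa, sd_aa = sd_aa, n_aa = n_aa,
                 mu_bb = mu_bb, sd_bb = sd_bb, n_bb = n_bb)
}

# Exact calibration fit with alpha = -5, beta = 10 (noise-free grid).
exact_fit <- local({
  grid <- tibble::tibble(fir = seq(0.05, 0.95, by = 0.05))
  grid$f <- stats::plogis(-5 + 10 * grid$fir)
  fit_calibration(grid, fir = fir, freq = f)
})
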