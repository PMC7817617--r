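#' Signal model for synthetic FIR data
#'
#' Describes how allele-B frequency maps to observed FIR in the synthetic
#' worlds: homozygous clusters at `mu_aa` / `mu_bb` with spreads `sd_aa` /
#' `sd_bb` (per-SNP cluster means jittered by `mean_jitter_sd` to create wd
#' variation), and a true calibration curve `logit(f) = alpha + beta * FIR`
#' whose inverse generates the FIR of polymorphic bulks with Gaussian
#' measurement noise `noise_sd`. Bulks exactly fixed for an allele emit FIR
#' anchored at the corresponding cluster mean, so a noise-free world is an
#' exact fixed point of the two-step estimator.
#'
#' @param mu_aa,sd_aa FIR cluster for AA homozygotes (defaults 0.08, 0.02).
#' @param mu_bb,sd_bb FIR cluster for BB homozygotes (defaults 0.92, 0.02).
#' @param alpha,beta True calibration curve (defaults -5, 10; `beta > 0`).
#' @param noise_sd Bulk FIR measurement noise (default 0.02).
#' @param mean_jitter_sd Per-SNP jitter of the cluster means (default 0.01).
#' @return List of class `signal_model`.
#' @export
signal_model <- function(mu_aa = 0.08, sd_aa = 0.02, mu_bb = 0.92,
                         sd_bb = 0.02, alpha = -5, beta = 10,
                         noise_sd = 0.02, mean_jitter_sd = 0.01) {
  if (any(c(sd_aa, sd_bb, noise_sd, mean_jitter_sd) < 0)) {
    abort("standard deviations must be non-negative")
  }
  if (mu_aa >= mu_bb) abort("`mu_aa` must be below `mu_bb`")
  if (beta <= 0) abort("`beta` must be positive")
  structure(list(mu_aa = mu_aa, sd_aa = sd_aa, mu_bb = mu_bb, sd_bb = sd_bb,
                 alpha = alpha, beta = beta, noise_sd = noise_sd,
                 mean_jitter_sd = mean_jitter_sd),
            class = "signal_model")
}

# Forward model: FIR emitted for a bulk with allele-B frequency `freq` at
# SNPs with per-SNP cluster means mu_aa / mu_bb. Fixed frequencies anchor at
# the cluster means; interior frequencies invert the calibration curve.
fir_from_freq <- function(freq, model, mu_aa = model$mu_aa,
                          mu_bb = model$mu_bb) {
  len <- length(freq)
  mu_aa <- rep_len(mu_aa, len)
  mu_bb <- rep_len(mu_bb, len)
  noise <- rnorm(len, 0, model$noise_sd)
  signal <- ifelse(freq <= 0, mu_aa,
                   ifelse(freq >= 1, mu_bb,
                          (qlogis(freq) - model$alpha) / model$beta))
  clamp01(signal + noise)
}

#' Simulate a reference inbred-line panel
#'
#' Draws, per SNP, a minor-allele frequency and fully homozygous line
#' genotypes (AA/BB Bernoulli draws), then emits line FIR values from the
#' per-SNP homozygous clusters (means jittered by `mean_jitter_sd`, values
#' clamped to `[0, 1]`).
#'
#' @param n_snps,n_lines Panel dimensions (`n_lines >= 2`).
#' @param model A [signal_model()].
#' @param maf Either a function `n -> n frequencies` drawing per-SNP
#'   allele-B frequencies, or a numeric vector recycled over SNPs. Default
#'   uniform on `[0.05, 0.5]`.
#' @return List with tibbles `calls` (`snp_id`, `sample_id`, `call`), `fir`
#'   (`snp_id`, `sample_id`, `fir`) and `snp_params` (`snp_id`, `maf`,
#'   `mu_aa`, `mu_bb`).
#' @export
simulate_inbred_panel <- function(n_snps, n_lines, model = signal_model(),
                                  maf = function(n) runif(n, 0.05, 0.5)) {
  if (n_lines < 2) abort("`n_lines` must be at least 2")
  snp_ids <- sprintf("snp%05d", seq_len(n_snps))
  line_ids <- sprintf("line%04d", seq_len(n_lines))
  maf_v <- if (is.function(maf)) maf(n_snps) else rep_len(maf, n_snps)
  assert_prob(maf_v, "maf")
  snp_params <- tibble(
    snp_id = snp_ids, maf = maf_v,
    mu_aa = model$mu_aa + rnorm(n_snps, 0, model$mean_jitter_sd),
    mu_bb = model$mu_bb + rnorm(n_snps, 0, model$mean_jitter_sd)
  )
  grid <- tidyr::expand_grid(snp_id = snp_ids, sample_id = line_ids) |>
    left_join(snp_params, by = "snp_id") |>
    mutate(
      call = ifelse(runif(n()) < .data$maf, "BB", "AA"),
      fir = clamp01(ifelse(.data$call == "BB",
                           rnorm(n(), .data$mu_bb, model$sd_bb),
                           rnorm(n(), .data$mu_aa, model$sd_aa)))
    )
  list(calls = select(grid, "snp_id", "sample_id", "call"),
       fir = select(grid, "snp_id", "sample_id", "fir"),
       snp_params = snp_params)
}

#' Simulate controlled pools from parental genotypes and a mixing design
#'
#' For each SNP, series and pool, computes the expected allele-B frequency
#' (proportion-weighted parental dosages) and emits the observed pool FIR
#' through the forward signal model.
#'
#' @param parent_genotypes Tibble `snp_id`, `series_id`, `g1`, `g2`, `g3`
#'   with parental allele-B dosages in `{0, 1}`.
#' @param design Mixing design, see [controlled_pool_design()].
#' @param model A [signal_model()].
#' @param snp_params Optional per-SNP cluster means (tibble `snp_id`,
#'   `mu_aa`, `mu_bb`) from [simulate_inbred_panel()]; defaults to the
#'   model's global means.
#' @return Tibble `snp_id`, `series_id`, `pool_id`, `sample_id`,
#'   `expected_freq`, `fir`, `is_pool` (all `TRUE`).
#' @export
simulate_controlled_pools <- function(parent_genotypes,
                                      design = controlled_pool_design(),
                                      model = signal_model(),
                                      snp_params = NULL) {
  assert_columns(parent_genotypes, c("snp_id", "series_id", "g1", "g2", "g3"),
                 "parent_genotypes")
  if (!all(unlist(parent_genotypes[c("g1", "g2", "g3")]) %in% c(0, 1))) {
    abort("parental dosages must be 0 or 1")
  }
  out <- tidyr::expand_grid(parent_genotypes,
                            design[c("pool_id", "p1", "p2", "p3")]) |>
    mutate(
      expected_freq = .data$p1 * .data$g1 + .data$p2 * .data$g2 +
        .data$p3 * .data$g3,
      # proportion sums are float; snap monomorphic pools to exact 0 / 1
      expected_freq = case_when(abs(.data$expected_freq) < 1e-9 ~ 0,
                                abs(.data$expected_freq - 1) < 1e-9 ~ 1,
                                TRUE ~ .data$expected_freq),
      sample_id = paste(.data$series_id, .data$pool_id, sep = "_")
    )
  if (!is.null(snp_params)) {
    out <- left_join(out, snp_params[c("snp_id", "mu_aa", "mu_bb")],
                     by = "snp_id")
  } else {
    out$mu_aa <- model$mu_aa
    out$mu_bb <- model$mu_bb
  }
  out |>
    mutate(fir = fir_from_freq(.data$expected_freq, model,
                               mu_aa = .data$mu_aa, mu_bb = .data$mu_bb),
           is_pool = TRUE) |>
    select("snp_id", "series_id", "pool_id", "sample_id",
           "expected_freq", "fir", "is_pool")
}

#' Simulate a landrace DNA bulk with binomial gamete sampling
#'
#' A bulk of `n_individuals` diploid plants carries `2 * n_individuals`
#' gametes: the realized bulk frequency at each SNP is a binomial draw
#' `Binomial(2 n, f) / (2 n)` around the population frequency `f`, and the
#' observed FIR is emitted from the realized frequency through the forward
#' signal model.
#'
#' @param true_freqs Population allele-B frequencies (one per SNP).
#' @param n_individuals Plants per bulk (default 15).
#' @param model A [signal_model()].
#' @param snp_params Optional per-SNP cluster means (see
#'   [simulate_controlled_pools()]).
#' @param snp_ids Optional SNP identifiers (defaults to `snp00001`, ...).
#' @return Tibble `snp_id`, `true_freq`, `sampled_freq`, `fir`.
#' @export
simulate_landrace_bulk <- function(true_freqs, n_individuals = 15,
                                   model = signal_model(), snp_params = NULL,
                                   snp_ids = NULL) {
  assert_prob(true_freqs, "true_freqs")
  n_snps <- length(true_freqs)
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%05d", seq_len(n_snps))
  gametes <- 2 * n_individuals
  sampled <- rbinom(n_snps, gametes, true_freqs) / gametes
  if (!is.null(snp_params)) {
    mu <- snp_params[match(snp_ids, snp_params$snp_id), ]
    mu_aa <- mu$mu_aa; mu_bb <- mu$mu_bb
  } else {
    mu_aa <- model$mu_aa; mu_bb <- model$mu_bb
  }
  tibble(snp_id = snp_ids, true_freq = true_freqs, sampled_freq = sampled,
         fir = fir_from_freq(sampled, model, mu_aa = mu_aa, mu_bb = mu_bb))
}

#' Simulate a complete synthetic study
#'
#' Builds everything the two-step estimator consumes, with ground truth
#' retained: a homozygous reference panel, two series of parental trios and
#' their controlled pools (plus the six parental-line calibration samples),
#' and landrace bulks drawn by binomial gamete sampling from known
#' population frequencies (a `fixed_prop` share of population-SNP cells is
#' fixed, the rest uniform on `[0.05, 0.95]`).
#'
#' @param n_snps,n_lines,n_pops World dimensions.
#' @param n_individuals Plants per landrace bulk.
#' @param model A [signal_model()].
#' @param fixed_prop Expected share of fixed population-SNP cells (default
#'   0.5).
#' @param seed Optional integer seed; a given seed reproduces the world
#'   bit-identically.
#' @return List of class `synthetic_world` with elements `model`,
#'   `panel_calls`, `panel_fir`, `snp_params`, `parent_genotypes`,
#'   `calibration` (pools + parent samples: `snp_id`, `sample_id`, `fir`,
#'   `expected_freq`, `is_pool`), `true_freqs`, `sampled_freqs` and
#'   `bulk_fir` (long tibbles over SNPs x populations).
#' @export
simulate_world <- function(n_snps = 1000, n_lines = 100, n_pops = 10,
                           n_individuals = 15, model = signal_model(),
                           fixed_prop = 0.5, seed = NULL) {
  with_seed_maybe(seed, {
    panel <- simulate_inbred_panel(n_snps, n_lines, model)
    snp_ids <- panel$snp_params$snp_id
    parents <- tidyr::expand_grid(snp_id = snp_ids,
                                  series_id = c("series1", "series2")) |>
      mutate(g1 = rbinom(n(), 1, 0.5), g2 = rbinom(n(), 1, 0.5),
             g3 = rbinom(n(), 1, 0.5))
    pools <- simulate_controlled_pools(parents, model = model,
                                       snp_params = panel$snp_params)
    parent_samples <- parents |>
      tidyr::pivot_longer(c("g1", "g2", "g3"), names_to = "parent",
                          values_to = "expected_freq") |>
      mutate(sample_id = paste(.data$series_id, .data$parent, sep = "_")) |>
      left_join(panel$snp_params[c("snp_id", "mu_aa", "mu_bb")], by = "snp_id") |>
      mutate(fir = clamp01(rnorm(n(),
                                 ifelse(.data$expected_freq == 1,
                                        .data$mu_bb, .data$mu_aa),
                                 model$noise_sd)),
             is_pool = FALSE) |>
      select("snp_id", "sample_id", "fir", "expected_freq", "is_pool")
    calibration <- bind_rows(
      select(pools, "snp_id", "sample_id", "fir", "expected_freq", "is_pool"),
      parent_samples
    )
    pop_ids <- sprintf("pop%03d", seq_len(n_pops))
    true_freqs <- tidyr::expand_grid(snp_id = snp_ids,
                                     population_id = pop_ids) |>
      mutate(freq_b = ifelse(runif(n()) < fixed_prop,
                             as.numeric(runif(n()) < 0.5),
                             runif(n(), 0.05, 0.95)))
    bulks <- true_freqs |>
      group_by(.data$population_id) |>
      group_modify(function(rows, key) {
        b <- simulate_landrace_bulk(rows$freq_b, n_individuals, model,
                                    snp_params = panel$snp_params,
                                    snp_ids = rows$snp_id)
        tibble(snp_id = b$snp_id, sampled_freq = b$sampled_freq, fir = b$fir)
      }) |>
      ungroup()
    structure(list(
      model = model, n_individuals = n_individuals,
      panel_calls = panel$calls, panel_fir = panel$fir,
      snp_params = panel$snp_params, parent_genotypes = parents,
      calibration = calibration, true_freqs = true_freqs,
      sampled_freqs = select(bulks, "snp_id", "population_id", "sampled_freq"),
      bulk_fir = select(bulks, "snp_id", "population_id", "fir")
    ), class = "synthetic_world")
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "Synthetic allelotyping world: %d SNPs, %d panel lines, %d populations\n",
    n_distinct(x$snp_params$snp_id), n_distinct(x$panel_calls$sample_id),
    n_distinct(x$true_freqs$population_id)))
  invisible(x)
}
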