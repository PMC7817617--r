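#' Impute missing allele frequencies by the per-SNP mean
#'
#' Each missing cell is replaced by the mean frequency of that SNP over the
#' populations where it is observed. SNPs missing in every population cannot
#' be imputed and are dropped with a warning.
#'
#' @param freqs Long tibble `snp_id`, `population_id`, `freq_b`.
#' @return The imputed tibble (possibly with all-missing SNPs dropped).
#' @export
impute_missing_frequencies <- function(freqs) {
  assert_columns(freqs, c("snp_id", "population_id", "freq_b"), "freqs")
  out <- freqs |>
    group_by(.data$snp_id) |>
    mutate(.n_obs = sum(!is.na(.data$freq_b)),
           freq_b = ifelse(is.na(.data$freq_b),
                           mean(.data$freq_b, na.rm = TRUE), .data$freq_b)) |>
    ungroup()
  dropped <- sum(out$.n_obs == 0 & !duplicated(out$snp_id))
  if (dropped > 0) {
    warn(sprintf("%d SNP(s) missing in every population were dropped", dropped))
  }
  out |> filter(.data$.n_obs > 0) |> select(-".n_obs")
}

#' Average replicate bulks into one frequency profile per population
#'
#' Columns (samples) belonging to the same population are averaged cell-wise
#' with pairwise-complete handling: a SNP missing in one replicate takes the
#' other replicate's value. Samples listed in `excluded_samples` are dropped
#' before averaging.
#'
#' @param freqs Long tibble `snp_id`, `population_id`, `freq_b` where
#'   `population_id` holds sample-level bulk ids.
#' @param replicate_map Tibble `sample_id`, `population_id` mapping each
#'   bulk sample to its population.
#' @param excluded_samples Character vector of sample ids to drop.
#' @return Long tibble `snp_id`, `population_id`, `freq_b` at population
#'   level.
#' @export
merge_replicates <- function(freqs, replicate_map, excluded_samples = character()) {
  assert_columns(freqs, c("snp_id", "population_id", "freq_b"), "freqs")
  assert_columns(replicate_map, c("sample_id", "population_id"), "replicate_map")
  unknown <- setdiff(replicate_map$sample_id, unique(freqs$population_id))
  if (length(unknown) > 0) {
    abort(sprintf("replicate map references unknown sample(s): %s",
                  paste(head(unknown, 3), collapse = ", ")))
  }
  map <- filter(replicate_map, !.data$sample_id %in% excluded_samples)
  freqs |>
    rename(sample_id = "population_id") |>
    inner_join(map, by = "sample_id") |>
    group_by(.data$snp_id, .data$population_id) |>
    summarise(freq_b = if (all(is.na(.data$freq_b))) NA_real_
              else mean(.data$freq_b, na.rm = TRUE), .groups = "drop")
}

#' Modified Roger's Distance between two frequency profiles
#'
#' For biallelic loci, \eqn{MRD(p, q) = \sqrt{\frac{1}{m}\sum_l (p_l -
#' q_l)^2}} over the `m` loci, which equals the general allele-wise form
#' \eqn{\sqrt{\frac{1}{2m}\sum_l\sum_a (p_{la} - q_{la})^2}}. MRD is a
#' Euclidean metric scaled to `[0, 1]`.
#'
#' @param p,q Equal-length allele-B frequency vectors without missing values
#'   (impute first, see [impute_missing_frequencies()]).
#' @return Distance in `[0, 1]`.
#' @export
#' @examples
#' mrd(c(1, 0, 0.5, 0.5), c(0, 0, 0.5, 1))
mrd <- function(p, q) {
  if (length(p) != length(q)) abort("`p` and `q` must have the same length")
  if (length(p) == 0) abort("need at least one locus")
  if (anyNA(p) || anyNA(q)) abort("frequency vectors must not contain missing values")
  sqrt(mean((p - q)^2))
}

#' Pairwise Modified Roger's Distances between populations
#'
#' Computes the MRD between every pair of populations from a long
#' allele-frequency table, optionally over a fixed or seeded-random SNP
#' subset (supporting marker-number and wd-band subsetting experiments).
#' Cells still missing are handled pairwise-complete; each pair's distance
#' uses the loci observed in both populations.
#'
#' @param freqs Long tibble `snp_id`, `population_id`, `freq_b`.
#' @param snp_subset Optional character vector of SNP ids to use.
#' @param n_snps Optional number of SNPs to draw at random (after
#'   `snp_subset`, if both are given).
#' @param seed Optional integer seed for the random draw.
#' @return Object of class `mrd_matrix`: list with `d` (symmetric distance
#'   matrix, zero diagonal) and `m_used` (loci counts per pair). Supports
#'   `as.matrix()` and [tidy()].
#' @export
mrd_matrix <- function(freqs, snp_subset = NULL, n_snps = NULL, seed = NULL) {
  assert_columns(freqs, c("snp_id", "population_id", "freq_b"), "freqs")
  if (!is.null(snp_subset)) {
    freqs <- filter(freqs, .data$snp_id %in% snp_subset)
  }
  snps <- unique(freqs$snp_id)
  if (length(snps) == 0) abort("SNP subset is empty")
  if (!is.null(n_snps)) {
    if (n_snps > length(snps)) abort("`n_snps` exceeds the available SNPs")
    chosen <- with_seed_maybe(seed, sample(sort(snps), n_snps))
    freqs <- filter(freqs, .data$snp_id %in% chosen)
  }
  wide <- tidyr::pivot_wider(freqs, id_cols = "snp_id",
                             names_from = "population_id",
                             values_from = "freq_b")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  pops <- colnames(mat)
  k <- length(pops)
  d <- matrix(0, k, k, dimnames = list(pops, pops))
  m_used <- matrix(0L, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k)) {
    m_used[i, i] <- sum(!is.na(mat[, i]))
    for (j in seq_len(k)[-seq_len(i)]) {
      ok <- !is.na(mat[, i]) & !is.na(mat[, j])
      if (!any(ok)) abort(sprintf(
        "populations '%s' and '%s' share no observed loci", pops[i], pops[j]))
      d[i, j] <- d[j, i] <- mrd(mat[ok, i], mat[ok, j])
      m_used[i, j] <- m_used[j, i] <- sum(ok)
    }
  }
  structure(list(d = d, m_used = m_used), class = "mrd_matrix")
}

#' @export
as.matrix.mrd_matrix <- function(x, ...) x$d

#' @export
print.mrd_matrix <- function(x, ...) {
  cat(sprintf("Modified Roger's Distances, %d populations\n", ncol(x$d)))
  print(round(x$d, 4))
  invisible(x)
}

#' @export
tidy.mrd_matrix <- function(x, ...) {
  pops <- colnames(x$d)
  idx <- which(upper.tri(x$d), arr.ind = TRUE)
  tibble(pop1 = pops[idx[, 1]], pop2 = pops[idx[, 2]],
         mrd = x$d[idx], m_used = x$m_used[idx])
}
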