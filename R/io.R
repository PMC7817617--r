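#' Column-name dialect for GenomeStudio-style final reports
#'
#' Illumina final-report exports vary in their column labels. A dialect maps
#' the four required fields to the column names used in a particular export.
#'
#' @param snp,sample,x,y Column names carrying the SNP identifier, the sample
#'   identifier, and the normalized A-channel and B-channel intensities.
#' @return A named list usable as the `dialect` argument of
#'   [read_final_report()].
#' @export
#' @examples
#' final_report_dialect(x = "X Raw", y = "Y Raw")
final_report_dialect <- function(snp = "SNP Name", sample = "Sample ID",
                                 x = "X", y = "Y") {
  list(snp = snp, sample = sample, x = x, y = y)
}

#' Read per-SNP, per-sample two-channel intensities from a final report
#'
#' Parses a tab-delimited GenomeStudio-final-report-like file: an optional
#' `[Header]` block terminated by a `[Data]` line, followed by a header row
#' and one row per (SNP, sample) combination. Intensities that fail numeric
#' parsing become missing (`NA`); duplicated (SNP, sample) pairs are an
#' error.
#'
#' @param path Path to the tab-delimited report.
#' @param dialect Column-name map, see [final_report_dialect()].
#' @return A tibble with columns `snp_id`, `sample_id`, `x`, `y` (one row per
#'   data row, in file order).
#' @export
read_final_report <- function(path, dialect = final_report_dialect()) {
  lines <- readr::read_lines(path)
  data_at <- which(trimws(lines) == "[Data]")
  skip <- if (length(data_at) > 0) data_at[[1]] else 0L
  raw <- readr::read_tsv(
    I(lines), skip = skip, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  miss <- setdiff(unlist(dialect), names(raw))
  if (length(miss) > 0) {
    abort(sprintf("final report is missing required column(s): %s",
                  paste0("'", miss, "'", collapse = ", ")))
  }
  out <- tibble(
    snp_id = raw[[dialect$snp]],
    sample_id = raw[[dialect$sample]],
    x = suppressWarnings(as.numeric(raw[[dialect$x]])),
    y = suppressWarnings(as.numeric(raw[[dialect$y]]))
  )
  dup <- duplicated(out[c("snp_id", "sample_id")])
  if (any(dup)) {
    first <- out[which(dup)[1], ]
    abort(sprintf("duplicate (SNP, sample) record: ('%s', '%s')",
                  first$snp_id, first$sample_id))
  }
  out
}

#' Fluorescence intensity ratios from two-channel intensities
#'
#' The FIR of a spot is `y / (x + y)`, the B-channel share of total signal;
#' it is the quantitative measurement from which bulk allele frequencies are
#' estimated. Records with zero total signal (or a missing channel) yield a
#' missing FIR.
#'
#' @param intensities Data frame with columns `snp_id`, `sample_id`, `x`, `y`
#'   (non-negative intensities), e.g. from [read_final_report()].
#' @return A tibble `snp_id`, `sample_id`, `fir` with `fir` in `[0, 1]` or
#'   `NA`, rows in first-appearance order.
#' @export
#' @examples
#' build_fir(tibble::tibble(snp_id = "s1", sample_id = "b1", x = 0.2, y = 0.6))
build_fir <- function(intensities) {
  assert_columns(intensities, c("snp_id", "sample_id", "x", "y"), "intensities")
  if (nrow(intensities) == 0) abort("`intensities` must contain at least one record")
  bad <- with(intensities, (!is.na(x) & x < 0) | (!is.na(y) & y < 0))
  if (any(bad)) abort("channel intensities must be non-negative")
  intensities |>
    mutate(
      total = .data$x + .data$y,
      fir = dplyr::if_else(!is.na(.data$total) & .data$total > 0,
                           .data$y / .data$total, NA_real_)
    ) |>
    select("snp_id", "sample_id", "fir") |>
    as_tibble()
}

#' Write / read an allele-frequency table as wide TSV matrices
#'
#' `write_frequency_table()` writes SNP-by-population allele-B frequencies as
#' a TSV matrix (SNPs as rows, six-decimal fixed formatting, missing as
#' `NA`), plus a sibling `<stem>_source.tsv` carrying the per-cell provenance
#' codes (`fixed_by_test`, `logistic`, `ambiguous`, `missing`).
#' `read_frequency_table()` restores the long form.
#'
#' @param freqs Data frame with columns `snp_id`, `population_id`, `freq_b`
#'   and optionally `source`.
#' @param path Output TSV path.
#' @return `write_frequency_table()` returns `path` invisibly;
#'   `read_frequency_table()` returns the long tibble.
#' @export
write_frequency_table <- function(freqs, path) {
  assert_columns(freqs, c("snp_id", "population_id", "freq_b"), "freqs")
  assert_prob(freqs$freq_b, "freq_b")
  wide <- freqs |>
    mutate(freq_b = ifelse(is.na(.data$freq_b), NA_character_,
                           sprintf("%.6f", .data$freq_b))) |>
    tidyr::pivot_wider(id_cols = "snp_id", names_from = "population_id",
                       values_from = "freq_b")
  readr::write_tsv(wide, path, na = "NA", progress = FALSE)
  if ("source" %in% names(freqs)) {
    swide <- tidyr::pivot_wider(freqs, id_cols = "snp_id",
                                names_from = "population_id",
                                values_from = "source")
    readr::write_tsv(swide, source_sibling(path), na = "NA", progress = FALSE)
  }
  invisible(path)
}

#' @rdname write_frequency_table
#' @export
read_frequency_table <- function(path) {
  wide <- readr::read_tsv(path, col_types = readr::cols(
    snp_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE, show_col_types = FALSE)
  long <- tidyr::pivot_longer(wide, -"snp_id", names_to = "population_id",
                              values_to = "freq_b")
  spath <- source_sibling(path)
  if (file.exists(spath)) {
    swide <- readr::read_tsv(spath, col_types = readr::cols(
      .default = readr::col_character()
    ), progress = FALSE, show_col_types = FALSE)
    slong <- tidyr::pivot_longer(swide, -"snp_id", names_to = "population_id",
                                 values_to = "source")
    long <- left_join(long, slong, by = c("snp_id", "population_id"))
  }
  long
}

source_sibling <- function(path) {
  ext <- tools::file_ext(path)
  stem <- tools::file_path_sans_ext(path)
  if (nzchar(ext)) paste0(stem, "_source.", ext) else paste0(stem, "_source")
}
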