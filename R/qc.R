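# Sample-level quality control for mini-bulk conditions and the MCF7
# dose-panel samples.

#' Mini-bulk sample QC
#'
#' A condition passes when it has at least `min_reads` total mapped reads,
#' at least `min_exonic` of mapped reads exonic, and a signal-to-noise ratio
#' `p_c / p_e` strictly greater than `min_snr`. A zero error rate gives an
#' infinite SNR, which passes the SNR criterion. QC is monotone: improving
#' any metric never flips a pass to a fail.
#'
#' @param metrics Tibble with columns `sample_id`, `total_reads`,
#'   `exonic_fraction`, and either `p_c` and `p_e` columns or nothing if
#'   `rates` is supplied.
#' @param rates Optional tibble (`sample_id`, `p_c`, `p_e`) joined onto
#'   `metrics`, e.g. from [em_rates()] results.
#' @param min_reads,min_exonic,min_snr QC thresholds; defaults 200000 reads,
#'   45\% exonic, SNR > 10.
#' @return Tibble `sample_id`, `total_reads`, `exonic_fraction`, `snr`,
#'   `pass`, `reasons` (comma-separated failure reasons, `""` when passing).
#' @examples
#' qc_minibulk(tibble::tibble(sample_id = "s1", total_reads = 250000,
#'                            exonic_fraction = 0.5, p_c = 0.02, p_e = 0.001))
#' @export
qc_minibulk <- function(metrics, rates = NULL, min_reads = 2e5,
                        min_exonic = 0.45, min_snr = 10) {
  if (!is.null(rates)) {
    metrics <- dplyr::left_join(metrics, rates[c("sample_id", "p_c", "p_e")],
                                by = "sample_id")
  }
  req <- c("sample_id", "total_reads", "exonic_fraction", "p_c", "p_e")
  stopifnot(all(req %in% names(metrics)))
  metrics |>
    dplyr::mutate(snr = ifelse(.data$p_e > 0, .data$p_c / .data$p_e, Inf)) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      reasons = paste(c(
        if (.data$total_reads < min_reads) sprintf("reads < %d", as.integer(min_reads)),
        if (.data$exonic_fraction < min_exonic) sprintf("exonic < %d%%", round(100 * min_exonic)),
        if (!(.data$snr > min_snr)) sprintf("snr <= %g", min_snr)
      ), collapse = ", "),
      pass = !nzchar(.data$reasons)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "total_reads", "exonic_fraction", "snr",
                  "pass", "reasons")
}

#' MCF7 dose-panel sample QC
#'
#' A sample fails when its exonic fraction is below `min_exonic`, its total
#' read count below `min_reads`, or the median width of its per-gene
#' credible intervals is `max_ci_width` or greater. Drugs left with fewer
#' than `min_replicates` passing samples are dropped entirely (their
#' passing samples are marked excluded).
#'
#' @param metrics Tibble `sample_id`, `total_reads`, `exonic_fraction`.
#' @param pi_table Tibble of per-gene estimates with `sample_id` and
#'   `ci_width` columns (as returned by [estimate_pi()]); used for the
#'   median credible-interval width per sample.
#' @param samples Tibble `sample_id`, `drug_id` mapping samples to drugs.
#' @param min_exonic,min_reads,max_ci_width,min_replicates Thresholds;
#'   defaults 45\% exonic, 1e6 reads, CI width < 0.4, 3 replicates per drug.
#' @return Tibble `sample_id`, `drug_id`, `median_ci_width`, `pass`
#'   (sample-level), `kept` (after the drug-replicate rule), `reasons`.
#' @export
qc_mcf7 <- function(metrics, pi_table, samples, min_exonic = 0.45,
                    min_reads = 1e6, max_ci_width = 0.4, min_replicates = 3) {
  ciw <- pi_table |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(median_ci_width = median(.data$ci_width), .groups = "drop")
  out <- metrics |>
    dplyr::left_join(ciw, by = "sample_id") |>
    dplyr::left_join(samples, by = "sample_id") |>
    dplyr::rowwise() |>
    dplyr::mutate(
      reasons = paste(c(
        if (.data$exonic_fraction < min_exonic) sprintf("exonic < %d%%", round(100 * min_exonic)),
        if (.data$total_reads < min_reads) sprintf("reads < %g", min_reads),
        if (!is.na(.data$median_ci_width) && .data$median_ci_width >= max_ci_width)
          sprintf("ci width >= %g", max_ci_width)
      ), collapse = ", "),
      pass = !nzchar(.data$reasons)
    ) |>
    dplyr::ungroup()
  out <- out |>
    dplyr::group_by(.data$drug_id) |>
    dplyr::mutate(kept = .data$pass & sum(.data$pass) >= min_replicates) |>
    dplyr::ungroup() |>
    dplyr::mutate(reasons = ifelse(.data$pass & !.data$kept,
                                   sprintf("drug has < %d passing replicates", min_replicates),
                                   .data$reasons))
  dplyr::select(out, "sample_id", "drug_id", "median_ci_width", "pass",
                "kept", "reasons")
}
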