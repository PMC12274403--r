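# Single-cell molecule classification: binomial likelihood-ratio test of
# new (labeled) versus pre-existing for each stitched molecule.

#' Critical conversion count for the molecule-level test
#'
#' Smallest integer `k*` such that `P(K >= k* | K ~ Binomial(n, p_e)) <=
#' alpha`. Because the likelihood ratio of the alternative (conversion rate
#' `p_c > p_e`) to the null is monotone increasing in `k`, rejecting when
#' `k >= k*` is the non-randomized Neyman-Pearson test of size at most
#' `alpha`. For `n = 0` the threshold is defined as 1, which is
#' unreachable, so uninformative molecules are always called old.
#'
#' @param n Convertible positions per molecule (vectorized).
#' @param p_e Error probability under the null.
#' @param alpha Nominal test size (default 0.05).
#' @return Integer vector of critical counts.
#' @examples
#' critical_k(50, p_e = 0.001)  # 1: P(K >= 1) ~ 0.049
#' critical_k(50, p_e = 0.01)   # 3
#' @export
critical_k <- function(n, p_e, alpha = 0.05) {
  stopifnot(all(n >= 0), alpha > 0, alpha < 1)
  check_prob(p_e, "p_e")
  # smallest x with P(K > x) <= alpha, then k* = x + 1
  ks <- qbinom(alpha, n, p_e, lower.tail = FALSE) + 1L
  ks[n == 0] <- 1L
  as.integer(ks)
}

#' Classify molecules as new or pre-existing
#'
#' Applies the binomial likelihood-ratio test per molecule: a molecule with
#' `k` specific mismatches over `n` convertible positions is called new
#' exactly when `k >= critical_k(n, p_e, alpha)`. Deterministic given the
#' rates.
#'
#' @param molecules Tibble with columns `n`, `k` and any identifier columns
#'   (e.g. `cell_id`, `gene_id`, `molecule_id`), all preserved.
#' @param p_c Conversion probability of the alternative; must exceed `p_e`
#'   (fixes the rejection direction).
#' @param p_e Error probability under the null.
#' @param alpha Nominal size (default 0.05).
#' @return Input tibble with `critical_k` and `call` (`"new"`/`"old"`)
#'   appended.
#' @export
classify_molecules <- function(molecules, p_c, p_e, alpha = 0.05) {
  if (!(p_c > p_e)) stop("degenerate rates: need p_c > p_e", call. = FALSE)
  stopifnot(all(molecules$k <= molecules$n))
  kc <- critical_k(molecules$n, p_e, alpha)
  dplyr::mutate(molecules, critical_k = kc,
                call = ifelse(.data$k >= kc, "new", "old"))
}

#' Per-cell new-RNA fractions from molecule calls
#'
#' @param calls Tibble from [classify_molecules()] with columns `cell_id`,
#'   `call`.
#' @return Tibble `cell_id`, `n_molecules`, `n_new`, `new_fraction`.
#' @export
cell_new_fraction <- function(calls) {
  stopifnot(nrow(calls) >= 1)
  calls |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(n_molecules = dplyr::n(),
                     n_new = sum(.data$call == "new"),
                     new_fraction = .data$n_new / .data$n_molecules,
                     .groups = "drop")
}
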