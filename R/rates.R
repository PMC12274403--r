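# Per-sample conversion (p_c) and error (p_e) probability estimation:
# strand-based error-rate estimators plus an expectation-maximization fit
# of the two-component binomial mixture.

#' Estimate the error rate from opposite-strand conversions
#'
#' The specific conversion class (T>C on plus-strand genes, A>G on
#' minus-strand genes) cannot arise from 4sU on the opposite strand, so the
#' rate of T>C mismatches on minus-strand genes plus A>G mismatches on
#' plus-strand genes, over the matching convertible coverage, estimates the
#' library/sequencing error probability without 4sU-negative controls.
#'
#' @param profile Mismatch profile tibble (`gene_strand`, `ref`, `alt`,
#'   `mismatches`, `coverage`) as produced by [count_conversions()].
#' @return Error probability `p_e`.
#' @export
estimate_pe_opposite_strand <- function(profile) {
  hit <- (profile$gene_strand == "-" & profile$ref == "T" & profile$alt == "C") |
    (profile$gene_strand == "+" & profile$ref == "A" & profile$alt == "G")
  mm <- sum(profile$mismatches[hit])
  cov <- sum(profile$coverage[hit])
  if (cov == 0) stop("insufficient data for p_e: zero opposite-strand coverage",
                     call. = FALSE)
  mm / cov
}

#' Estimate the error rate from complementary mismatches
#'
#' The mean of the C>T and G>A mismatch rates (pooled over gene strands);
#' these classes mirror the conversion chemistry but cannot be produced by
#' it. Used as the single-cell default.
#'
#' @inheritParams estimate_pe_opposite_strand
#' @return Error probability `p_e`.
#' @export
estimate_pe_complementary <- function(profile) {
  rate_of <- function(ref, alt) {
    hit <- profile$ref == ref & profile$alt == alt
    mm <- sum(profile$mismatches[hit])
    cov <- sum(profile$coverage[hit])
    if (cov == 0) stop("insufficient data for p_e: zero ", ref, " coverage",
                       call. = FALSE)
    mm / cov
  }
  (rate_of("C", "T") + rate_of("G", "A")) / 2
}

#' EM estimate of the conversion probability and global new fraction
#'
#' Fits the two-component binomial mixture to all reads of one treatment:
#' a read converts at rate `p_e` (pre-existing) or `p_c + p_e` (labeled),
#' with mixing weight the global new fraction. `p_e` is fixed from a
#' strand-based estimator rather than re-estimated, which avoids
#' identifiability problems at low labeled fractions. The E-step computes
#' per-read responsibilities
#' `r_i = pi * B(k_i; n_i, p_c + p_e) / [pi * B(k_i; n_i, p_c + p_e) + (1 - pi) * B(k_i; n_i, p_e)]`;
#' the M-step sets `pi = mean(r_i)` and
#' `p_c = max(0, sum(r_i k_i) / sum(r_i n_i) - p_e)`. Iteration stops when
#' the log-likelihood improves by less than `tol`; the log-likelihood is
#' checked to be non-decreasing at every step.
#'
#' @param records Tibble of read records with columns `n`, `k`. Reads with
#'   `n = 0` are dropped before fitting.
#' @param p_e Fixed error probability.
#' @param init_pi Initial global new fraction (default 0.1).
#' @param init_pc Initial conversion probability; default
#'   `max(10 * p_e, pooled k/n among reads with k >= 2)` - reads with two
#'   or more mismatches are almost surely labeled at realistic error rates.
#' @param tol Convergence tolerance on the log-likelihood (default 1e-8).
#' @param max_iter Maximum EM iterations (default 1000).
#' @return An object of class `em_rates`: list with `p_c`, `p_e`, `pi_bar`,
#'   `snr`, `converged`, `iterations`, `loglik`, `loglik_trace`,
#'   `unidentifiable`, `n_reads`. `tidy()` and `glance()` methods apply.
#' @examples
#' reads <- simulate_reads(n_genes = 5, reads_per_gene = 2000, pi = 0.3,
#'                         p_c = 0.02, p_e = 0.001, seed = 1)
#' fit <- em_rates(reads, p_e = 0.001)
#' glance(fit)
#' @export
em_rates <- function(records, p_e, init_pi = 0.1, init_pc = NULL,
                     tol = 1e-8, max_iter = 1000) {
  check_prob(p_e, "p_e", allow_one = FALSE)
  records <- records[records$n >= 1, , drop = FALSE]
  if (nrow(records) == 0) stop("need at least one read with n >= 1", call. = FALSE)

  # collapse to unique (n, k) with weights: EM is invariant to read order
  # and scales with the number of distinct pairs, not reads
  tab <- dplyr::count(records, .data$n, .data$k, name = "w")
  n <- tab$n; k <- tab$k; w <- tab$w

  if (all(k == 0)) {
    return(structure(list(p_c = NA_real_, p_e = p_e, pi_bar = 0,
                          snr = NA_real_, converged = TRUE, iterations = 0L,
                          loglik = sum(w * dbinom(k, n, p_e, log = TRUE)),
                          loglik_trace = numeric(0), unidentifiable = TRUE,
                          n_reads = sum(w)),
                     class = "em_rates"))
  }

  if (is.null(init_pc)) {
    hi <- k >= 2
    pooled <- if (any(hi)) sum(w[hi] * k[hi]) / sum(w[hi] * n[hi]) else 0
    init_pc <- max(10 * p_e, pooled, 1e-4)
  }
  pc <- min(init_pc, 1 - p_e)
  pi_bar <- init_pi
  logB_e <- dbinom(k, n, p_e, log = TRUE)
  ll_of <- function(pc, pi_bar) {
    logB_c <- dbinom(k, n, min(pc + p_e, 1), log = TRUE)
    m <- pmax(logB_c, logB_e)
    sum(w * (m + log(pi_bar * exp(logB_c - m) + (1 - pi_bar) * exp(logB_e - m))))
  }
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    logB_c <- dbinom(k, n, min(pc + p_e, 1), log = TRUE)
    m <- pmax(logB_c, logB_e)
    num <- pi_bar * exp(logB_c - m)
    den <- num + (1 - pi_bar) * exp(logB_e - m)
    r <- ifelse(den > 0, num / den, 0)
    pi_bar <- sum(w * r) / sum(w)
    sr_n <- sum(w * r * n)
    pc <- if (sr_n > 0) max(0, sum(w * r * k) / sr_n - p_e) else 0
    ll <- ll_of(pc, pi_bar)
    if (ll < ll_old - 1e-9) {
      stop("EM log-likelihood decreased: ", ll_old, " -> ", ll, call. = FALSE)
    }
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  structure(list(p_c = pc, p_e = p_e, pi_bar = pi_bar,
                 snr = if (p_e > 0) pc / p_e else Inf,
                 converged = converged, iterations = it,
                 loglik = trace[length(trace)], loglik_trace = trace,
                 unidentifiable = FALSE, n_reads = sum(w)),
            class = "em_rates")
}

#' @export
print.em_rates <- function(x, ...) {
  cat("Binomial-mixture EM conversion-rate fit\n")
  cat(sprintf("  p_c = %.6g  p_e = %.6g  snr = %.3g\n", x$p_c, x$p_e, x$snr))
  cat(sprintf("  global new fraction = %.4g  (%d reads)\n", x$pi_bar, x$n_reads))
  cat(sprintf("  %s after %d iterations; log-likelihood %.4f\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$loglik))
  if (x$unidentifiable) cat("  flagged unidentifiable: no converted reads\n")
  invisible(x)
}

#' @rdname em_rates
#' @param x An `em_rates` object.
#' @param ... Unused.
#' @export
tidy.em_rates <- function(x, ...) {
  tibble(term = c("p_c", "p_e", "pi_bar"),
         estimate = c(x$p_c, x$p_e, x$pi_bar))
}

#' @rdname em_rates
#' @export
glance.em_rates <- function(x, ...) {
  tibble(p_c = x$p_c, p_e = x$p_e, snr = x$snr, pi_bar = x$pi_bar,
         logLik = x$loglik, iterations = x$iterations,
         converged = x$converged, unidentifiable = x$unidentifiable,
         n_reads = x$n_reads)
}
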