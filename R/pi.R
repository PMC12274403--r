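# Per-gene, per-sample posterior inference of the new-RNA fraction under
# the two-component binomial mixture: a deterministic grid oracle and a
# Monte-Carlo sampler that must agree with it.

#' Binomial mixture probability mass function
#'
#' The probability of observing `k` specific mismatches in a read with `n`
#' convertible positions when a fraction `pi` of the gene's reads are new:
#' `pi * B(k; n, p_c + p_e) + (1 - pi) * B(k; n, p_e)`, evaluated in log
#' space for stability.
#'
#' @param k,n Observed mismatch count and convertible positions (vectors).
#' @param pi New-RNA fraction in `[0, 1]` (scalar).
#' @param p_c,p_e Conversion and error probabilities.
#' @param log Return log probabilities?
#' @return Numeric vector of (log) probabilities.
#' @export
mixture_pmf <- function(k, n, pi, p_c, p_e, log = FALSE) {
  if (any(k < 0) || any(k > n)) stop("need 0 <= k <= n", call. = FALSE)
  check_prob(pi, "pi"); check_prob(p_c, "p_c"); check_prob(p_e, "p_e")
  if (p_c + p_e > 1) stop("p_c + p_e must not exceed 1", call. = FALSE)
  la <- dbinom(k, n, p_c + p_e, log = TRUE)
  lb <- dbinom(k, n, p_e, log = TRUE)
  m <- pmax(la, lb)
  out <- m + base::log(pi * exp(la - m) + (1 - pi) * exp(lb - m))
  out[!is.finite(m)] <- -Inf
  if (log) out else exp(out)
}

#' Joint log-likelihood of one gene's reads
#'
#' Sum of log mixture probabilities over the reads mapping to a gene, for
#' one or many proposed values of the new-RNA fraction.
#'
#' @param records Tibble with columns `n`, `k` (one row per read).
#' @param pi Proposed new-RNA fraction(s); vectorized.
#' @inheritParams mixture_pmf
#' @return Numeric vector, one log-likelihood per element of `pi`.
#' @export
pi_loglik <- function(records, pi, p_c, p_e) {
  if (nrow(records) == 0) stop("records must be nonempty", call. = FALSE)
  check_prob(pi, "pi")
  parts <- loglik_parts(records, p_c, p_e)
  vapply(pi, function(p) loglik_eval(parts, p), numeric(1))
}

# Collapse reads to unique (n, k) pairs and precompute the two component
# log-masses; the grid and the sampler both evaluate against this.
loglik_parts <- function(records, p_c, p_e) {
  check_prob(p_c, "p_c"); check_prob(p_e, "p_e")
  if (p_c + p_e > 1) stop("p_c + p_e must not exceed 1", call. = FALSE)
  tab <- dplyr::count(records, .data$n, .data$k, name = "w")
  la <- dbinom(tab$k, tab$n, p_c + p_e, log = TRUE)
  lb <- dbinom(tab$k, tab$n, p_e, log = TRUE)
  m <- pmax(la, lb)
  m[!is.finite(m)] <- 0
  list(w = tab$w, a = exp(la - m), b = exp(lb - m), m = m)
}

loglik_eval <- function(parts, pi) {
  sum(parts$w * (parts$m + base::log(pi * parts$a + (1 - pi) * parts$b)))
}

# Vectorized over a pi grid: pairs x grid outer products.
loglik_grid <- function(parts, grid) {
  mix <- parts$a %o% grid + parts$b %o% (1 - grid)
  colSums(parts$w * (parts$m + base::log(mix)))
}

#' Grid posterior for the new-RNA fraction (deterministic oracle)
#'
#' Evaluates the joint log-likelihood on a uniform grid over `[0, 1]`,
#' applies the uniform prior, normalizes with log-sum-exp, and returns the
#' posterior mean together with the equal-tailed credible interval obtained
#' from interpolated quantiles of the discrete posterior. Deterministic;
#' this backend serves as the oracle the Monte-Carlo backend is checked
#' against.
#'
#' @param records Tibble with columns `n`, `k`.
#' @param p_c,p_e Conversion and error probabilities.
#' @param grid_points Number of grid points (default 10001).
#' @param level Credibility level of the equal-tailed interval (default 0.95).
#' @return One-row tibble `pi_mean`, `ci_low`, `ci_high`, `ci_width`,
#'   `n_reads_used`, `backend`; the normalized posterior is attached as
#'   attribute `posterior` (tibble `pi`, `weight`).
#' @examples
#' reads <- tibble::tibble(n = rep(20, 5), k = c(0, 0, 0, 2, 0))
#' posterior_grid(reads, p_c = 0.05, p_e = 0.001)
#' @export
posterior_grid <- function(records, p_c, p_e, grid_points = 10001,
                           level = 0.95) {
  if (nrow(records) == 0) stop("records must be nonempty", call. = FALSE)
  parts <- loglik_parts(records, p_c, p_e)
  grid <- seq(0, 1, length.out = grid_points)
  ll <- loglik_grid(parts, grid)
  if (!any(is.finite(ll))) stop("likelihood is zero everywhere on the grid",
                                call. = FALSE)
  w <- exp(ll - max(ll[is.finite(ll)]))
  w <- w / sum(w)
  pi_mean <- sum(grid * w)
  cdf <- cumsum(w)
  alpha <- (1 - level) / 2
  qs <- interp_quantile(grid, cdf, c(alpha, 1 - alpha))
  out <- tibble(pi_mean = pi_mean, ci_low = qs[1], ci_high = qs[2],
                ci_width = qs[2] - qs[1], n_reads_used = sum(parts$w),
                backend = "grid")
  attr(out, "posterior") <- tibble(pi = grid, weight = w)
  out
}

# Interpolated quantiles of a discrete CDF on an ordered grid.
interp_quantile <- function(grid, cdf, probs) {
  vapply(probs, function(p) {
    i <- findInterval(p, cdf) + 1L
    if (i <= 1) return(grid[1])
    if (i > length(grid)) return(grid[length(grid)])
    c0 <- cdf[i - 1L]; c1 <- cdf[i]
    if (c1 <= c0) return(grid[i])
    grid[i - 1L] + (grid[i] - grid[i - 1L]) * (p - c0) / (c1 - c0)
  }, numeric(1))
}

#' Monte-Carlo posterior for the new-RNA fraction
#'
#' Samples the posterior of the new-RNA fraction under a uniform prior with
#' a random-walk Metropolis chain on the logit-transformed parameter (with
#' the Jacobian correction, so the uniform prior on `[0, 1]` is respected).
#' One chain, initial value 0.1, 1000 burn-in and 5000 kept iterations by
#' default; the proposal scale adapts toward a 0.44 acceptance rate during
#' burn-in only, so kept draws form a valid fixed-kernel chain. Returns the
#' sample mean and the empirical equal-tailed quantiles. The sampler's
#' contract is agreement with [posterior_grid()].
#'
#' @inheritParams posterior_grid
#' @param iterations Kept iterations after burn-in (default 5000).
#' @param burn_in Burn-in iterations (default 1000).
#' @param init Initial value of the new-RNA fraction (default 0.1).
#' @param seed Integer seed; fixed seed reproduces the chain exactly.
#' @return One-row tibble as [posterior_grid()] with `backend = "mcmc"`;
#'   kept draws attached as attribute `draws`.
#' @export
posterior_mcmc <- function(records, p_c, p_e, iterations = 5000,
                           burn_in = 1000, init = 0.1, level = 0.95,
                           seed = 1L) {
  if (nrow(records) == 0) stop("records must be nonempty", call. = FALSE)
  parts <- loglik_parts(records, p_c, p_e)
  logit <- function(p) base::log(p / (1 - p))
  inv_logit <- function(x) 1 / (1 + exp(-x))
  # log posterior density of theta = logit(pi): loglik + log|d pi / d theta|
  lp <- function(theta) {
    p <- inv_logit(theta)
    loglik_eval(parts, p) + base::log(p) + base::log1p(-p)
  }
  with_seed(seed, {
    theta <- logit(init)
    cur <- lp(theta)
    if (!is.finite(cur)) stop("chain failure: log-posterior not finite at init",
                              call. = FALSE)
    step <- 0.5
    total <- burn_in + iterations
    draws <- numeric(iterations)
    accepted <- 0L
    for (i in seq_len(total)) {
      prop <- theta + rnorm(1, 0, step)
      lp_prop <- lp(prop)
      if (is.finite(lp_prop) && base::log(runif(1)) < lp_prop - cur) {
        theta <- prop; cur <- lp_prop; accepted <- accepted + 1L
      }
      if (i <= burn_in) {
        # Robbins-Monro scale adaptation toward 0.44 acceptance, burn-in only
        acc <- accepted / i
        step <- exp(base::log(step) + (acc - 0.44) / sqrt(i))
      } else {
        draws[i - burn_in] <- inv_logit(theta)
      }
    }
    if (accepted == 0L) {
      stop("chain failure: no proposals accepted (step = ", signif(step, 3),
           ")", call. = FALSE)
    }
    alpha <- (1 - level) / 2
    qs <- unname(quantile(draws, c(alpha, 1 - alpha), type = 7))
    out <- tibble(pi_mean = mean(draws), ci_low = qs[1], ci_high = qs[2],
                  ci_width = qs[2] - qs[1], n_reads_used = sum(parts$w),
                  backend = "mcmc")
    attr(out, "draws") <- draws
    out
  })
}

#' Estimate per-gene, per-sample new-RNA fractions
#'
#' Applies, per `(sample_id, gene_id)` group: (1) downsampling to at most
#' `max_reads` reads, uniformly without replacement, with the RNG seeded
#' from `(seed, sample_id, gene_id)` so partial reruns reproduce the same
#' subsample; (2) the zero-conversion shortcut - when no read of the gene
#' carries a conversion, the fraction is reported as exactly zero without
#' running the posterior; (3) the chosen posterior backend otherwise.
#' Reads with `n = 0` are uninformative and excluded. Genes with zero reads
#' are absent from the output.
#'
#' @param records Tibble with columns `sample_id`, `gene_id`, `n`, `k`.
#' @param rates Either an [em_rates()] object or a list/tibble providing
#'   `p_c` and `p_e`.
#' @param backend `"grid"` (deterministic, default) or `"mcmc"`.
#' @param max_reads Downsampling cap (default 5000 reads).
#' @param level Credibility level (default 0.95).
#' @param seed Integer seed for downsampling and the MCMC backend.
#' @param ... Passed to the backend ([posterior_grid()] / [posterior_mcmc()]).
#' @return Tibble with one row per gene and sample: `sample_id`, `gene_id`,
#'   `pi_mean`, `ci_low`, `ci_high`, `ci_width`, `n_reads_used`,
#'   `downsampled`, `zero_shortcut`, `backend`.
#' @examples
#' reads <- simulate_reads(n_genes = 4, reads_per_gene = 500, pi = 0.2,
#'                         seed = 7)
#' estimate_pi(reads, list(p_c = 0.02, p_e = 0.001))
#' @export
estimate_pi <- function(records, rates, backend = c("grid", "mcmc"),
                        max_reads = 5000, level = 0.95, seed = 1L, ...) {
  backend <- match.arg(backend)
  p_c <- rates$p_c %||% rates[["p_c"]]
  p_e <- rates$p_e %||% rates[["p_e"]]
  records <- records[records$n >= 1, , drop = FALSE]
  if (nrow(records) == 0) {
    return(tibble(sample_id = character(), gene_id = character(),
                  pi_mean = double(), ci_low = double(), ci_high = double(),
                  ci_width = double(), n_reads_used = integer(),
                  downsampled = logical(), zero_shortcut = logical(),
                  backend = character()))
  }
  records |>
    dplyr::group_by(.data$sample_id, .data$gene_id) |>
    dplyr::group_modify(function(g, key) {
      downsampled <- nrow(g) > max_reads
      if (downsampled) {
        idx <- with_seed(derive_seed(seed, key$sample_id, key$gene_id),
                         sample.int(nrow(g), max_reads))
        g <- g[idx, , drop = FALSE]
      }
      if (!any(g$k >= 1)) {
        return(tibble(pi_mean = 0, ci_low = 0, ci_high = 0, ci_width = 0,
                      n_reads_used = nrow(g), downsampled = downsampled,
                      zero_shortcut = TRUE, backend = backend))
      }
      est <- if (backend == "grid") {
        posterior_grid(g, p_c, p_e, level = level, ...)
      } else {
        posterior_mcmc(g, p_c, p_e, level = level,
                       seed = derive_seed(seed, key$sample_id, key$gene_id, "mcmc"),
                       ...)
      }
      dplyr::mutate(est, downsampled = downsampled, zero_shortcut = FALSE,
                    .before = "backend")
    }) |>
    dplyr::ungroup()
}

#' Derive the new-RNA expression layer
#'
#' Multiplies total abundance by the estimated new fraction, per gene and
#' sample. Entries without a fraction estimate are treated as absent and
#' dropped.
#'
#' @param total Long expression tibble `gene_id`, `sample_id`, `value`.
#' @param pi_table Tibble from [estimate_pi()] (needs `sample_id`,
#'   `gene_id`, `pi_mean`).
#' @return Tibble `gene_id`, `sample_id`, `total`, `pi_mean`, `value` where
#'   `value` is the new-RNA abundance.
#' @export
new_expression <- function(total, pi_table) {
  dplyr::inner_join(
    dplyr::rename(total, total = "value"),
    pi_table[c("sample_id", "gene_id", "pi_mean")],
    by = c("gene_id", "sample_id")
  ) |>
    dplyr::mutate(value = .data$total * .data$pi_mean)
}
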