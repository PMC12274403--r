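#' Simulate per-read conversion counts under the binomial mixture model
#'
#' Generates read-level conversion records from the generative model that the
#' new-RNA fraction estimator assumes: each read covers `n` convertible
#' positions (T positions for plus-strand genes); with probability `pi` the
#' read derives from labeled (new) RNA and its conversion count is
#' `k ~ Binomial(n, p_c + p_e)`, otherwise `k ~ Binomial(n, p_e)`. The true
#' label of every read is retained so estimators can be scored against truth.
#'
#' @param n_genes Number of genes to simulate.
#' @param reads_per_gene Reads per gene; scalar or length-`n_genes` vector.
#' @param pi Per-gene new-RNA fraction; scalar (recycled) or length-`n_genes`
#'   vector in `[0, 1]`. Default draws each gene's fraction from Uniform(0,1).
#' @param p_c Conversion probability per convertible position on labeled
#'   reads (net of error; labeled reads convert at `p_c + p_e`).
#' @param p_e Sequencing/library error probability per convertible position,
#'   in `[0, 1)`.
#' @param n_range Inclusive integer range of convertible positions per read;
#'   `n` is drawn uniformly from it. Default `c(20, 200)` spans the
#'   T-content of realistic 100-150 bp reads.
#' @param sample_id Sample identifier stamped on every record.
#' @param seed Integer seed; fixed seed gives byte-identical output. The
#'   caller's RNG state is left untouched.
#'
#' @return A tibble with columns `sample_id`, `gene_id`, `read_id`, `n`, `k`,
#'   `true_label` (logical; `TRUE` = labeled/new) and `true_pi`.
#' @examples
#' reads <- simulate_reads(n_genes = 3, reads_per_gene = 100,
#'                         pi = c(0, 0.3, 1), seed = 1)
#' dplyr::count(reads, gene_id, true_label)
#' @export
simulate_reads <- function(n_genes = 10, reads_per_gene = 200, pi = NULL,
                           p_c = 0.02, p_e = 0.001,
                           n_range = c(20L, 200L),
                           sample_id = "sample1", seed = 1L) {
  stopifnot(n_genes >= 1, all(reads_per_gene >= 1))
  check_prob(p_c, "p_c")
  check_prob(p_e, "p_e", allow_one = FALSE)
  if (p_c + p_e > 1) stop("p_c + p_e must not exceed 1", call. = FALSE)
  if (length(n_range) != 2 || n_range[1] < 0 || n_range[2] < n_range[1]) {
    stop("`n_range` must be an increasing pair of non-negative integers",
         call. = FALSE)
  }
  reads_per_gene <- rep_len(as.integer(reads_per_gene), n_genes)
  with_seed(seed, {
    if (is.null(pi)) pi <- runif(n_genes)
    check_prob(pi, "pi")
    pi <- rep_len(pi, n_genes)
    gene_id <- sprintf("g%04d", seq_len(n_genes))
    total <- sum(reads_per_gene)
    gidx <- rep.int(seq_len(n_genes), reads_per_gene)
    n_vals <- seq.int(n_range[1], n_range[2])
    n <- n_vals[sample.int(length(n_vals), total, replace = TRUE)]
    labeled <- runif(total) < pi[gidx]
    rate <- ifelse(labeled, p_c + p_e, p_e)
    k <- rbinom(total, n, rate)
    tibble(
      sample_id = sample_id,
      gene_id = gene_id[gidx],
      read_id = sprintf("r%07d", seq_len(total)),
      n = as.integer(n),
      k = as.integer(k),
      true_label = labeled,
      true_pi = pi[gidx]
    )
  })
}

#' Simulate a mini-bulk compound screen expression matrix
#'
#' Fixture generator for the variance-adjusted differential-expression
#' pipeline: log2-scale expression for `n_genes` genes across compound-treated
#' replicates and a pool of DMSO controls, with a monotone mean-variance
#' trend and treatment effects injected into a subset of genes in treated
#' replicates only. The ground-truth effect table is returned alongside.
#'
#' Gene base means are Uniform(`base_mean_range`) on the log2 scale and the
#' per-gene noise standard deviation follows the monotone decreasing trend
#' `sd(mu) = 0.1 + 1.5 * exp(-mu / 3)`, emulating the higher relative noise
#' of lowly expressed genes.
#'
#' @param n_genes Number of genes.
#' @param n_compounds Number of treated compounds.
#' @param replicates Treated replicates per compound (>= 2).
#' @param n_controls Number of DMSO control samples (>= 2).
#' @param effects Optional tibble (`gene_id`, `compound_id`, `lfc`) of true
#'   log2 effects. When `NULL`, `prop_affected` of genes per compound get a
#'   shift of `effect_lfc` with random sign.
#' @param prop_affected Fraction of genes affected per compound when
#'   `effects` is `NULL`; `0` gives a global-null screen.
#' @param effect_lfc Magnitude of the injected log2 shift.
#' @param base_mean_range Range of log2 base means.
#' @param noise_sd Function mapping a log2 mean to the noise sd.
#' @param seed Integer seed.
#'
#' @return A list of class `minibulk_sim`: `expr` (long tibble `gene_id`,
#'   `sample_id`, `value` on log2 scale), `samples` (`sample_id`,
#'   `compound_id`, `role`), `truth` (true effects) and `genes`
#'   (`gene_id`, `base_mean`, `true_sd`).
#' @export
simulate_minibulk_screen <- function(n_genes = 2000, n_compounds = 1,
                                     replicates = 3, n_controls = 10,
                                     effects = NULL, prop_affected = 0.05,
                                     effect_lfc = 2,
                                     base_mean_range = c(2, 12),
                                     noise_sd = function(mu) 0.1 + 1.5 * exp(-mu / 3),
                                     seed = 1L) {
  stopifnot(replicates >= 2, n_controls >= 2, n_genes >= 1, n_compounds >= 0)
  with_seed(seed, {
    gene_id <- sprintf("g%05d", seq_len(n_genes))
    base_mean <- runif(n_genes, base_mean_range[1], base_mean_range[2])
    true_sd <- noise_sd(base_mean)
    compounds <- if (n_compounds > 0) sprintf("cmp%02d", seq_len(n_compounds)) else character()

    if (is.null(effects)) {
      n_aff <- floor(prop_affected * n_genes)
      effects <- purrr::map_dfr(compounds, function(cmp) {
        if (n_aff == 0) return(tibble(gene_id = character(), compound_id = character(), lfc = double()))
        idx <- sample.int(n_genes, n_aff)
        tibble(gene_id = gene_id[idx], compound_id = cmp,
               lfc = effect_lfc * sample(c(-1, 1), n_aff, replace = TRUE))
      })
    }

    samples <- dplyr::bind_rows(
      tibble(sample_id = sprintf("DMSO_%02d", seq_len(n_controls)),
             compound_id = "DMSO", role = "control"),
      purrr::map_dfr(compounds, function(cmp) {
        tibble(sample_id = sprintf("%s_rep%d", cmp, seq_len(replicates)),
               compound_id = cmp, role = "treated")
      })
    )

    expr <- tidyr::expand_grid(gene_id = gene_id, sample_id = samples$sample_id)
    expr <- dplyr::left_join(expr, samples, by = "sample_id")
    gi <- match(expr$gene_id, gene_id)
    expr$value <- rnorm(nrow(expr), mean = base_mean[gi], sd = true_sd[gi])
    if (nrow(effects) > 0) {
      expr <- dplyr::left_join(
        expr, dplyr::rename(effects, .lfc = "lfc"),
        by = c("gene_id", "compound_id")
      )
      expr$value <- expr$value + dplyr::coalesce(expr$.lfc, 0)
      expr$.lfc <- NULL
    }
    structure(
      list(
        expr = dplyr::select(expr, "gene_id", "sample_id", "value"),
        samples = samples,
        truth = as_tibble(effects),
        genes = tibble(gene_id = gene_id, base_mean = base_mean, true_sd = true_sd)
      ),
      class = "minibulk_sim"
    )
  })
}

#' Simulate labeled molecule counts under the telegraph model
#'
#' Exact stochastic (event-driven) simulation of the two-state promoter:
#' the promoter switches ON at rate `k_on` and OFF at rate `k_off`,
#' synthesizes transcripts at rate `k_syn` only while ON, and every
#' transcript degrades at rate `k_deg`. The labeled counter starts at 0 at
#' labeling onset and the promoter starts from its stationary
#' Bernoulli(`k_on / (k_on + k_off)`) occupancy; transcripts born during
#' `[0, t_label]` are labeled and may degrade before the end of the window.
#'
#' @param k_on,k_off Promoter switching rates (per hour), `>= 0`.
#' @param k_syn Synthesis rate in the ON state (per hour).
#' @param k_deg First-order degradation rate (per hour).
#' @param t_label Labeling duration in hours (> 0).
#' @param n_cells Number of independent cells to simulate.
#' @param seed Integer seed.
#'
#' @return A tibble with columns `cell_id` and `labeled` (molecule count at
#'   the end of the labeling window).
#' @examples
#' counts <- simulate_telegraph_labeled(k_on = 2, k_off = 100, k_syn = 400,
#'                                      k_deg = 0.065, t_label = 1,
#'                                      n_cells = 500, seed = 1)
#' mean(counts$labeled)
#' @export
simulate_telegraph_labeled <- function(k_on, k_off, k_syn, k_deg,
                                       t_label = 1, n_cells = 1000, seed = 1L) {
  rates <- c(k_on = k_on, k_off = k_off, k_syn = k_syn, k_deg = k_deg)
  if (anyNA(rates) || any(rates < 0)) stop("all rates must be >= 0", call. = FALSE)
  if (t_label <= 0) stop("t_label must be > 0", call. = FALSE)
  stopifnot(n_cells >= 1)
  counts <- with_seed(seed,
    telegraph_ssa(as.integer(n_cells), k_on, k_off, k_syn, k_deg, t_label)
  )
  tibble(cell_id = sprintf("c%06d", seq_len(n_cells)), labeled = counts)
}
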