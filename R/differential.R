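# Mini-bulk differential expression with variance adjustment and two-stage
# FDR; dose-response slope fitting and response clustering for drug panels.

#' Fit the expected-variance trend over expression level
#'
#' Regresses per-gene observed variance on per-gene mean expression, by
#' lowess (default, span 0.3) or ordinary least squares, and returns a
#' prediction function. The prediction is used as a variance floor in the
#' adjusted t-test: genes whose observed variance falls below the trend are
#' assigned the trend value, guarding against spuriously small variances at
#' few replicates.
#'
#' @param means Per-gene mean expression (log2 scale).
#' @param vars Per-gene observed variance.
#' @param method `"lowess"` (default) or `"linear"`.
#' @param span Lowess smoother span (default 0.3).
#' @return A function mapping mean expression to predicted variance
#'   (truncated below at 0; constant extrapolation outside the fitted
#'   range for lowess).
#' @export
variance_floor <- function(means, vars, method = c("lowess", "linear"),
                           span = 0.3) {
  method <- match.arg(method)
  stopifnot(length(means) == length(vars), length(means) >= 10)
  if (all(vars == 0)) stop("degenerate fit: all variances are zero", call. = FALSE)
  if (method == "lowess") {
    fit <- lowess(means, vars, f = span)
    f <- approxfun(fit$x, fit$y, rule = 2, ties = "ordered")
    function(m) pmax(0, f(m))
  } else {
    fit <- lm(vars ~ means)
    a <- coef(fit)[[1]]; b <- coef(fit)[[2]]
    function(m) pmax(0, a + b * m)
  }
}

#' Welch t-test with a variance floor
#'
#' Welch's unequal-variance t-test in which each group's variance is
#' replaced by `max(observed variance, floor(group mean))` before the
#' statistic and the Welch-Satterthwaite degrees of freedom are formed.
#' Flooring can only increase the variance, hence never inflates `|t|`.
#' When both floored variances are zero the statistic is defined as 0 with
#' p = 1.
#'
#' @param treated,control Numeric vectors (at least 2 values each).
#' @param floor_fn Function mapping a group mean to the minimum admissible
#'   variance; `NULL` disables flooring.
#' @return One-row tibble `mean_diff` (treated - control), `t_stat`, `df`,
#'   `p_value`, `floored_treated`, `floored_control`.
#' @export
adjusted_t_test <- function(treated, control, floor_fn = NULL) {
  if (length(treated) < 2 || length(control) < 2) {
    stop("need at least 2 values per group", call. = FALSE)
  }
  m1 <- mean(treated); m2 <- mean(control)
  v1 <- var(treated); v2 <- var(control)
  f1 <- f2 <- FALSE
  if (!is.null(floor_fn)) {
    fl1 <- floor_fn(m1); fl2 <- floor_fn(m2)
    if (v1 < fl1) { v1 <- fl1; f1 <- TRUE }
    if (v2 < fl2) { v2 <- fl2; f2 <- TRUE }
  }
  n1 <- length(treated); n2 <- length(control)
  se2 <- v1 / n1 + v2 / n2
  if (se2 <= 0) {
    return(tibble(mean_diff = m1 - m2, t_stat = 0, df = n1 + n2 - 2,
                  p_value = 1, floored_treated = f1, floored_control = f2))
  }
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  tibble(mean_diff = m1 - m2, t_stat = t_stat, df = df,
         p_value = 2 * pt(-abs(t_stat), df),
         floored_treated = f1, floored_control = f2)
}

#' Two-stage linear step-up false-discovery-rate adjustment
#'
#' The two-stage Benjamini-Krieger-Yekutieli procedure: a first
#' Benjamini-Hochberg pass at level `alpha / (1 + alpha)` estimates the
#' number of true null hypotheses `m0 = m - r1` from its rejection count
#' `r1`; the second pass applies the linear step-up procedure with the
#' level rescaled by `m0 / m`. Returned adjusted values are the standard BH
#' adjusted p-values multiplied by `m0 / m` (capped at 1), so
#' `q <= alpha` reproduces the two-stage rejection set.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param alpha Target FDR level used in the first stage (default 0.05).
#' @return Vector of adjusted values (`q`), same length and order as `p`.
#' @export
two_stage_fdr <- function(p, alpha = 0.05) {
  if (length(p) == 0) return(numeric(0))
  check_prob(p, "p")
  m <- length(p)
  adj <- p.adjust(p, method = "BH")
  r1 <- sum(adj <= alpha / (1 + alpha))
  m0 <- max(1L, m - r1)  # floor: never estimate zero true nulls
  pmin(1, adj * m0 / m)
}

#' Differential expression for one compound against sampled controls
#'
#' For one compound's three treated replicates, draws `n_controls` DMSO
#' control samples without replacement (seeded from `(seed, compound_id)`,
#' independently per compound), fits the mean-variance floor on the drawn
#' control pool across genes, runs the floored Welch t-test per gene, and
#' applies two-stage FDR across genes. Expression values are expected on
#' the log2 scale (e.g. `log2(CPM + 1)` of the new-RNA layer).
#'
#' @param expr Long expression tibble `gene_id`, `sample_id`, `value`
#'   (log2 scale).
#' @param treated_samples Character vector of the compound's replicate
#'   sample ids; the paper's design uses exactly 3, and compounds without 3
#'   replicates are skipped (empty result, with a warning).
#' @param control_pool Character vector of available DMSO sample ids
#'   (>= `n_controls`).
#' @param compound_id Compound identifier stamped on the result.
#' @param n_controls Number of controls drawn per test (default 10).
#' @param floor_method Passed to [variance_floor()].
#' @param seed Integer seed; the control draw is derived from
#'   `(seed, compound_id)`.
#' @return Tibble of class `newrna_de`: `gene_id`, `compound_id`,
#'   `mean_diff`, `t_stat`, `p_value`, `q_value`, `floored_treated`,
#'   `floored_control`; drawn control ids in attribute `controls`.
#' @export
de_compound <- function(expr, treated_samples, control_pool,
                        compound_id = "compound", n_controls = 10,
                        floor_method = "lowess", seed = 1L) {
  if (length(treated_samples) != 3) {
    warning("compound ", compound_id, " does not have exactly 3 replicates; skipped")
    out <- tibble(gene_id = character(), compound_id = character(),
                  mean_diff = double(), t_stat = double(), p_value = double(),
                  q_value = double(), floored_treated = logical(),
                  floored_control = logical())
    return(structure(out, class = c("newrna_de", class(out))))
  }
  stopifnot(length(control_pool) >= n_controls)
  controls <- with_seed(derive_seed(seed, compound_id),
                        sample(control_pool, n_controls))
  wide_t <- tidyr::pivot_wider(
    expr[expr$sample_id %in% treated_samples, ],
    names_from = "sample_id", values_from = "value") |>
    dplyr::arrange(.data$gene_id)
  wide_c <- tidyr::pivot_wider(
    expr[expr$sample_id %in% controls, ],
    names_from = "sample_id", values_from = "value") |>
    dplyr::arrange(.data$gene_id)
  stopifnot(identical(wide_t$gene_id, wide_c$gene_id))
  mt <- as.matrix(wide_t[-1]); mc <- as.matrix(wide_c[-1])

  ctrl_mean <- rowMeans(mc)
  ctrl_var <- apply(mc, 1, var)
  floor_fn <- variance_floor(ctrl_mean, ctrl_var, method = floor_method)

  res <- purrr::map_dfr(seq_len(nrow(mt)), function(i) {
    adjusted_t_test(mt[i, ], mc[i, ], floor_fn)
  })
  out <- dplyr::bind_cols(
    tibble(gene_id = wide_t$gene_id, compound_id = compound_id), res) |>
    dplyr::mutate(q_value = two_stage_fdr(.data$p_value), .after = "p_value") |>
    dplyr::select(-"df")
  attr(out, "controls") <- controls
  structure(out, class = c("newrna_de", class(out)))
}

#' log2 counts-per-million transform
#'
#' Standard `log2(CPM + 1)` normalization of a long count table, the
#' expression unit the differential tests operate on.
#' @param expr Long tibble `gene_id`, `sample_id`, `value` of non-negative
#'   abundances.
#' @return Same shape with `value` replaced by `log2(CPM + 1)`.
#' @export
normalize_log2_cpm <- function(expr) {
  expr |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(value = log2(.data$value / sum(.data$value) * 1e6 + 1)) |>
    dplyr::ungroup()
}

#' Dose-response slope per gene
#'
#' Least-squares regression of log2 new expression on log10 dose. Untreated
#' controls enter at a pseudo-dose one decade below the lowest treated dose
#' (0.1 nM for the 1 nM - 10 uM design). Genes with fewer than 3 distinct
#' dose levels are skipped. Two-stage FDR is applied across genes.
#'
#' @param expr Long tibble `gene_id`, `sample_id`, `value` (log2 scale).
#' @param doses Tibble `sample_id`, `dose_nm`; `NA` or 0 marks untreated
#'   controls.
#' @param drug_id Identifier stamped on the result.
#' @param pseudo_dose Dose assigned to controls; default one decade below
#'   the minimum treated dose.
#' @param alpha FDR level for the two-stage adjustment (default 0.05).
#' @return Tibble of class `newrna_dose`: `gene_id`, `drug_id`, `slope`
#'   (log2 expression change per decade of dose), `intercept`, `p_value`,
#'   `q_value`, `n_dose_levels`.
#' @export
dose_response_fit <- function(expr, doses, drug_id = "drug",
                              pseudo_dose = NULL, alpha = 0.05) {
  stopifnot(all(c("sample_id", "dose_nm") %in% names(doses)))
  d <- doses$dose_nm
  treated_doses <- unique(d[!is.na(d) & d > 0])
  if (is.null(pseudo_dose)) pseudo_dose <- min(treated_doses) / 10
  doses$dose_nm[is.na(d) | d == 0] <- pseudo_dose
  x <- dplyr::inner_join(expr, doses, by = "sample_id")
  out <- x |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(g, key) {
      lvls <- unique(g$dose_nm[g$dose_nm != pseudo_dose])
      if (length(lvls) < 3 || nrow(g) < 3) {
        return(tibble(slope = NA_real_, intercept = NA_real_,
                      p_value = NA_real_, n_dose_levels = length(lvls)))
      }
      fit <- lm(value ~ log10(dose_nm), data = g)
      s <- suppressWarnings(summary(fit))
      # a numerically perfect fit has no residual scale to test against
      p <- if (s$sigma < 1e-10 || is.na(s$coefficients[2, 4])) 1 else s$coefficients[2, 4]
      tibble(slope = coef(fit)[[2]], intercept = coef(fit)[[1]],
             p_value = p, n_dose_levels = length(lvls))
    }) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$slope)) |>
    dplyr::mutate(drug_id = drug_id, .after = "gene_id") |>
    dplyr::mutate(q_value = two_stage_fdr(.data$p_value, alpha),
                  .after = "p_value")
  structure(out, class = c("newrna_dose", class(out)))
}

#' Cluster drugs by correlation of dose-response slopes
#'
#' Pairwise Pearson correlation between the drugs' per-gene slope vectors,
#' distance `1 - r`, average-linkage agglomeration, and flat clusters cut
#' at distance `1 - r_cutoff` (default cutoff r = 0.33). Drugs with a
#' constant slope vector have undefined correlations and are excluded with
#' a warning.
#'
#' @param slopes Wide tibble/data frame with `gene_id` plus one numeric
#'   column per drug (e.g. pivoted from [dose_response_fit()] results), or
#'   a genes x drugs matrix.
#' @param r_cutoff Correlation cutoff defining flat clusters (default 0.33).
#' @return List of class `newrna_clusters`: `tree` (hclust), `clusters`
#'   (tibble `drug_id`, `cluster`), `correlation` (matrix), `excluded`.
#' @export
cluster_responses <- function(slopes, r_cutoff = 0.33) {
  m <- if (is.matrix(slopes)) slopes else as.matrix(slopes[setdiff(names(slopes), "gene_id")])
  if (ncol(m) < 2) stop("need at least 2 drugs", call. = FALSE)
  const <- apply(m, 2, function(x) sd(x, na.rm = TRUE) == 0 || all(is.na(x)))
  if (any(const)) {
    warning("excluding constant drug column(s): ",
            paste(colnames(m)[const], collapse = ", "))
    m <- m[, !const, drop = FALSE]
  }
  if (ncol(m) < 2) stop("fewer than 2 drugs with variation", call. = FALSE)
  r <- cor(m, use = "pairwise.complete.obs")
  tree <- hclust(as.dist(1 - r), method = "average")
  cl <- cutree(tree, h = 1 - r_cutoff)
  structure(list(tree = tree,
                 clusters = tibble(drug_id = names(cl), cluster = unname(cl)),
                 correlation = r,
                 excluded = colnames(slopes)[const %in% TRUE]),
            class = "newrna_clusters")
}
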