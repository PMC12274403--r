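test_that("variance floor recovers exact and constant trends", {
  means <- seq(1, 20, length.out = 50)
  vars <- 0.5 + 0.3 * means
  f_lin <- variance_floor(means, vars, method = "linear")
  expect_equal(f_lin(means), vars, tolerance = 1e-8)

  f_const <- variance_floor(means, rep(2, 50), method = "lowess")
  expect_equal(f_const(c(3, 10, 18)), rep(2, 3), tolerance = 1e-6)

  expect_error(variance_floor(means, rep(0, 50)), "degenerate")
  expect_error(variance_floor(1:5, 1:5), "10")
})

test_that("lowess floor tracks the generative mean-variance trend", {
  sim <- simulate_minibulk_screen(n_genes = 3000, n_compounds = 0,
                                  n_controls = 12, prop_affected = 0, seed = 42)
  wide <- tidyr::pivot_wider(sim$expr, names_from = "sample_id",
                             values_from = "value")
  m <- as.matrix(wide[-1])
  means <- rowMeans(m)
  vars <- apply(m, 1, var)
  floor_fn <- variance_floor(means, vars, method = "lowess")
  truth <- sim$genes$true_sd[match(wide$gene_id, sim$genes$gene_id)]^2
  central <- means > quantile(means, 0.1) & means < quantile(means, 0.9)
  rel_err <- abs(floor_fn(means[central]) - truth[central]) / truth[central]
  expect_lt(median(rel_err), 0.2)
  expect_lt(mean(rel_err > 0.2), 0.25)
})

test_that("adjusted t-test matches Welch when variances exceed the floor", {
  treated <- c(4, 5, 6)
  control <- rnorm(10, 2, 1) |> round(3)
  no_floor <- function(m) 0
  got <- adjusted_t_test(treated, control, no_floor)
  ref <- t.test(treated, control)
  expect_equal(got$t_stat, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(got$mean_diff, mean(treated) - mean(control))
})

test_that("flooring only lowers |t| and handles the degenerate constant case", {
  treated <- c(1.00, 1.01, 1.02)
  control <- c(0.50, 0.49, 0.51, 0.50)
  raw <- adjusted_t_test(treated, control, NULL)
  floored <- adjusted_t_test(treated, control, function(m) 0.5)
  expect_lt(abs(floored$t_stat), abs(raw$t_stat))
  expect_gt(floored$p_value, raw$p_value)
  # identical constant groups with a positive floor: t = 0, p = 1
  same <- adjusted_t_test(c(2, 2, 2), c(2, 2, 2), function(m) 0.1)
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)
  expect_error(adjusted_t_test(1, c(1, 2), NULL), "2 values")
})

test_that("two-stage FDR matches the hand-executed procedure", {
  p <- c(0.001, 0.01, 0.02, 0.8, 0.9)
  expect_equal(two_stage_fdr(p), two_stage_oracle(p), tolerance = 1e-12)
  # frozen hand computation: BH adj = (.005,.025,.0333,.9,.9), r1 = 3 at
  # alpha' = 0.0476 so m0 = 2, q = adj * 2/5
  expect_equal(two_stage_fdr(p), c(0.002, 0.01, 0.04 / 3, 0.36, 0.36),
               tolerance = 1e-10)
  expect_equal(two_stage_fdr(rep(1, 6)), rep(1, 6))
  expect_equal(two_stage_fdr(0.03), 0.03)
  expect_equal(two_stage_fdr(numeric(0)), numeric(0))
  for (seed in 1:5) {
    set.seed(seed)
    p <- runif(50)^2
    expect_equal(two_stage_fdr(p), two_stage_oracle(p), tolerance = 1e-12)
  }
})

test_that("compound DE finds a spiked gene and is seed-reproducible", {
  eff <- tibble::tibble(gene_id = "g00007", compound_id = "cmp01", lfc = 2)
  sim <- simulate_minibulk_screen(n_genes = 400, n_compounds = 1,
                                  n_controls = 12, effects = eff,
                                  noise_sd = function(mu) rep(0.1, length(mu)),
                                  seed = 9)
  treated <- sim$samples$sample_id[sim$samples$role == "treated"]
  pool <- sim$samples$sample_id[sim$samples$role == "control"]
  de <- de_compound(sim$expr, treated, pool, "cmp01", n_controls = 10, seed = 1)
  expect_equal(de$gene_id[which.min(de$p_value)], "g00007")
  expect_equal(abs(de$mean_diff[de$gene_id == "g00007"]), 2, tolerance = 0.3)

  de2 <- de_compound(sim$expr, treated, pool, "cmp01", n_controls = 10, seed = 1)
  expect_identical(attr(de, "controls"), attr(de2, "controls"))
  expect_equal(de$p_value, de2$p_value)
  # different compound id draws a different control set
  de3 <- de_compound(sim$expr, treated, pool, "other", n_controls = 10, seed = 1)
  expect_false(identical(attr(de, "controls"), attr(de3, "controls")))

  expect_warning(de_compound(sim$expr, treated[1:2], pool, "cmp01"),
                 "3 replicates")
})

test_that("DE q-values respect order and gene-order invariance", {
  sim <- simulate_minibulk_screen(n_genes = 300, n_compounds = 1,
                                  prop_affected = 0.1, seed = 13)
  treated <- sim$samples$sample_id[sim$samples$role == "treated"]
  pool <- sim$samples$sample_id[sim$samples$role == "control"]
  de <- de_compound(sim$expr, treated, pool, "cmp01", seed = 2)
  # q is a monotone transform of p within the family
  o <- order(de$p_value)
  expect_true(all(diff(de$q_value[o]) >= -1e-12))
  # permuting gene order changes nothing per gene
  shuf <- sim$expr[sample(nrow(sim$expr)), ]
  de_s <- de_compound(shuf, treated, pool, "cmp01", seed = 2)
  j <- dplyr::inner_join(de, de_s, by = "gene_id")
  expect_equal(j$p_value.x, j$p_value.y, tolerance = 1e-12)
})

test_that("dose-response fits recover flat and exactly linear responses", {
  doses <- tibble::tibble(
    sample_id = c(sprintf("d%d", 1:5), sprintf("c%d", 1:3)),
    dose_nm = c(1, 10, 100, 1000, 10000, NA, NA, NA)
  )
  flat <- tidyr::expand_grid(gene_id = "flat", sample_id = doses$sample_id)
  flat$value <- 5
  linear <- tidyr::expand_grid(gene_id = "lin", sample_id = doses$sample_id)
  linear$value <- log10(ifelse(is.na(doses$dose_nm[match(linear$sample_id,
                                                         doses$sample_id)]),
                               0.1, doses$dose_nm[match(linear$sample_id,
                                                        doses$sample_id)]))
  fit <- dose_response_fit(dplyr::bind_rows(flat, linear), doses)
  expect_equal(fit$slope[fit$gene_id == "flat"], 0, tolerance = 1e-12)
  expect_gt(fit$p_value[fit$gene_id == "flat"], 0.99)
  expect_equal(fit$slope[fit$gene_id == "lin"], 1, tolerance = 1e-10)
  # untreated controls enter one decade below the lowest dose
  expect_equal(fit$n_dose_levels[fit$gene_id == "lin"], 5)
})

test_that("dose-response slopes are unbiased on noisy linear data", {
  doses <- tibble::tibble(
    sample_id = c(sprintf("d%d", 1:5), sprintf("c%d", 1:3)),
    dose_nm = c(1, 10, 100, 1000, 10000, NA, NA, NA)
  )
  x <- log10(c(1, 10, 100, 1000, 10000, 0.1, 0.1, 0.1))
  slopes <- sapply(1:20, function(seed) {
    set.seed(seed)
    expr <- tibble::tibble(gene_id = "g", sample_id = doses$sample_id,
                           value = 2 + 0.5 * x + rnorm(8, 0, 0.2))
    dose_response_fit(expr, doses)$slope
  })
  se <- 0.2 / sqrt(sum((x - mean(x))^2)) / sqrt(20)
  expect_lt(abs(mean(slopes) - 0.5), 3 * se)
})

test_that("genes with fewer than 3 dose levels are skipped", {
  doses <- tibble::tibble(sample_id = c("d1", "d2", "c1"),
                          dose_nm = c(1, 10, NA))
  expr <- tibble::tibble(gene_id = "g", sample_id = doses$sample_id,
                         value = c(1, 2, 0))
  expect_equal(nrow(dose_response_fit(expr, doses)), 0L)
})

test_that("response clustering reproduces hand-computed average linkage", {
  # three drugs with known correlation structure
  set.seed(3)
  base <- rnorm(200)
  m <- cbind(A = base, B = base + rnorm(200, 0, 0.4), C = rnorm(200))
  r <- cor(m)
  tree <- cluster_responses(m, r_cutoff = 0.33)
  # hand agglomeration: A and B merge first at 1 - r(A,B); C joins at the
  # average of its distances to A and B
  h1 <- 1 - r["A", "B"]
  h2 <- mean(c(1 - r["A", "C"], 1 - r["B", "C"]))
  expect_equal(sort(tree$tree$height), sort(c(h1, h2)), tolerance = 1e-12)
  cl <- tree$clusters
  expect_equal(cl$cluster[cl$drug_id == "A"], cl$cluster[cl$drug_id == "B"])
  expect_false(cl$cluster[cl$drug_id == "C"] == cl$cluster[cl$drug_id == "A"])

  # identical columns merge at distance 0; anti-correlated never below cutoff
  m2 <- cbind(X = base, Y = base, Z = -base)
  t2 <- cluster_responses(m2)
  expect_equal(min(t2$tree$height), 0, tolerance = 1e-12)
  expect_equal(max(t2$tree$height), 2, tolerance = 1e-12)
  cl2 <- t2$clusters
  expect_equal(cl2$cluster[cl2$drug_id == "X"], cl2$cluster[cl2$drug_id == "Y"])
  expect_false(cl2$cluster[cl2$drug_id == "Z"] == cl2$cluster[cl2$drug_id == "X"])

  expect_warning(cluster_responses(cbind(A = base, B = base, K = rep(1, 200))),
                 "constant")
  expect_error(cluster_responses(cbind(A = base)), "2 drugs")
})
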