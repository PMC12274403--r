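test_that("promoter windows follow the strand-aware TSS arithmetic", {
  annot <- tibble::tibble(
    gene_id = c("plus", "minus", "edge"),
    chrom = "chr1",
    tss = c(10000, 10000, 500),
    strand = c("+", "-", "+")
  )
  w <- promoter_windows(annot)
  expect_equal(w$start[w$gene_id == "plus"], 9000)
  expect_equal(w$end[w$gene_id == "plus"], 10100)
  expect_equal(w$start[w$gene_id == "minus"], 9900)
  expect_equal(w$end[w$gene_id == "minus"], 11000)
  # complete windows have width 1100
  expect_equal(w$end[1:2] - w$start[1:2], c(1100, 1100))
  # truncation at the chromosome start
  expect_equal(w$start[w$gene_id == "edge"], 0)
  expect_error(promoter_windows(dplyr::mutate(annot, tss = c(0, 1, 1))), "positive")
})

test_that("overlap detection agrees with the brute-force all-pairs oracle", {
  set.seed(17)
  windows <- tibble::tibble(
    gene_id = sprintf("g%04d", 1:1000),
    chrom = sample(c("chr1", "chr2"), 1000, replace = TRUE),
    start = sample.int(100000, 1000)
  )
  windows$end <- windows$start + sample.int(2000, 1000)
  peaks <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 800, replace = TRUE),
    start = sample.int(100000, 800),
    factor_id = sample(c("f1", "f2"), 800, replace = TRUE)
  )
  peaks$end <- peaks$start + sample.int(500, 800, replace = TRUE)
  got <- peak_in_promoter(windows, peaks)
  oracle <- sapply(seq_len(nrow(got)), function(i) {
    w <- windows[windows$gene_id == got$gene_id[i], ]
    pk <- peaks[peaks$factor_id == got$factor_id[i] & peaks$chrom == w$chrom, ]
    any(pk$start < w$end & pk$end > w$start)
  })
  expect_equal(got$has_peak, oracle)
})

test_that("factor enrichment matches the hypergeometric enumeration oracle", {
  genes_up <- sprintf("u%03d", 1:100)
  genes_dn <- sprintf("d%03d", 1:100)
  pk <- tibble::tibble(
    gene_id = c(genes_up, genes_dn), factor_id = "fx",
    has_peak = c(rep(TRUE, 30), rep(FALSE, 70), rep(TRUE, 10), rep(FALSE, 90))
  )
  res <- factor_enrichment(genes_up, genes_dn, pk)
  expect_equal(res$fold_change, 3.0)
  expect_equal(res$p_value, fisher_oracle(30, 70, 10, 90), tolerance = 1e-10)

  # identical proportions: fold change 1, maximal two-sided p
  pk_null <- dplyr::mutate(pk, has_peak = rep(c(TRUE, FALSE), 100))
  res_null <- factor_enrichment(genes_up, genes_dn, pk_null)
  expect_equal(res_null$fold_change, 1)
  expect_gt(res_null$p_value, 0.99)
})

test_that("Fisher p agrees with enumeration across random tables", {
  set.seed(23)
  for (i in 1:25) {
    a <- sample(0:60, 1); b <- sample(0:140, 1)
    c_ <- sample(0:60, 1); d <- sample(0:140, 1)
    if (a + c_ == 0 || b + d == 0 || a + b == 0 || c_ + d == 0) next
    p_pkg <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
    expect_equal(p_pkg, fisher_oracle(a, b, c_, d), tolerance = 1e-10,
                 info = sprintf("(%d,%d,%d,%d)", a, b, c_, d))
  }
})

test_that("enrichment is label-symmetric and skips zero-margin factors", {
  up <- sprintf("u%02d", 1:50); dn <- sprintf("d%02d", 1:50)
  pk <- tibble::tibble(
    gene_id = rep(c(up, dn), 2),
    factor_id = rep(c("hit", "empty"), each = 100),
    has_peak = c(rep(c(TRUE, FALSE), c(20, 30)), rep(c(TRUE, FALSE), c(5, 45)),
                 rep(FALSE, 100))
  )
  fwd <- factor_enrichment(up, dn, pk)
  rev <- factor_enrichment(dn, up, pk)
  expect_equal(attr(fwd, "skipped"), "empty")
  expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-12)
  expect_equal(fwd$fold_change, 1 / rev$fold_change, tolerance = 1e-12)
})

test_that("region scheme builds promoter, gene body and downstream windows", {
  annot <- tibble::tibble(gene_id = c("p", "m"), chrom = "chr1",
                          tss = c(5000, 20000), tes = c(9000, 16000),
                          strand = c("+", "-"))
  reg <- gene_regions(annot)
  expect_setequal(unique(reg$region), c("promoter", "gene_body", "downstream"))
  gb_p <- reg[reg$gene_id == "p" & reg$region == "gene_body", ]
  expect_equal(gb_p$start, 5100); expect_equal(gb_p$end, 9000)
  ds_p <- reg[reg$gene_id == "p" & reg$region == "downstream", ]
  expect_equal(ds_p$start, 9000); expect_equal(ds_p$end, 10000)
  # minus strand mirrors in transcription direction
  gb_m <- reg[reg$gene_id == "m" & reg$region == "gene_body", ]
  expect_equal(gb_m$start, 15999); expect_equal(gb_m$end, 19900)

  pk <- tibble::tibble(chrom = "chr1", start = 5150, end = 5200,
                       factor_id = "mark")
  tab <- peak_in_promoter(reg, pk)
  hit <- tab[tab$gene_id == "p" & tab$region == "gene_body", ]
  expect_true(hit$has_peak)
  res <- region_enrichment("p", "m", tab)
  expect_true(all(c("region", "p_value", "q_value") %in% names(res)))
})

test_that("expression matching picks nearest unused neighbors by rank", {
  # universe of 40 genes; input = every other gene in rank order
  universe <- tibble::tibble(gene_id = sprintf("g%02d", 1:40),
                             mean_expr = 40:1)
  input <- universe$gene_id[seq(1, 40, by = 2)]
  m <- expression_matched_background(input, universe)
  expect_true(all(m$rank_diff == 1))
  expect_equal(sort(attr(m, "background")),
               sort(setdiff(universe$gene_id, input)))
  # matched background mean expression close to the input's
  bg_expr <- universe$mean_expr[universe$gene_id %in% attr(m, "background")]
  in_expr <- universe$mean_expr[universe$gene_id %in% input]
  expect_lt(abs(mean(bg_expr) - mean(in_expr)) / mean(in_expr), 0.05)
})

test_that("matching respects the rank-distance cap and the abort budget", {
  # an input gene isolated by > 100 ranks from any unused non-input gene
  universe <- tibble::tibble(gene_id = sprintf("g%03d", 1:300),
                             mean_expr = 300:1)
  input <- sprintf("g%03d", 1:110)  # genes 1..110 contiguous at the top
  m <- suppressWarnings(
    expression_matched_background(input, universe)
  )
  # deepest-ranked inputs can reach g111+... but the top ones cannot
  expect_true(anyNA(m$matched_gene_id))
  expect_true(isTRUE(attr(m, "aborted")) || mean(is.na(m$matched_gene_id)) <= 0.1 + 1e-9)

  expect_error(expression_matched_background(sprintf("g%03d", 1:200), universe),
               "twice")
})

test_that("matching quality holds on a realistic expression fixture", {
  set.seed(31)
  universe <- tibble::tibble(gene_id = sprintf("g%04d", 1:2000),
                             mean_expr = rlnorm(2000, 4, 1.5))
  input <- sample(universe$gene_id, 150)
  m <- expression_matched_background(input, universe)
  expect_false(isTRUE(attr(m, "aborted")))
  bg <- attr(m, "background")
  in_mean <- mean(universe$mean_expr[universe$gene_id %in% input])
  bg_mean <- mean(universe$mean_expr[universe$gene_id %in% bg])
  expect_lt(abs(bg_mean - in_mean) / in_mean, 0.05)
  expect_equal(anyDuplicated(bg), 0L)
  expect_length(intersect(bg, input), 0)
})

test_that("GO overrepresentation picks the right test branch per expected counts", {
  # large balanced counts: all expected > 10, chi-square branch
  study <- sprintf("s%03d", 1:60)
  bg <- sprintf("b%03d", 1:60)
  g2g_big <- tibble::tibble(
    gene_id = c(study[1:27], bg[1:15]),
    term_id = "GO:big"
  )
  res_big <- go_overrepresentation(study, bg, g2g_big)
  expect_equal(res_big$test, "chisq")
  ref <- chisq.test(matrix(c(27, 33, 15, 45), 2, byrow = TRUE),
                    correct = FALSE)$p.value
  expect_equal(res_big$p_value, ref, tolerance = 1e-12)

  # sparse term: Fisher branch, p equals the enumeration oracle
  g2g_small <- tibble::tibble(gene_id = c(study[1:5], bg[1]),
                              term_id = "GO:small")
  res_small <- go_overrepresentation(study, bg, g2g_small)
  expect_equal(res_small$test, "fisher")
  expect_equal(res_small$p_value, fisher_oracle(5, 55, 1, 59), tolerance = 1e-10)
})

test_that("GO universe drops obsolete terms and the self-comparison is null", {
  study <- sprintf("s%02d", 1:30)
  bg <- sprintf("b%02d", 1:30)
  g2g <- tibble::tibble(gene_id = c(study[1:10], bg[1:3]),
                        term_id = rep(c("GO:live", "GO:dead"), c(10, 3)))
  onto <- tibble::tibble(term_id = c("GO:live", "GO:dead"),
                         obsolete = c(FALSE, TRUE))
  res <- go_overrepresentation(study, bg, g2g, ontology = onto)
  expect_equal(res$term_id, "GO:live")

  # identical study and background composition: p = 1
  g2g_eq <- tibble::tibble(gene_id = c(study[1:8], bg[1:8]), term_id = "GO:t")
  res_eq <- go_overrepresentation(study, bg, g2g_eq)
  expect_gt(res_eq$p_value, 0.99)
})
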