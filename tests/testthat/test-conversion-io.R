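genes2 <- tibble::tibble(gene_id = c("gp", "gm"), strand = c("+", "-"))

test_that("conversion counting recovers constructed (n, k) from SAM", {
  # hand-constructed alignments: a clean 30-T read and a 40-T read with two
  # T>C substitutions, plus minus-strand mirrors
  recs <- tibble::tibble(
    read_id = c("r1", "r2", "r3"),
    gene_id = c("gp", "gp", "gm"),
    n = c(30L, 40L, 25L), k = c(0L, 2L, 3L)
  )
  sam <- tempfile(fileext = ".sam")
  write_read_sam(recs, genes2, sam)
  out <- count_conversions(sam, genes2)
  got <- dplyr::arrange(out$records, read_id)
  expect_equal(got$n, recs$n)
  expect_equal(got$k, recs$k)
  expect_equal(got$strand, c("+", "+", "-"))
})

test_that("SAM round trip recovers every simulated (n, k) and the profile books balance", {
  reads <- simulate_reads(n_genes = 2, reads_per_gene = 60, pi = 0.5,
                          p_c = 0.1, p_e = 0.01, n_range = c(10L, 80L),
                          seed = 21)
  reads$gene_id <- ifelse(reads$gene_id == "g0001", "gp", "gm")
  sam <- tempfile(fileext = ".sam")
  write_read_sam(reads, genes2, sam)
  out <- count_conversions(sam, genes2)
  merged <- dplyr::inner_join(reads, out$records,
                              by = "read_id", suffix = c("", ".got"))
  expect_equal(nrow(merged), nrow(reads))
  expect_equal(merged$n.got, merged$n)
  expect_equal(merged$k.got, merged$k)
  # mismatch count never exceeds coverage of its reference base
  expect_true(all(out$profile$mismatches <= out$profile$coverage))
  # T>C mismatches on plus-strand genes equal the summed k of those reads
  tc <- out$profile$mismatches[out$profile$gene_strand == "+" &
                                 out$profile$ref == "T" &
                                 out$profile$alt == "C"]
  expect_equal(tc, sum(reads$k[reads$gene_id == "gp"]))
})

test_that("counting is strand-consistent: flipping gene strand swaps the counted class", {
  recs <- tibble::tibble(read_id = sprintf("r%d", 1:10), gene_id = "gp",
                         n = rep(20L, 10), k = c(0:4, 0:4))
  sam <- tempfile(fileext = ".sam")
  write_read_sam(recs, genes2, sam)
  fwd <- count_conversions(sam, genes2)
  # same alignments, gene reannotated to the minus strand: T>C positions are
  # no longer the convertible class, so k drops to zero while the mismatch
  # mass moves to the opposite-strand stratum
  flipped <- tibble::tibble(gene_id = c("gp", "gm"), strand = c("-", "+"))
  rev <- count_conversions(sam, flipped)
  expect_equal(sum(fwd$records$k), 20L)
  expect_equal(sum(rev$records$k), 0L)
  tc_minus <- rev$profile$mismatches[rev$profile$gene_strand == "-" &
                                       rev$profile$ref == "T" &
                                       rev$profile$alt == "C"]
  expect_equal(tc_minus, 20)
})

test_that("reads with missing MD or unknown genes are skipped and counted", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chrS\tLN:100000",
    "ok\t0\tchrS\t1\t255\t4M\t*\t0\t0\tTTTT\tIIII\tMD:Z:4\tGE:Z:gp",
    "nomd\t0\tchrS\t1\t255\t4M\t*\t0\t0\tTTTT\tIIII\tGE:Z:gp",
    "nogene\t0\tchrS\t1\t255\t4M\t*\t0\t0\tTTTT\tIIII\tMD:Z:4\tGE:Z:mystery"
  ), sam)
  out <- count_conversions(sam, genes2)
  expect_equal(nrow(out$records), 1L)
  expect_equal(unname(out$skipped["missing_md"]), 1L)
  expect_equal(unname(out$skipped["unknown_gene"]), 1L)
})

test_that("low-quality bases and indel/clip positions are excluded from n and k", {
  sam <- tempfile(fileext = ".sam")
  # 6 T positions; position 2 is a T>C at quality 5 (below threshold),
  # position 4 a T>C at quality 40
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chrS\tLN:100000",
    paste0("q1\t0\tchrS\t1\t255\t6M\t*\t0\t0\tTCTCTT\t",
           "I&IIII", "\tMD:Z:1T1T2\tGE:Z:gp"),
    # soft clip + insertion: clipped TT and inserted CC touch no reference
    paste0("q2\t0\tchrS\t10\t255\t2S3M2I2M\t*\t0\t0\tTTTTTCCTT\t",
           "IIIIIIIII", "\tMD:Z:5\tGE:Z:gp"),
    # deletion of two reference T: not covered by the read
    paste0("q3\t0\tchrS\t30\t255\t3M2D3M\t*\t0\t0\tTTTTTT\t",
           "IIIIII", "\tMD:Z:3^TT3\tGE:Z:gp")
  ), sam)
  out <- count_conversions(sam, genes2, min_base_quality = 20)
  r <- dplyr::arrange(out$records, read_id)
  expect_equal(r$n[r$read_id == "q1"], 5L)  # low-qual position dropped
  expect_equal(r$k[r$read_id == "q1"], 1L)
  expect_equal(r$n[r$read_id == "q2"], 5L)  # clip/insertion excluded
  expect_equal(r$k[r$read_id == "q2"], 0L)
  expect_equal(r$n[r$read_id == "q3"], 6L)  # deleted refs not counted
})

test_that("tabular round trips are lossless and malformed input is rejected", {
  reads <- simulate_reads(n_genes = 3, reads_per_gene = 20, seed = 30)
  f <- tempfile(fileext = ".tsv")
  write_records_tsv(reads, f)
  expect_equal(as.data.frame(read_records_tsv(f)), as.data.frame(reads))

  expr <- simulate_minibulk_screen(n_genes = 40, seed = 31)$expr
  ft <- tempfile(fileext = ".tsv")
  write_expression_tsv(expr, ft)
  back <- read_expression_tsv(ft)
  expect_equal(dplyr::arrange(back, gene_id, sample_id),
               dplyr::arrange(expr, gene_id, sample_id), tolerance = 1e-12)

  fm <- tempfile(fileext = ".mtx")
  write_expression_mtx(expr, fm)
  backm <- read_expression_mtx(fm)
  expect_equal(dplyr::arrange(backm, gene_id, sample_id),
               dplyr::arrange(expr, gene_id, sample_id), tolerance = 1e-6)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgene_id\tn\tk", "s\tg\t5\t9"), bad)
  expect_error(read_records_tsv(bad), "line 2")
})

test_that("BED is parsed 0-based half-open and bad lines carry line numbers", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t999\t1100\tpkA"), f)
  bed <- read_bed(f)
  expect_equal(bed$start, 999)
  expect_equal(bed$end, 1100)
  # half-open: abuts a window ending at 999, overlaps one starting there
  w <- tibble::tibble(gene_id = c("a", "b"), chrom = "chr1",
                      start = c(899, 999), end = c(999, 1100))
  hits <- peak_in_promoter(w, dplyr::mutate(bed, factor_id = "pkA"))
  expect_equal(hits$has_peak[hits$gene_id == "a"], FALSE)
  expect_equal(hits$has_peak[hits$gene_id == "b"], TRUE)

  badf <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\t50\tx"), badf)
  expect_error(read_bed(badf), "line 2")
})

test_that("OBO parsing flags obsolete terms and GO tables read back", {
  f <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: mitochondrion inheritance", "",
    "[Term]", "id: GO:0000002", "name: obsolete thing", "is_obsolete: true", "",
    "[Typedef]", "id: part_of"
  ), f)
  obo <- read_obo(f)
  expect_equal(nrow(obo), 2L)
  expect_equal(obo$obsolete, c(FALSE, TRUE))

  g2g <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tterm_id", "g1\tGO:0000001", "g2\tGO:0000002"), g2g)
  expect_equal(nrow(read_gene2go(g2g)), 2L)
})
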