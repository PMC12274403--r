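# Conversion counting from aligned reads (SAM/BAM with MD tags) and the
# synthetic SAM fixture writer used to test it.

#' Count 4sU-specific conversions per read from aligned reads
#'
#' Walks the CIGAR and MD tag of every alignment to reconstruct, for each
#' covered reference position, the reference base, the read base and the base
#' quality. For a read assigned to a plus-strand gene, `n` is the number of
#' covered reference T positions and `k` the number of those read as C; for a
#' minus-strand gene the mirrored A-to-G class is counted (conversions on the
#' transcribed strand appear as A>G in reference coordinates). Positions in
#' insertions, deletions and soft clips are excluded, as are bases below the
#' quality threshold (excluded from both `n` and `k`). All 12 mismatch types
#' and the coverage of each reference base are accumulated into a mismatch
#' profile stratified by gene strand, from which the strand-based error-rate
#' estimators are computed.
#'
#' @param path Path to a BAM file, or a SAM text file (converted on the fly).
#' @param genes Tibble with columns `gene_id` and `strand` (`"+"`/`"-"`).
#' @param min_base_quality Minimum Phred base quality for a position to be
#'   counted (default 20, standard for conversion calling).
#' @param gene_tag Name of the per-read gene tag (default `"GE"`).
#' @param sample_id Sample identifier stamped on the records.
#'
#' @return A list of class `conversion_counts`: `records` (tibble
#'   `sample_id`, `gene_id`, `read_id`, `n`, `k`, `strand`), `profile`
#'   (mismatch profile tibble: `gene_strand`, `ref`, `alt`, `mismatches`,
#'   `coverage`), and `skipped` (named counts of reads skipped for missing
#'   MD tags or unknown genes).
#' @export
count_conversions <- function(path, genes, min_base_quality = 20,
                              gene_tag = "GE", sample_id = "sample1") {
  stopifnot(all(c("gene_id", "strand") %in% names(genes)))
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "cigar", "seq", "qual"),
    tag = c("MD", gene_tag)
  )
  b <- Rsamtools::scanBam(path, param = param)[[1]]
  md <- b$tag$MD
  ge <- b$tag[[gene_tag]]
  seqs <- as.character(b$seq)
  quals <- as(b$qual, "IntegerList")
  strand_of <- setNames(genes$strand, genes$gene_id)

  n_reads <- length(b$qname)
  skipped <- c(missing_md = 0L, unknown_gene = 0L, unmapped = 0L)
  recs <- vector("list", n_reads)
  # 12 mismatch types x 2 gene-strand strata
  bases <- c("A", "C", "G", "T")
  prof_mm <- array(0, dim = c(2, 4, 4), dimnames = list(c("+", "-"), bases, bases))
  prof_cov <- array(0, dim = c(2, 4), dimnames = list(c("+", "-"), bases))

  for (i in seq_len(n_reads)) {
    if (bitwAnd(b$flag[i], 4L) != 0L) { skipped["unmapped"] <- skipped["unmapped"] + 1L; next }
    if (is.na(md[i])) { skipped["missing_md"] <- skipped["missing_md"] + 1L; next }
    g <- ge[i]
    if (is.na(g) || !g %in% names(strand_of)) {
      skipped["unknown_gene"] <- skipped["unknown_gene"] + 1L; next
    }
    al <- alignment_bases(b$cigar[i], md[i], seqs[i], quals[[i]])
    al <- al[al$qual >= min_base_quality, , drop = FALSE]
    gs <- strand_of[[g]]
    si <- if (gs == "+") 1L else 2L
    for (rb in bases) {
      sel <- al$ref == rb
      prof_cov[si, rb] <- prof_cov[si, rb] + sum(sel)
      if (any(sel)) {
        mm <- al$read[sel]
        for (ab in bases) {
          if (ab != rb) prof_mm[si, rb, ab] <- prof_mm[si, rb, ab] + sum(mm == ab)
        }
      }
    }
    if (gs == "+") {
      conv <- al$ref == "T"
      n_i <- sum(conv); k_i <- sum(conv & al$read == "C")
    } else {
      conv <- al$ref == "A"
      n_i <- sum(conv); k_i <- sum(conv & al$read == "G")
    }
    recs[[i]] <- list(read_id = b$qname[i], gene_id = g, strand = gs,
                      n = n_i, k = k_i)
  }
  recs <- purrr::compact(recs)
  records <- tibble(
    sample_id = sample_id,
    gene_id = purrr::map_chr(recs, "gene_id"),
    read_id = purrr::map_chr(recs, "read_id"),
    n = purrr::map_int(recs, ~ as.integer(.x$n)),
    k = purrr::map_int(recs, ~ as.integer(.x$k)),
    strand = purrr::map_chr(recs, "strand")
  )
  profile <- tidyr::expand_grid(gene_strand = c("+", "-"), ref = bases, alt = bases)
  profile <- profile[profile$ref != profile$alt, ]
  profile$mismatches <- mapply(function(s, r, a) prof_mm[s, r, a],
                               profile$gene_strand, profile$ref, profile$alt,
                               USE.NAMES = FALSE)
  profile$coverage <- mapply(function(s, r) prof_cov[s, r],
                             profile$gene_strand, profile$ref,
                             USE.NAMES = FALSE)
  structure(list(records = records, profile = as_tibble(profile),
                 skipped = skipped),
            class = "conversion_counts")
}

# Reconstruct per-position (ref base, read base, quality) for one alignment
# from its CIGAR, MD tag, read sequence and quality vector. Only positions
# consuming both read and reference (CIGAR M/=/X) are returned.
alignment_bases <- function(cigar, md, seq, qual) {
  ops <- cigar_ops(cigar)
  read_bases <- strsplit(seq, "")[[1]]
  rpos <- integer(0)  # read indices of aligned (M) positions, in order
  r <- 1L
  for (j in seq_len(nrow(ops))) {
    op <- ops$op[j]; len <- ops$len[j]
    if (op %in% c("M", "=", "X")) {
      rpos <- c(rpos, seq.int(r, r + len - 1L)); r <- r + len
    } else if (op %in% c("I", "S")) {
      r <- r + len
    } # D/N/H/P consume no read bases
  }
  ref_at <- md_reference(md)  # NA = matches read; letter = mismatched ref base
  if (length(ref_at) != length(rpos)) {
    stop("MD tag inconsistent with CIGAR: ", md, " vs ", cigar, call. = FALSE)
  }
  rb <- read_bases[rpos]
  data.frame(
    ref = ifelse(is.na(ref_at), rb, ref_at),
    read = rb,
    qual = qual[rpos],
    stringsAsFactors = FALSE
  )
}

cigar_ops <- function(cigar) {
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar)[[1]]
  parts <- regmatches(cigar, gregexpr("(\\d+)([MIDNSHP=X])", cigar))[[1]]
  if (length(parts) == 0) stop("unparseable CIGAR: ", cigar, call. = FALSE)
  data.frame(
    len = as.integer(sub("[MIDNSHP=X]$", "", parts)),
    op = sub("^\\d+", "", parts),
    stringsAsFactors = FALSE
  )
}

# Expand an MD tag into one entry per aligned (read-consuming) reference
# position: NA where reference equals the read, otherwise the reference base.
# Deletion runs (^XYZ) are skipped - they have no read base.
md_reference <- function(md) {
  toks <- regmatches(md, gregexpr("\\d+|\\^[A-Za-z]+|[A-Za-z]", md))[[1]]
  out <- character(0)
  for (tk in toks) {
    if (grepl("^\\d+$", tk)) {
      n <- as.integer(tk)
      if (n > 0) out <- c(out, rep(NA_character_, n))
    } else if (startsWith(tk, "^")) {
      # deleted reference bases: not present in the read
    } else {
      out <- c(out, toupper(tk))
    }
  }
  out
}

#' Write conversion records as a synthetic SAM file
#'
#' Emits one alignment per record with a sequence, CIGAR and MD tag that
#' encode exactly `n` convertible positions of which `k` carry the specific
#' mismatch (T>C for plus-strand genes, A>G for minus-strand genes),
#' interleaved with non-convertible G/C bases so the counter is exercised on
#' mixed-composition reads. Used as the round-trip fixture for
#' [count_conversions()].
#'
#' @param records Tibble with `read_id`, `gene_id`, `n`, `k` and optionally
#'   `strand` (joined from `genes` otherwise).
#' @param genes Tibble with `gene_id`, `strand`.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_read_sam <- function(records, genes, path) {
  stopifnot(all(records$k <= records$n))
  strand_of <- setNames(genes$strand, genes$gene_id)
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             "@SQ\tSN:chrS\tLN:100000")
  for (i in seq_len(nrow(records))) {
    n <- records$n[i]; k <- records$k[i]
    gs <- strand_of[[records$gene_id[i]]]
    conv_ref <- if (gs == "+") "T" else "A"
    conv_alt <- if (gs == "+") "C" else "G"
    pad <- if (gs == "+") "G" else "C"
    ref <- as.vector(rbind(rep(pad, n), rep(conv_ref, n)))
    read <- ref
    if (k > 0) {
      idx <- 2L * seq_len(k)  # first k convertible positions
      read[idx] <- conv_alt
    }
    md <- md_encode(ref, read)
    lines <- c(lines, paste(
      records$read_id[i], 0, "chrS", 1 + (i - 1L) %% 1000L, 255,
      paste0(length(read), "M"), "*", 0, 0,
      paste(read, collapse = ""), strrep("I", length(read)),
      paste0("MD:Z:", md), paste0("GE:Z:", records$gene_id[i]),
      sep = "\t"
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

# MD tag for an ungapped alignment given reference and read base vectors.
md_encode <- function(ref, read) {
  out <- character(0)
  run <- 0L
  for (i in seq_along(ref)) {
    if (ref[i] == read[i]) {
      run <- run + 1L
    } else {
      out <- c(out, as.character(run), ref[i])
      run <- 0L
    }
  }
  paste(c(out, as.character(run)), collapse = "")
}
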