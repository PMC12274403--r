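# Readers and writers for the tabular and genomic formats the toolkit
# touches. Internal coordinates are 0-based half-open everywhere; each
# reader documents its conversion at the boundary.

#' Read / write read-conversion record tables
#'
#' TSV with columns `sample_id`, `gene_id`, `read_id`, `n`, `k` and any
#' extra columns (e.g. `true_label` from the simulator). Round trips are
#' lossless.
#' @param path File path.
#' @return A tibble of records.
#' @export
read_records_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("sample_id", "gene_id", "n", "k")
  if (!all(req %in% names(x))) {
    stop("records table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(x$k > x$n) || any(x$n < 0)) {
    bad <- which(x$k > x$n | x$n < 0)[1]
    stop("invalid record at line ", bad + 1L, ": need 0 <= k <= n", call. = FALSE)
  }
  x
}

#' @rdname read_records_tsv
#' @param records Tibble of records to write.
#' @export
write_records_tsv <- function(records, path) {
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}

#' Read / write expression matrices
#'
#' Wide TSV (first column `gene_id`, one column per sample) read into the
#' package's long form (`gene_id`, `sample_id`, `value`), and back.
#' @param path File path.
#' @return Long tibble `gene_id`, `sample_id`, `value`.
#' @export
read_expression_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(x)[1] != "gene_id") stop("first column must be gene_id", call. = FALSE)
  tidyr::pivot_longer(x, -"gene_id", names_to = "sample_id", values_to = "value")
}

#' @rdname read_expression_tsv
#' @param expr Long expression tibble (`gene_id`, `sample_id`, `value`).
#' @export
write_expression_tsv <- function(expr, path) {
  wide <- tidyr::pivot_wider(expr[c("gene_id", "sample_id", "value")],
                             names_from = "sample_id", values_from = "value")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read / write expression matrices in MatrixMarket form
#'
#' `path` is the `.mtx` file; gene and sample identifiers live in sibling
#' plain-text files (one id per line).
#' @param path Path to the `.mtx` file.
#' @param genes_path,samples_path Paths to the row/column id files; default
#'   `<path>.genes` / `<path>.samples`.
#' @return Long tibble `gene_id`, `sample_id`, `value`.
#' @export
read_expression_mtx <- function(path, genes_path = paste0(path, ".genes"),
                                samples_path = paste0(path, ".samples")) {
  m <- as.matrix(Matrix::readMM(path))
  genes <- readr::read_lines(genes_path, progress = FALSE)
  samples <- readr::read_lines(samples_path, progress = FALSE)
  dimnames(m) <- list(genes, samples)
  tidyr::pivot_longer(
    dplyr::mutate(as_tibble(m), gene_id = genes, .before = 1),
    -"gene_id", names_to = "sample_id", values_to = "value"
  )
}

#' @rdname read_expression_mtx
#' @param expr Long expression tibble.
#' @export
write_expression_mtx <- function(expr, path,
                                 genes_path = paste0(path, ".genes"),
                                 samples_path = paste0(path, ".samples")) {
  wide <- tidyr::pivot_wider(expr[c("gene_id", "sample_id", "value")],
                             names_from = "sample_id", values_from = "value")
  m <- as.matrix(wide[-1])
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
  readr::write_lines(wide$gene_id, genes_path)
  readr::write_lines(colnames(m), samples_path)
  invisible(path)
}

#' Read BED peak intervals
#'
#' BED is 0-based half-open and is kept that way internally. Columns beyond
#' the first three are read as `name`, `score`, `strand` when present.
#' @param path BED file path.
#' @return Tibble `chrom`, `start`, `end` (0-based half-open) plus optional
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 fields",
         call. = FALSE)
  }
  start <- suppressWarnings(as.double(purrr::map_chr(fields, 2)))
  end <- suppressWarnings(as.double(purrr::map_chr(fields, 3)))
  if (anyNA(start) || anyNA(end) || any(end < start)) {
    bad <- which(is.na(start) | is.na(end) | end < start)[1]
    stop("malformed BED line ", bad, ": bad coordinates", call. = FALSE)
  }
  out <- tibble(chrom = purrr::map_chr(fields, 1), start = start, end = end)
  if (all(nf >= 4)) out$name <- purrr::map_chr(fields, 4)
  out
}

#' Read a TSS/strand annotation table
#'
#' TSV with columns `gene_id`, `chrom`, `tss`, `strand` and optionally
#' `tes`. `tss`/`tes` are 1-based genomic positions (GTF convention); window
#' builders convert to 0-based half-open internally.
#' @param path File path.
#' @return Annotation tibble.
#' @export
read_tss_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("gene_id", "chrom", "tss", "strand")
  if (!all(req %in% names(x))) {
    stop("TSS table must have columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(x$tss <= 0)) stop("TSS positions must be positive (1-based)", call. = FALSE)
  x
}

#' Derive a one-TSS-per-gene annotation from a GTF file
#'
#' Reads transcript records (1-based inclusive, converted internally) and
#' keeps, per gene, the most upstream TSS in the direction of transcription
#' (minimum start on plus-strand genes, maximum end on minus-strand genes),
#' along with the matching transcript end site.
#' @param path GTF file path.
#' @return Tibble `gene_id`, `chrom`, `tss`, `strand`, `tes` (1-based).
#' @export
tss_from_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("tss_from_gtf() requires the rtracklayer package", call. = FALSE)
  }
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type %in% c("transcript", "mRNA")]
  if (length(gr) == 0) stop("no transcript records in ", path, call. = FALSE)
  tx <- tibble(
    gene_id = gr$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  tx |>
    dplyr::mutate(
      tss = ifelse(.data$strand == "+", .data$start, .data$end),
      tes = ifelse(.data$strand == "+", .data$end, .data$start)
    ) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::slice(if (dplyr::first(.data$strand) == "+") which.min(.data$tss)
                 else which.max(.data$tss)) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "chrom", "tss", "strand", "tes")
}

#' Read a gene-to-GO annotation table
#'
#' Two-column TSV `gene_id`, `term_id`.
#' @param path File path.
#' @return Tibble `gene_id`, `term_id`.
#' @export
read_gene2go <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene_id", "term_id") %in% names(x))) {
    stop("gene2go table must have columns gene_id, term_id", call. = FALSE)
  }
  x
}

#' Read an OBO ontology (term names and obsolete flags only)
#'
#' Minimal stanza parser covering what GO overrepresentation needs: term
#' identifiers, names and `is_obsolete` flags. Obsolete terms are excluded
#' from the testing universe by [go_overrepresentation()].
#' @param path OBO file path.
#' @return Tibble `term_id`, `name`, `obsolete`.
#' @export
read_obo <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  starts <- which(lines == "[Term]")
  if (length(starts) == 0) stop("no [Term] stanzas in ", path, call. = FALSE)
  bounds <- c(starts, length(lines) + 1L)
  purrr::map_dfr(seq_along(starts), function(i) {
    chunk <- lines[seq.int(bounds[i] + 1L, bounds[i + 1L] - 1L)]
    chunk <- chunk[nzchar(chunk) & !startsWith(chunk, "[")]
    grab <- function(key) {
      hit <- chunk[startsWith(chunk, paste0(key, ": "))]
      if (length(hit) == 0) NA_character_ else sub(paste0("^", key, ": "), "", hit[1])
    }
    tibble(
      term_id = grab("id"),
      name = grab("name"),
      obsolete = identical(grab("is_obsolete"), "true")
    )
  })
}
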