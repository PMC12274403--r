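# Promoter ChIP-peak enrichment (up- vs down-regulated genes), region
# schemes, expression-matched backgrounds and GO overrepresentation.

#' Promoter windows around transcription start sites
#'
#' The promoter is the region from 1000 bp upstream to 100 bp downstream of
#' the TSS, oriented by gene strand. With `tss` the 1-based TSS position,
#' the window is the 0-based half-open interval `[tss - 1000, tss + 100)`
#' on plus-strand genes and `[tss - 100, tss + 1000)` on minus-strand
#' genes (upstream/downstream in transcription direction), truncated at the
#' chromosome start. Complete windows have width 1100.
#'
#' @param annot Annotation tibble `gene_id`, `chrom`, `tss` (1-based),
#'   `strand`.
#' @param upstream,downstream Window extent in bp (defaults 1000 and 100).
#' @return Tibble `gene_id`, `chrom`, `start`, `end` (0-based half-open),
#'   `strand`.
#' @examples
#' promoter_windows(tibble::tibble(gene_id = "g", chrom = "chr1",
#'                                 tss = 10000, strand = "+"))
#' @export
promoter_windows <- function(annot, upstream = 1000, downstream = 100) {
  stopifnot(all(c("gene_id", "chrom", "tss", "strand") %in% names(annot)))
  if (any(annot$tss <= 0)) stop("TSS positions must be positive (1-based)",
                                call. = FALSE)
  plus <- annot$strand == "+"
  tibble(
    gene_id = annot$gene_id,
    chrom = annot$chrom,
    start = pmax(0, ifelse(plus, annot$tss - upstream, annot$tss - downstream)),
    end = ifelse(plus, annot$tss + downstream, annot$tss + upstream),
    strand = annot$strand
  )
}

#' Gene-relative region windows
#'
#' Region scheme used for histone-mark enrichment: `promoter` as in
#' [promoter_windows()]; `gene_body` from 100 bp downstream of the TSS to
#' the transcript end site; `downstream` from the TES to `tail` bp past it.
#' All windows are oriented by strand and returned 0-based half-open.
#'
#' @param annot Annotation tibble `gene_id`, `chrom`, `tss`, `tes`
#'   (1-based), `strand`.
#' @param regions Which regions to build.
#' @param tail Extent of the downstream region in bp (default 1000).
#' @return Tibble `gene_id`, `region`, `chrom`, `start`, `end`, `strand`.
#' @export
gene_regions <- function(annot,
                         regions = c("promoter", "gene_body", "downstream"),
                         tail = 1000) {
  stopifnot(all(c("gene_id", "chrom", "tss", "tes", "strand") %in% names(annot)))
  regions <- match.arg(regions, several.ok = TRUE)
  plus <- annot$strand == "+"
  build <- function(region, start, end) {
    tibble(gene_id = annot$gene_id, region = region, chrom = annot$chrom,
           start = pmax(0, pmin(start, end)), end = pmax(start, end, 0),
           strand = annot$strand)
  }
  out <- list()
  if ("promoter" %in% regions) {
    pw <- promoter_windows(annot)
    out$promoter <- tibble(gene_id = pw$gene_id, region = "promoter",
                           chrom = pw$chrom, start = pw$start, end = pw$end,
                           strand = pw$strand)
  }
  if ("gene_body" %in% regions) {
    out$gene_body <- build("gene_body",
                           ifelse(plus, annot$tss + 100, annot$tes - 1),
                           ifelse(plus, annot$tes, annot$tss - 100))
  }
  if ("downstream" %in% regions) {
    out$downstream <- build("downstream",
                            ifelse(plus, annot$tes, annot$tes - 1 - tail),
                            ifelse(plus, annot$tes + tail, annot$tes - 1))
  }
  dplyr::bind_rows(out)
}

#' Peak presence per gene window
#'
#' Records, for every window and peak source, whether any peak interval
#' overlaps the window by at least 1 bp. Both inputs are 0-based half-open;
#' an interval ending exactly where a window starts does not overlap.
#'
#' @param windows Tibble `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), optionally `region`.
#' @param peaks Tibble `chrom`, `start`, `end` (0-based half-open, e.g.
#'   from [read_bed()]) with a `factor_id` column naming the peak source
#'   (a single unnamed source is labelled `"peaks"`).
#' @return Tibble `gene_id` (and `region` if present), `factor_id`,
#'   `has_peak` over the full window x factor grid.
#' @export
peak_in_promoter <- function(windows, peaks) {
  if (!"factor_id" %in% names(peaks)) peaks$factor_id <- "peaks"
  shared <- intersect(unique(windows$chrom), unique(peaks$chrom))
  if (length(shared) == 0) {
    warning("no shared chromosome names between windows (",
            paste(unique(windows$chrom), collapse = ","), ") and peaks (",
            paste(unique(peaks$chrom), collapse = ","), ")")
  }
  # 0-based half-open -> 1-based inclusive for IRanges
  wgr <- GenomicRanges::GRanges(windows$chrom,
                                IRanges::IRanges(windows$start + 1, windows$end))
  key_cols <- intersect(c("gene_id", "region"), names(windows))
  grid <- tidyr::expand_grid(
    dplyr::distinct(windows[key_cols]),
    factor_id = unique(peaks$factor_id)
  )
  hits <- purrr::map_dfr(unique(peaks$factor_id), function(f) {
    pk <- peaks[peaks$factor_id == f, ]
    pgr <- GenomicRanges::GRanges(pk$chrom,
                                  IRanges::IRanges(pk$start + 1, pk$end))
    ov <- GenomicRanges::findOverlaps(wgr, pgr, minoverlap = 1)
    idx <- unique(S4Vectors::queryHits(ov))
    if (length(idx) == 0) return(NULL)
    dplyr::mutate(dplyr::distinct(windows[idx, key_cols, drop = FALSE]),
                  factor_id = f, has_peak = TRUE)
  })
  if (nrow(hits) == 0) return(dplyr::mutate(grid, has_peak = FALSE))
  dplyr::left_join(grid, hits, by = c(key_cols, "factor_id")) |>
    dplyr::mutate(has_peak = dplyr::coalesce(.data$has_peak, FALSE))
}

#' Factor enrichment in promoters of up- vs down-regulated genes
#'
#' For each peak factor, forms the 2x2 table of (up/down regulated) x
#' (promoter peak / no peak), computes a two-sided Fisher exact p-value,
#' and an effect size as the fraction of peak-containing genes among the
#' upregulated divided by that fraction among the downregulated.
#' Benjamini-Hochberg adjustment across tested factors; factors with a
#' zero table margin are skipped with a reason.
#'
#' @param up_genes,down_genes Character vectors of gene ids (nonempty).
#' @param peak_table Tibble `gene_id`, `factor_id`, `has_peak` from
#'   [peak_in_promoter()].
#' @param alpha Significance cutoff on adjusted p (default 0.05).
#' @return Tibble of class `newrna_enrichment`: `factor_id`,
#'   `n_up_with_peak`, `n_up_total`, `n_down_with_peak`, `n_down_total`,
#'   `fold_change`, `p_value`, `q_value`, `significant`; skipped factors in
#'   attribute `skipped`.
#' @export
factor_enrichment <- function(up_genes, down_genes, peak_table, alpha = 0.05) {
  stopifnot(length(up_genes) > 0, length(down_genes) > 0)
  res <- peak_table |>
    dplyr::filter(.data$gene_id %in% c(up_genes, down_genes)) |>
    dplyr::group_by(.data$factor_id) |>
    dplyr::group_modify(function(g, key) {
      up <- g[g$gene_id %in% up_genes, ]
      dn <- g[g$gene_id %in% down_genes, ]
      a <- sum(up$has_peak); b <- nrow(up) - a
      c_ <- sum(dn$has_peak); d <- nrow(dn) - c_
      tibble(n_up_with_peak = a, n_up_total = nrow(up),
             n_down_with_peak = c_, n_down_total = nrow(dn),
             zero_margin = (a + c_ == 0) || (b + d == 0) ||
               nrow(up) == 0 || nrow(dn) == 0)
    }) |>
    dplyr::ungroup()
  skipped <- res$factor_id[res$zero_margin]
  res <- res[!res$zero_margin, ]
  if (nrow(res) == 0) {
    out <- tibble(factor_id = character(), n_up_with_peak = integer(),
                  n_up_total = integer(), n_down_with_peak = integer(),
                  n_down_total = integer(), fold_change = double(),
                  p_value = double(), q_value = double(),
                  significant = logical())
    attr(out, "skipped") <- skipped
    return(structure(out, class = c("newrna_enrichment", class(out))))
  }
  res <- res |>
    dplyr::rowwise() |>
    dplyr::mutate(
      fold_change = (.data$n_up_with_peak / .data$n_up_total) /
        (.data$n_down_with_peak / .data$n_down_total),
      p_value = fisher.test(matrix(c(.data$n_up_with_peak,
                                     .data$n_up_total - .data$n_up_with_peak,
                                     .data$n_down_with_peak,
                                     .data$n_down_total - .data$n_down_with_peak),
                                   nrow = 2, byrow = TRUE))$p.value
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"zero_margin") |>
    dplyr::mutate(q_value = p.adjust(.data$p_value, "BH"),
                  significant = .data$q_value < alpha)
  attr(res, "skipped") <- skipped
  structure(res, class = c("newrna_enrichment", class(res)))
}

#' Region-parameterized mark enrichment
#'
#' The same 2x2 Fisher machinery as [factor_enrichment()], run per genomic
#' region (promoter, gene body, downstream by default), reporting both
#' nominal and BH-adjusted p-values per factor and region.
#'
#' @inheritParams factor_enrichment
#' @param peak_table Tibble `gene_id`, `region`, `factor_id`, `has_peak`
#'   from [peak_in_promoter()] on [gene_regions()] windows.
#' @return Tibble as [factor_enrichment()] plus a `region` column; BH is
#'   applied within each region across factors.
#' @export
region_enrichment <- function(up_genes, down_genes, peak_table, alpha = 0.05) {
  stopifnot("region" %in% names(peak_table))
  peak_table |>
    dplyr::group_by(.data$region) |>
    dplyr::group_modify(function(g, key) {
      r <- factor_enrichment(up_genes, down_genes, g, alpha = alpha)
      as_tibble(r)
    }) |>
    dplyr::ungroup() |>
    (\(x) structure(x, class = c("newrna_enrichment", class(x))))()
}

#' Expression-matched background gene set
#'
#' Builds a background set matched to the input genes on average
#' expression: all genes are ranked by expression, then for each input gene
#' the ranking is searched in alternating directions for the nearest unused
#' non-input gene. A gene is unmatchable when no candidate lies within
#' `max_rank_diff` ranks; when more than `max_unmatched_frac` of the input
#' cannot be matched, matching aborts with a warning and the partial map is
#' returned (attribute `aborted`).
#'
#' @param genes Character vector of input gene ids (subset of the universe).
#' @param universe Tibble `gene_id`, `mean_expr` for all candidate genes.
#' @param max_rank_diff Maximum allowed rank distance (default 100).
#' @param max_unmatched_frac Abort threshold on the unmatchable fraction
#'   (default 0.1).
#' @return Tibble of class `newrna_matched`: `gene_id`, `matched_gene_id`
#'   (`NA` when unmatched), `rank_diff`; the matched background ids are in
#'   attribute `background`.
#' @export
expression_matched_background <- function(genes, universe,
                                          max_rank_diff = 100,
                                          max_unmatched_frac = 0.1) {
  stopifnot(all(c("gene_id", "mean_expr") %in% names(universe)))
  if (!all(genes %in% universe$gene_id)) {
    stop("input genes must be a subset of the universe", call. = FALSE)
  }
  if (nrow(universe) < 2 * length(genes)) {
    stop("universe smaller than twice the input set", call. = FALSE)
  }
  ord <- order(universe$mean_expr, decreasing = TRUE)
  ranked <- universe$gene_id[ord]
  rank_of <- setNames(seq_along(ranked), ranked)
  is_input <- ranked %in% genes
  used <- is_input  # input genes are never usable as matches
  # process input genes in rank order for determinism
  genes_ord <- genes[order(rank_of[genes])]
  n <- length(ranked)
  out <- vector("list", length(genes_ord))
  unmatched <- 0L
  budget <- max_unmatched_frac * length(genes)
  aborted <- FALSE
  for (i in seq_along(genes_ord)) {
    g <- genes_ord[i]
    r <- rank_of[[g]]
    match_idx <- NA_integer_
    for (d in seq_len(max_rank_diff)) {
      for (cand in c(r - d, r + d)) {
        if (cand >= 1 && cand <= n && !used[cand]) { match_idx <- cand; break }
      }
      if (!is.na(match_idx)) break
    }
    if (is.na(match_idx)) {
      unmatched <- unmatched + 1L
      out[[i]] <- tibble(gene_id = g, matched_gene_id = NA_character_,
                         rank_diff = NA_integer_)
      if (unmatched > budget) {
        warning("matching aborted: more than ",
                round(100 * max_unmatched_frac), "% of input genes unmatchable")
        aborted <- TRUE
        break
      }
    } else {
      used[match_idx] <- TRUE
      out[[i]] <- tibble(gene_id = g, matched_gene_id = ranked[match_idx],
                         rank_diff = abs(match_idx - r))
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "background") <- res$matched_gene_id[!is.na(res$matched_gene_id)]
  attr(res, "aborted") <- aborted
  structure(res, class = c("newrna_matched", class(res)))
}

#' GO term overrepresentation with expression-matched backgrounds
#'
#' Per term, forms the 2x2 table of (study/background) x (annotated to the
#' term or not). When all four expected counts exceed 10 a chi-square test
#' without continuity correction is used, otherwise Fisher's exact test.
#' Two-stage FDR is applied across all tested terms. Obsolete ontology
#' terms are excluded from the universe when an ontology is supplied. The
#' background may be an expression-matched set or the opposite regulation
#' direction (e.g. down- vs up-regulated genes); overlapping genes are
#' removed from the background.
#'
#' @param study Character vector of study gene ids.
#' @param background Character vector of background gene ids.
#' @param gene2go Tibble `gene_id`, `term_id`.
#' @param ontology Optional tibble from [read_obo()] (`term_id`,
#'   `obsolete`); obsolete terms are dropped.
#' @param alpha FDR level for the two-stage adjustment (default 0.05; the
#'   exploratory analyses in the field often use 0.5).
#' @param min_expected Expected-count threshold for the chi-square branch
#'   (default 10).
#' @return Tibble of class `newrna_go`: `term_id`, `n_study`,
#'   `n_background`, `study_in_term`, `background_in_term`, `ratio`,
#'   `test`, `p_value`, `q_value`, `significant`.
#' @export
go_overrepresentation <- function(study, background, gene2go,
                                  ontology = NULL, alpha = 0.05,
                                  min_expected = 10) {
  background <- setdiff(background, study)
  stopifnot(length(study) > 0, length(background) > 0)
  if (!is.null(ontology)) {
    keep <- ontology$term_id[!ontology$obsolete]
    gene2go <- gene2go[gene2go$term_id %in% keep, ]
  }
  gene2go <- gene2go[gene2go$gene_id %in% c(study, background), ]
  terms <- unique(gene2go$term_id)
  ns <- length(study); nb <- length(background)
  res <- purrr::map_dfr(terms, function(tm) {
    in_term <- gene2go$gene_id[gene2go$term_id == tm]
    a <- sum(study %in% in_term); b <- ns - a
    c_ <- sum(background %in% in_term); d <- nb - c_
    tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    use_chisq <- all(expected > min_expected)
    p <- if (use_chisq) {
      suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
    } else {
      fisher.test(tab)$p.value
    }
    tibble(term_id = tm, n_study = ns, n_background = nb,
           study_in_term = a, background_in_term = c_,
           ratio = (a / ns) / ifelse(c_ > 0, c_ / nb, NA_real_),
           test = if (use_chisq) "chisq" else "fisher", p_value = p)
  })
  if (nrow(res) == 0) return(structure(res, class = c("newrna_go", class(res))))
  res <- dplyr::mutate(res, q_value = two_stage_fdr(.data$p_value, alpha),
                       significant = .data$q_value < alpha)
  structure(res, class = c("newrna_go", class(res)))
}
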