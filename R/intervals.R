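# Interval arithmetic and peak annotation. All coordinates are 0-based
# half-open; GRanges (1-based closed) is used only as an internal engine,
# converted at the call boundary.

grange_from0 <- function(chrom, start0, end0) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start0 + 1L,
                                                 end = as.integer(end0)))
}

anchors_granges <- function(pk) {
  a <- peak_anchor(pk)
  GenomicRanges::GRanges(pk$chrom, IRanges::IRanges(start = a + 1L, width = 1L))
}

#' Transcription start site of each gene
#'
#' Strand-aware: the TSS of a plus-strand gene is its span start; of a
#' minus-strand gene the 0-based coordinate of its last base (`end - 1`).
#'
#' @param genes Gene table (the `genes` component of a `genome_annotation`,
#'   or any data.frame with `strand`, `start`, `end`).
#' @return Integer vector of 0-based TSS coordinates.
#' @export
tss_position <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end - 1L)
}

#' Signed distance from a position to a gene's TSS
#'
#' Negative values are upstream of the TSS relative to gene orientation.
#'
#' @param position 0-based genomic position(s).
#' @param genes Gene table row(s) (recycled against `position`).
#' @return Signed integer distance(s) in bp.
#' @export
signed_tss_distance <- function(position, genes) {
  tss <- tss_position(genes)
  ifelse(genes$strand == "+", position - tss, tss - position)
}

#' Strand-aware promoter window around a TSS
#'
#' Both boundary bases are included (`TSS - upstream` through
#' `TSS + downstream` inclusive, hence half-open end + 1), clamped at zero
#' and at the chromosome length when known.
#'
#' @param gene One-row gene table.
#' @param upstream,downstream Extent in bp on each side of the TSS (default
#'   5000, the promoter window used for direct-target calling).
#' @param chrom_lengths Optional named vector of chromosome lengths.
#' @return List with `chrom`, `start`, `end` (0-based half-open).
#' @export
promoter_window <- function(gene, upstream = 5000L, downstream = 5000L,
                            chrom_lengths = NULL) {
  stopifnot(upstream >= 0, downstream >= 0)
  tss <- tss_position(gene)
  if (gene$strand == "+") {
    s <- tss - upstream; e <- tss + downstream + 1L
  } else {
    s <- tss - downstream; e <- tss + upstream + 1L
  }
  s <- max(0L, s)
  if (!is.null(chrom_lengths) && gene$chrom %in% names(chrom_lengths))
    e <- min(e, as.integer(chrom_lengths[[gene$chrom]]))
  list(chrom = gene$chrom, start = as.integer(s), end = as.integer(e))
}

#' Partition two peak sets into common and unique peaks
#'
#' A peak is "common" iff it overlaps at least `min_overlap` bp with any peak
#' of the other set; abutting half-open intervals do not overlap.
#'
#' @param a,b `peak_set` data.frames.
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return List `common_a`, `unique_a`, `common_b`, `unique_b` of `peak_set`s.
#' @export
compare_peak_sets <- function(a, b, min_overlap = 1L) {
  ga <- grange_from0(a$chrom, a$start, a$end)
  gb <- grange_from0(b$chrom, b$start, b$end)
  ca <- GenomicRanges::countOverlaps(ga, gb, minoverlap = min_overlap) > 0
  cb <- GenomicRanges::countOverlaps(gb, ga, minoverlap = min_overlap) > 0
  list(common_a = a[ca, , drop = FALSE], unique_a = a[!ca, , drop = FALSE],
       common_b = b[cb, , drop = FALSE], unique_b = b[!cb, , drop = FALSE])
}

peak_categories <- c("Promoter<=1kb", "Promoter1-2kb", "Promoter2-3kb",
                     "5UTR", "3UTR", "Exon", "Intron", "Downstream<=3kb",
                     "DistalIntergenic")

#' Annotate peaks with genomic-feature categories
#'
#' Each peak is classified by its anchor (summit when present, else the
#' midpoint) with the priority Promoter bins (unsigned TSS distance <= 1 kb,
#' 1-2 kb, 2-3 kb over all genes) > 5'UTR > 3'UTR > Exon > Intron >
#' Downstream (<= 3 kb past a gene's 3' end) > DistalIntergenic, mirroring
#' ChIPseeker-style defaults. `nearest_gene` is the gene minimizing the
#' unsigned TSS distance, with `tss_distance` signed relative to its strand.
#'
#' @param pk A `peak_set` data.frame.
#' @param ann A `genome_annotation`.
#' @return data.frame: the peaks plus `anchor`, `category`, `nearest_gene`,
#'   `tss_distance`.
#' @export
annotate_peaks <- function(pk, ann) {
  if (!nrow(ann$genes)) stop_ctx("empty genome annotation")
  if (!nrow(pk)) stop_ctx("no peaks to annotate")
  anchor <- peak_anchor(pk)
  g <- ann$genes
  tss <- tss_position(g)
  # nearest TSS per anchor, deterministic tie-break by gene-table order
  nearest_idx <- integer(nrow(pk))
  absdist <- integer(nrow(pk))
  for (ch in unique(pk$chrom)) {
    pi <- which(pk$chrom == ch)
    gi <- which(g$chrom == ch)
    if (!length(gi)) {
      nearest_idx[pi] <- NA_integer_
      absdist[pi] <- NA_integer_
      next
    }
    ord <- gi[order(tss[gi], gi)]
    st <- tss[ord]
    pos <- anchor[pi]
    right <- findInterval(pos, st) + 1L        # first TSS >= pos (1..n+1)
    left <- right - 1L
    dl <- ifelse(left >= 1L, pos - st[pmax(left, 1L)], NA_integer_)
    dr <- ifelse(right <= length(st), st[pmin(right, length(st))] - pos,
                 NA_integer_)
    use_left <- !is.na(dl) & (is.na(dr) | dl <= dr)
    idx <- ifelse(use_left, ord[pmax(left, 1L)],
                  ord[pmin(right, length(st))])
    nearest_idx[pi] <- idx
    absdist[pi] <- ifelse(use_left, dl, dr)
  }
  category <- rep("DistalIntergenic", nrow(pk))
  category[!is.na(absdist) & absdist <= 3000L] <- "Promoter2-3kb"
  category[!is.na(absdist) & absdist <= 2000L] <- "Promoter1-2kb"
  category[!is.na(absdist) & absdist <= 1000L] <- "Promoter<=1kb"
  open <- category == "DistalIntergenic"
  ga <- anchors_granges(pk)
  in_feature <- function(df) {
    if (!nrow(df)) return(rep(FALSE, nrow(pk)))
    ch <- g$chrom[match(df$gene_id, g$gene_id)]
    GenomicRanges::countOverlaps(ga, grange_from0(ch, df$start, df$end)) > 0
  }
  category[open & in_feature(ann$utr5)] <- "5UTR"
  open <- category == "DistalIntergenic"
  category[open & in_feature(ann$utr3)] <- "3UTR"
  open <- category == "DistalIntergenic"
  category[open & in_feature(ann$exons)] <- "Exon"
  open <- category == "DistalIntergenic"
  in_span <- GenomicRanges::countOverlaps(
    ga, grange_from0(g$chrom, g$start, g$end)) > 0
  category[open & in_span] <- "Intron"
  open <- category == "DistalIntergenic"
  if (any(open)) {
    # within 3 kb past the 3' end, strand-aware
    dstart <- ifelse(g$strand == "+", g$end, pmax(0L, g$start - 3000L))
    dend <- ifelse(g$strand == "+", g$end + 3000L, g$start)
    ok <- dend > dstart
    down <- GenomicRanges::countOverlaps(
      ga, grange_from0(g$chrom[ok], dstart[ok], dend[ok])) > 0
    category[open & down] <- "Downstream<=3kb"
  }
  out <- as.data.frame(pk)
  out$anchor <- anchor
  out$category <- factor(category, levels = peak_categories)
  out$nearest_gene <- ifelse(is.na(nearest_idx), NA_character_,
                             g$symbol[nearest_idx])
  out$tss_distance <- ifelse(is.na(nearest_idx), NA_integer_,
                             signed_tss_distance(anchor,
                                                 g[nearest_idx, , drop = FALSE]))
  out
}

#' Fraction of peaks per genomic-feature category
#'
#' @param pk A `peak_set`.
#' @param ann A `genome_annotation`.
#' @return Named numeric vector over all categories; sums to 1.
#' @export
annotation_summary <- function(pk, ann) {
  if (!nrow(pk)) stop_ctx("annotation_summary: zero peaks")
  tab <- table(annotate_peaks(pk, ann)$category)
  as.numeric(tab) / nrow(pk) -> fr
  setNames(fr, names(tab))
}

#' Map peaks to genes by promoter-window containment
#'
#' A peak supports gene `g` when its anchor lies inside
#' `promoter_window(g, window, window)` (TSS +/- window, both ends
#' inclusive). Genes without supporting peaks are absent from the result.
#'
#' @param pk A `peak_set`.
#' @param ann A `genome_annotation`.
#' @param window Half-width of the promoter window in bp (default 5000).
#' @return Named list, gene symbol -> data.frame with `peak` (row index in
#'   `pk`), `name` and `tss_distance`.
#' @export
map_peaks_to_genes <- function(pk, ann, window = 5000L) {
  if (window <= 0) stop_ctx("map_peaks_to_genes: window must be > 0")
  g <- ann$genes
  if (!nrow(pk) || !nrow(g)) return(setNames(list(), character(0)))
  tss <- tss_position(g)
  win <- grange_from0(g$chrom, pmax(0L, tss - as.integer(window)),
                      tss + as.integer(window) + 1L)
  hits <- GenomicRanges::findOverlaps(anchors_granges(pk), win)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  if (!length(qh)) return(setNames(list(), character(0)))
  anchor <- peak_anchor(pk)
  d <- signed_tss_distance(anchor[qh], g[sh, , drop = FALSE])
  sym <- g$symbol[sh]
  out <- lapply(split(seq_along(qh), sym), function(ii) {
    data.frame(peak = qh[ii], name = pk$name[qh[ii]], tss_distance = d[ii],
               stringsAsFactors = FALSE)
  })
  out[order(names(out))]
}
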