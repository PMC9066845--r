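#' Read gene models from a GTF file
#'
#' Parses a GTF-dialect annotation restricted to the feature types `gene`,
#' `exon`, `five_prime_utr` and `three_prime_utr`. GTF coordinates (1-based,
#' closed) are converted to the internal 0-based half-open convention at this
#' boundary and nowhere else. Gene identity is the symbol (`gene_name`,
#' falling back to `gene_id`).
#'
#' @param path Path to a GTF file.
#' @param chrom_lengths Optional named integer vector of chromosome lengths.
#' @return A `genome_annotation` object: list with `genes` (data.frame:
#'   `gene_id`, `symbol`, `chrom`, `strand`, `start`, `end`), `exons`,
#'   `utr5`, `utr3` (data.frames keyed by `gene_id`) and `chrom_lengths`.
#' @export
read_gene_model <- function(path, chrom_lengths = NULL) {
  if (!file.exists(path)) stop_ctx("GTF file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 9L)
  if (length(bad))
    stop_ctx("GTF parse error at line ", lineno[bad[1]], ": fewer than 9 columns")
  feat <- vapply(fields, `[[`, "", 3L)
  use <- feat %in% c("gene", "exon", "five_prime_utr", "three_prime_utr")
  fields <- fields[use]; feat <- feat[use]; lineno <- lineno[use]
  if (!length(fields)) stop_ctx("GTF contains no gene/exon/UTR features")
  chrom <- vapply(fields, `[[`, "", 1L)
  s1 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
  e1 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
  strand <- vapply(fields, `[[`, "", 7L)
  attrs <- vapply(fields, `[[`, "", 9L)
  if (any(is.na(s1) | is.na(e1) | e1 < s1))
    stop_ctx("GTF parse error at line ",
             lineno[which(is.na(s1) | is.na(e1) | e1 < s1)[1]],
             ": bad coordinates")
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad))
    stop_ctx("GTF validation error at line ", lineno[bad[1]],
             ": unknown strand '", strand[bad[1]], "'")
  get_attr <- function(a, key) {
    m <- regmatches(a, regexec(paste0(key, ' "([^"]*)"'), a))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
  }
  gene_id <- get_attr(attrs, "gene_id")
  bad <- which(is.na(gene_id) | !nzchar(gene_id))
  if (length(bad))
    stop_ctx("GTF validation error at line ", lineno[bad[1]],
             ": missing gene_id attribute")
  gene_name <- get_attr(attrs, "gene_name")
  # convert 1-based closed -> 0-based half-open
  start0 <- s1 - 1L; end0 <- e1
  gi <- feat == "gene"
  if (!any(gi)) stop_ctx("GTF contains no gene features")
  if (anyDuplicated(gene_id[gi]))
    stop_ctx("GTF validation error: duplicate gene_id ",
             gene_id[gi][duplicated(gene_id[gi])][1])
  genes <- data.frame(
    gene_id = gene_id[gi],
    symbol = ifelse(is.na(gene_name[gi]), gene_id[gi], gene_name[gi]),
    chrom = chrom[gi], strand = strand[gi],
    start = start0[gi], end = end0[gi], stringsAsFactors = FALSE)
  sub_feature <- function(type) {
    fi <- feat == type
    df <- data.frame(gene_id = gene_id[fi], start = start0[fi], end = end0[fi],
                     stringsAsFactors = FALSE)
    orphan <- setdiff(df$gene_id, genes$gene_id)
    if (length(orphan))
      stop_ctx("GTF validation error: ", type, " for unknown gene ", orphan[1])
    sp <- genes[match(df$gene_id, genes$gene_id), ]
    if (nrow(df) && any(df$start < sp$start | df$end > sp$end))
      stop_ctx("GTF validation error: ", type, " outside gene span for ",
               df$gene_id[which(df$start < sp$start | df$end > sp$end)[1]])
    df[order(match(df$gene_id, genes$gene_id), df$start), , drop = FALSE]
  }
  ann <- list(genes = genes, exons = sub_feature("exon"),
              utr5 = sub_feature("five_prime_utr"),
              utr3 = sub_feature("three_prime_utr"),
              chrom_lengths = chrom_lengths)
  class(ann) <- "genome_annotation"
  ann
}

#' Write a genome annotation back to GTF
#'
#' Mirrors [read_gene_model()]: internal 0-based half-open coordinates are
#' converted back to 1-based closed GTF coordinates.
#'
#' @param ann A `genome_annotation`.
#' @param path Output file path.
#' @export
write_gene_model <- function(ann, path) {
  row <- function(chrom, feat, start0, end0, strand, gid, sym) {
    paste(chrom, "hif2sig", feat, start0 + 1L, end0, ".", strand, ".",
          sprintf('gene_id "%s"; gene_name "%s";', gid, sym), sep = "\t")
  }
  g <- ann$genes
  out <- character(0)
  for (i in seq_len(nrow(g))) {
    out <- c(out, row(g$chrom[i], "gene", g$start[i], g$end[i], g$strand[i],
                      g$gene_id[i], g$symbol[i]))
    sub <- ann$exons[ann$exons$gene_id == g$gene_id[i], , drop = FALSE]
    for (j in seq_len(nrow(sub)))
      out <- c(out, row(g$chrom[i], "exon", sub$start[j], sub$end[j],
                        g$strand[i], g$gene_id[i], g$symbol[i]))
    for (pair in list(c("five_prime_utr", "utr5"), c("three_prime_utr", "utr3"))) {
      sub <- ann[[pair[2]]][ann[[pair[2]]]$gene_id == g$gene_id[i], , drop = FALSE]
      for (j in seq_len(nrow(sub)))
        out <- c(out, row(g$chrom[i], pair[1], sub$start[j], sub$end[j],
                          g$strand[i], g$gene_id[i], g$symbol[i]))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$genes), "genes on",
      length(unique(x$genes$chrom)), "chromosome(s)\n")
  invisible(x)
}
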