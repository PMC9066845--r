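# Direct-target signature construction and cohort scoring: DE genes
# intersected with promoter-proximal binding, signed-weight sums of
# z-scored expression, EMT and hypoxia scores, and the association tests.

#' Build a direct-target gene signature
#'
#' Genes called differentially expressed (`padj < fdr` and
#' `|log2fc| >= lfc`) that also carry promoter-proximal binding (a key of
#' `peak_gene_map`, built at TSS +/- 5 kb) enter the signature with weight
#' +1 (up) or -1 (down). Provenance (DE statistics and the best supporting
#' peak) is recorded per gene.
#'
#' @param de A `de_result`.
#' @param peak_gene_map Output of [map_peaks_to_genes()].
#' @param fdr,lfc DE thresholds (defaults 0.05 and 1).
#' @param weight_by `"sign"` (default) for +/-1 weights, `"log2fc"` to weight
#'   by the fold-change magnitude.
#' @return A `signature` data.frame: `gene`, `weight`, `log2fc`, `padj`,
#'   `peak_id`, `tss_distance`; empty (with a warning) when no gene
#'   satisfies both criteria.
#' @export
build_signature <- function(de, peak_gene_map, fdr = 0.05, lfc = 1.0,
                            weight_by = c("sign", "log2fc")) {
  weight_by <- match.arg(weight_by)
  calls <- call_de(de, fdr, lfc)
  genes <- sort(intersect(c(calls$up, calls$down), names(peak_gene_map)))
  if (!length(genes)) {
    warning("build_signature: no gene passes both DE and binding criteria",
            call. = FALSE)
    return(empty_signature())
  }
  i <- match(genes, de$gene)
  w <- if (weight_by == "sign") sign(de$log2fc[i]) else de$log2fc[i]
  best_peak <- vapply(genes, function(g) {
    m <- peak_gene_map[[g]]
    j <- which.min(abs(m$tss_distance))
    if (is.na(m$name[j])) paste0("peak", m$peak[j]) else m$name[j]
  }, "")
  best_dist <- vapply(genes, function(g) {
    m <- peak_gene_map[[g]]
    m$tss_distance[which.min(abs(m$tss_distance))]
  }, 0)
  sig <- data.frame(gene = genes, weight = w, log2fc = de$log2fc[i],
                    padj = de$padj[i], peak_id = best_peak,
                    tss_distance = best_dist, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(sig) <- c("signature", "data.frame")
  sig
}

empty_signature <- function() {
  sig <- data.frame(gene = character(0), weight = numeric(0),
                    log2fc = numeric(0), padj = numeric(0),
                    peak_id = character(0), tss_distance = numeric(0),
                    stringsAsFactors = FALSE)
  class(sig) <- c("signature", "data.frame")
  sig
}

#' @export
print.signature <- function(x, ...) {
  cat("signature:", nrow(x), "genes (", sum(x$weight > 0), "up,",
      sum(x$weight < 0), "down )\n")
  invisible(x)
}

#' Write / read a signature TSV
#' @param sig A `signature`.
#' @param path File path.
#' @export
write_signature <- function(sig, path) {
  out <- sig
  for (cc in c("weight", "log2fc", "padj")) out[[cc]] <- fmt_num(out[[cc]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  sig <- read.delim(path, stringsAsFactors = FALSE)
  class(sig) <- c("signature", "data.frame")
  sig
}

#' Per-gene cohort z-score normalization
#'
#' Each gene (row) is centered by its cohort mean and scaled by its cohort
#' standard deviation; constant genes become all-zero rows.
#'
#' @param expr Genes x samples numeric matrix.
#' @return Matrix of the same shape.
#' @export
zscore_normalize <- function(expr) {
  if (ncol(expr) < 2L) stop_ctx("z-scoring needs >= 2 samples")
  mu <- rowMeans(expr)
  sd <- apply(expr, 1, sd)
  z <- (expr - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}

#' Weighted-sum signature score per sample
#'
#' `score(sample) = sum over signature genes of weight * z`, over the genes
#' present in the expression matrix (missing genes are dropped with a log
#' message).
#'
#' @param z Z-scored expression matrix (genes x samples).
#' @param sig A `signature` (or named weight vector).
#' @return Named numeric vector of per-sample scores.
#' @export
signature_score <- function(z, sig) {
  w <- if (inherits(sig, "signature") || is.data.frame(sig))
    setNames(sig$weight, sig$gene) else sig
  present <- names(w) %in% rownames(z)
  if (!any(present)) stop_ctx("no signature gene present in expression matrix")
  if (any(!present))
    log_msg("signature_score: dropped ", sum(!present),
            " signature gene(s) absent from the matrix")
  w <- w[present]
  drop(crossprod(z[names(w), , drop = FALSE], w))[colnames(z)]
}

#' EMT score: mesenchymal minus epithelial mean z-score
#'
#' Higher values indicate more mesenchymal differentiation. Requires at
#' least one positively weighted (mesenchymal) and one negatively weighted
#' (epithelial) gene present.
#'
#' @param z Z-scored expression matrix.
#' @param emt_set Signed gene set (named weights; sign defines the side).
#' @return Named numeric vector of per-sample scores.
#' @export
emt_score <- function(z, emt_set) {
  mes <- intersect(names(emt_set)[emt_set > 0], rownames(z))
  epi <- intersect(names(emt_set)[emt_set < 0], rownames(z))
  if (!length(mes) || !length(epi))
    stop_ctx("emt_score: need both mesenchymal and epithelial genes present")
  colMeans(z[mes, , drop = FALSE]) - colMeans(z[epi, , drop = FALSE])
}

#' Hypoxia score by median dichotomization
#'
#' Per sample, the sum over hypoxia-signature genes of +1 when the sample's
#' expression exceeds the cohort median for that gene and -1 otherwise
#' (values exactly at the median count -1).
#'
#' @param expr Expression matrix (genes x samples; raw or normalized --
#'   the rule is rank-based per gene).
#' @param hypoxia_genes Character vector of signature genes.
#' @return Named integer-valued numeric vector of per-sample scores.
#' @export
hypoxia_score <- function(expr, hypoxia_genes) {
  genes <- intersect(hypoxia_genes, rownames(expr))
  if (!length(genes)) stop_ctx("hypoxia_score: no signature gene present")
  sub <- expr[genes, , drop = FALSE]
  med <- apply(sub, 1, median)
  colSums(ifelse(sub > med, 1, -1))
}

#' Pearson correlation between two score vectors
#'
#' Samples are matched by name (intersection); the two-sided p-value comes
#' from the usual t transform of r.
#'
#' @param a,b Named numeric score vectors.
#' @return List with `r`, `p` and `n`.
#' @export
pearson_correlation <- function(a, b) {
  ids <- intersect(names(a), names(b))
  if (length(ids) < 3L) stop_ctx("pearson_correlation: need >= 3 paired samples")
  x <- a[ids]; y <- b[ids]
  if (sd(x) == 0 || sd(y) == 0)
    stop_ctx("pearson_correlation: zero variance")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(ids))
}

#' Compare score distributions across groups
#'
#' Two groups: Mann-Whitney U (exact when the combined size is <= 10 and
#' tie-free, normal approximation with tie correction otherwise). More than
#' two groups: Kruskal-Wallis H with chi-square p-value.
#'
#' @param scores Named numeric vector.
#' @param labels Group labels (named or in score order).
#' @return List with `test`, `statistic`, `p` and group sizes `n`.
#' @export
compare_groups <- function(scores, labels) {
  if (!is.null(names(labels))) labels <- labels[names(scores)]
  g <- factor(labels)
  if (any(table(g) == 0) || nlevels(g) < 2L)
    stop_ctx("compare_groups: need >= 2 non-empty groups")
  if (nlevels(g) == 2L) {
    ht <- suppressWarnings(wilcox.test(scores[g == levels(g)[1]],
                                       scores[g == levels(g)[2]]))
    list(test = "mann-whitney", statistic = unname(ht$statistic),
         p = ht$p.value, n = as.integer(table(g)))
  } else {
    ht <- kruskal.test(scores, g)
    list(test = "kruskal-wallis", statistic = unname(ht$statistic),
         p = ht$p.value, n = as.integer(table(g)))
  }
}

#' Pooled-variance two-sided Student's t test
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return List with `t`, `df` and `p`.
#' @export
two_sample_t <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  sp <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  if (sp == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = length(a) + length(b) - 2,
                                        p = 1))
    stop_ctx("two_sample_t: zero pooled variance with unequal means")
  }
  ht <- t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}
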