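# Preranked GSEA from scratch: weighted Kolmogorov-Smirnov running-sum
# enrichment score, size-matched random-gene-set permutation null, NES and
# same-sign FDR.

#' Build a ranked gene list
#'
#' Sorts genes by score in strictly descending order; ties are broken by
#' gene symbol (lexicographic) so the ranking is deterministic.
#'
#' @param scores Named numeric vector (e.g. Wald statistics), one per gene.
#' @return A `ranked_list`: named numeric vector sorted descending.
#' @export
ranked_list <- function(scores) {
  if (is.null(names(scores)) || anyDuplicated(names(scores)))
    stop_ctx("ranking requires unique gene names")
  if (any(!is.finite(scores))) stop_ctx("ranking scores must be finite")
  ord <- order(-scores, names(scores), method = "radix")
  structure(scores[ord], class = "ranked_list")
}

# Fast ES for a hit set given sorted scores: the running-sum extremes can
# only occur immediately after a hit (candidate maxima) or immediately
# before the next hit (candidate minima), so only 2K positions are examined.
es_stat <- function(scores, hit_idx, p_exp = 1) {
  N <- length(scores); K <- length(hit_idx)
  hi <- sort(hit_idx)
  w <- abs(scores[hi])^p_exp
  NR <- sum(w)
  cumhit <- if (NR > 0) cumsum(w) / NR else cumsum(rep(1 / K, K))
  miss_step <- 1 / (N - K)
  # running sum after the j-th hit, and just before the j-th hit
  after <- cumhit - (hi - seq_len(K)) * miss_step
  before <- c(0, cumhit[-K]) - (hi - seq_len(K)) * miss_step
  hi_max <- max(after); lo_min <- min(before)
  if (hi_max >= -lo_min) hi_max else lo_min
}

#' Weighted-KS enrichment score with running sum and leading edge
#'
#' Walking the ranking, member genes ("hits") add
#' `|score|^p_exp / sum(|score|^p_exp over hits)` and non-members subtract
#' `1/(N - N_hits)`; the enrichment score is the running-sum value of
#' maximal absolute deviation. The leading edge contains the hits at or
#' before the extremum (at or after it for negative scores).
#'
#' @param ranked A `ranked_list`.
#' @param geneset Character vector of member gene symbols.
#' @param p_exp Weighting exponent (1 = the "weighted" statistic; 0 gives
#'   the classic unweighted KS walk).
#' @return List: `es`, `running` (length-N running sum), `leading_edge`.
#' @export
enrichment_score <- function(ranked, geneset, p_exp = 1) {
  genes <- names(ranked)
  hit <- genes %in% geneset
  if (!any(hit)) stop_ctx("gene set does not intersect the ranking")
  if (all(hit)) stop_ctx("gene set equals the ranked universe")
  w <- abs(as.numeric(ranked))^p_exp
  NR <- sum(w[hit])
  inc <- numeric(length(ranked))
  inc[hit] <- if (NR > 0) w[hit] / NR else 1 / sum(hit)
  inc[!hit] <- -1 / sum(!hit)
  running <- cumsum(inc)
  i_max <- which.max(running); i_min <- which.min(running)
  es <- if (running[i_max] >= -running[i_min]) running[i_max] else running[i_min]
  if (es >= 0) {
    le <- genes[hit & seq_along(genes) <= i_max]
  } else {
    le <- genes[hit & seq_along(genes) >= i_min]
  }
  list(es = es, running = running, leading_edge = le)
}

#' Preranked GSEA over a gene-set collection
#'
#' Sets are restricted to the ranked universe and kept when their restricted
#' size is within `[min_size, max_size]`. The null distribution for each set
#' size is built from size-matched random gene sets drawn from the universe
#' (gene-tag permutation). The nominal p-value is the same-sign tail
#' frequency with a +1 pseudocount; NES divides the ES by the mean absolute
#' same-sign null ES. FDR q pools same-sign null and observed NES:
#' `q(NES*) = [frac of null NES with same sign and |NES| >= |NES*|] /`
#' `[frac of observed NES with same sign and |NES| >= |NES*|]`, capped at 1.
#'
#' @param ranked A `ranked_list`.
#' @param collection Named list of gene sets.
#' @param n_perm Number of permutations (default 1000).
#' @param max_size,min_size Set-size bounds after restriction (defaults 5000
#'   and 5).
#' @param p_exp Weighting exponent (default 1).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A `gsea_result` data.frame: `set`, `size`, `es`, `nes`, `pvalue`,
#'   `fdr`, `leading_edge` (comma-joined).
#' @export
preranked_gsea <- function(ranked, collection, n_perm = 1000L,
                           max_size = 5000L, min_size = 5L, p_exp = 1,
                           seed = 1L) {
  stopifnot(n_perm >= 100L)
  genes <- names(ranked)
  sizes <- vapply(collection, function(s) sum(genes %in% s), 0L)
  keep <- sizes >= min_size & sizes <= max_size & sizes < length(genes)
  if (!any(keep)) {
    warning("preranked_gsea: no eligible gene set", call. = FALSE)
    return(empty_gsea_result())
  }
  collection <- collection[keep]; sizes <- sizes[keep]
  scores <- as.numeric(ranked)
  obs <- lapply(collection, function(s) enrichment_score(ranked, s, p_exp))
  es <- vapply(obs, `[[`, 0, "es")
  uniq_sizes <- sort(unique(sizes))
  null_es <- with_seed(seed, {
    lapply(setNames(uniq_sizes, uniq_sizes), function(k) {
      vapply(seq_len(n_perm), function(i)
        es_stat(scores, sample.int(length(genes), k), p_exp), 0)
    })
  })
  pos_mean <- vapply(null_es, function(v) mean(v[v > 0]), 0)
  neg_mean <- vapply(null_es, function(v) mean(abs(v[v < 0])), 0)
  nes <- pvalue <- numeric(length(es))
  null_nes <- list()
  for (i in seq_along(es)) {
    nv <- null_es[[as.character(sizes[i])]]
    if (es[i] >= 0) {
      same <- nv[nv >= 0]
      pvalue[i] <- (1 + sum(same >= es[i])) / (1 + length(same))
      nes[i] <- es[i] / pos_mean[[as.character(sizes[i])]]
    } else {
      same <- nv[nv < 0]
      pvalue[i] <- (1 + sum(same <= es[i])) / (1 + length(same))
      nes[i] <- es[i] / neg_mean[[as.character(sizes[i])]]
    }
  }
  # pooled null NES for the FDR (each null ES normalized by its own
  # size/sign-matched mean)
  all_null_nes <- unlist(lapply(as.character(uniq_sizes), function(k) {
    v <- null_es[[k]]
    ifelse(v >= 0, v / pos_mean[[k]], v / neg_mean[[k]])
  }), use.names = FALSE)
  fdr <- vapply(seq_along(es), function(i) {
    if (nes[i] >= 0) {
      num <- mean(all_null_nes[all_null_nes >= 0] >= nes[i])
      den <- mean(nes[nes >= 0] >= nes[i])
    } else {
      num <- mean(all_null_nes[all_null_nes < 0] <= nes[i])
      den <- mean(nes[nes < 0] <= nes[i])
    }
    if (!is.finite(num / den)) 1 else min(1, num / den)
  }, 0)
  res <- data.frame(set = names(collection), size = sizes, es = es,
                    nes = nes, pvalue = pvalue, fdr = fdr,
                    leading_edge = vapply(obs, function(o)
                      paste(o$leading_edge, collapse = ","), ""),
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[order(-abs(res$nes)), ]
  rownames(res) <- NULL
  class(res) <- c("gsea_result", "data.frame")
  res
}

empty_gsea_result <- function() {
  res <- data.frame(set = character(0), size = integer(0), es = numeric(0),
                    nes = numeric(0), pvalue = numeric(0), fdr = numeric(0),
                    leading_edge = character(0), stringsAsFactors = FALSE)
  class(res) <- c("gsea_result", "data.frame")
  res
}

#' @export
print.gsea_result <- function(x, ...) {
  cat("gsea_result:", nrow(x), "gene sets tested\n")
  if (nrow(x)) {
    top <- head(as.data.frame(x)[, c("set", "size", "nes", "pvalue", "fdr")], 5)
    print(top, row.names = FALSE)
  }
  invisible(x)
}
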