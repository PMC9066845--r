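# Negative-binomial differential expression, re-implemented as a documented
# simplification of the NB-Wald framework: median-of-ratios size factors,
# method-of-moments gene dispersions shrunk in log space toward a least-
# squares a0 + a1/mu trend, and a per-gene NB GLM (log link, expected
# information IRLS) for the two-group Wald test.

#' Construct a count matrix with condition labels
#'
#' @param counts Integer matrix, genes x samples, with dimnames.
#' @param condition Character/factor of per-sample condition labels.
#' @return A `count_matrix` object (list with `counts` and `condition`).
#' @export
count_matrix <- function(counts, condition) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_ctx("count matrix needs gene rownames and sample colnames")
  if (length(condition) != ncol(counts))
    stop_ctx("one condition label per sample required")
  if (any(counts < 0) || any(counts != round(counts)))
    stop_ctx("counts must be non-negative integers")
  if (ncol(counts) < 2L) stop_ctx("need >= 2 samples")
  obj <- list(counts = counts,
              condition = setNames(as.character(condition), colnames(counts)))
  class(obj) <- "count_matrix"
  obj
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples;", "conditions:",
      paste(names(table(x$condition)), table(x$condition), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Remove genes with low cumulative counts
#'
#' Genes whose total count across all samples falls below `min_total`
#' (default 2, i.e. "< 2 cumulative reads" removed) are dropped; gene order
#' is preserved.
#'
#' @param cm A `count_matrix`.
#' @param min_total Minimum cumulative count to keep a gene.
#' @return Filtered `count_matrix`.
#' @export
filter_low_counts <- function(cm, min_total = 2L) {
  keep <- rowSums(cm$counts) >= min_total
  if (!any(keep)) stop_ctx("all genes removed by low-count filter")
  count_matrix(cm$counts[keep, , drop = FALSE], cm$condition)
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over genes (nonzero in every sample) of the
#' ratio of its count to the gene's geometric mean across samples. Factors
#' are not renormalized.
#'
#' @param cm A `count_matrix` (or plain counts matrix).
#' @return Named positive numeric vector, one per sample.
#' @export
size_factors <- function(cm) {
  k <- if (inherits(cm, "count_matrix")) cm$counts else cm
  use <- rowSums(k == 0) == 0L
  if (!any(use)) stop_ctx("size_factors: no gene with nonzero counts in every sample")
  logk <- log(k[use, , drop = FALSE])
  loggeo <- rowMeans(logk)
  sf <- apply(exp(logk - loggeo), 2, median)
  setNames(sf, colnames(k))
}

trend_dispersion <- function(coefs, mu) {
  pmax(coefs[1] + coefs[2] / mu, 1e-8)
}

#' Estimate per-gene dispersions with trend shrinkage
#'
#' Per gene, a method-of-moments raw dispersion
#' `alpha_hat = max(alpha_min, (pooled within-condition variance - mu)/mu^2)`
#' on normalized counts; a mean-dispersion trend `alpha(mu) = a0 + a1/mu` fit
#' by least squares over genes with `alpha_hat > alpha_min` (coefficients
#' clamped at zero); and a final dispersion obtained by log-space shrinkage
#' `log alpha* = (1-delta) log alpha_hat + delta log alpha_trend(mu)`,
#' clamped to `[alpha_min, alpha_max]`.
#'
#' @param cm A `count_matrix`.
#' @param sf Size factors from [size_factors()].
#' @param delta Shrinkage weight toward the trend (default 0.5).
#' @param alpha_min,alpha_max Dispersion clamp bounds.
#' @return A `dispersion_model`: list with `alpha_raw`, `trend` (a0, a1),
#'   `alpha` (final), `mu` (per-gene mean normalized count).
#' @export
estimate_dispersions <- function(cm, sf = size_factors(cm), delta = 0.5,
                                 alpha_min = 1e-8, alpha_max = 10) {
  k <- cm$counts
  cond <- cm$condition
  reps <- table(cond)
  if (!any(reps >= 2)) stop_ctx("need >= 2 replicates in some condition")
  q <- sweep(k, 2, sf, "/")
  mu <- rowMeans(q)
  # pooled within-condition variance (conditions with >= 2 replicates)
  ss <- rep(0, nrow(k)); df <- 0
  for (cn in names(reps)[reps >= 2]) {
    qc <- q[, cond == cn, drop = FALSE]
    ss <- ss + rowSums((qc - rowMeans(qc))^2)
    df <- df + ncol(qc) - 1L
  }
  v <- ss / df
  alpha_raw <- pmax(alpha_min, (v - mu) / mu^2)
  alpha_raw[!is.finite(alpha_raw)] <- alpha_min
  fit_idx <- which(alpha_raw > alpha_min & mu > 0)
  if (length(fit_idx) >= 2) {
    co <- coef(lm(alpha_raw[fit_idx] ~ I(1 / mu[fit_idx])))
    co <- pmax(co, 0)
  } else co <- c(0.1, 1)  # fallback trend when nearly all genes are Poisson-like
  names(co) <- c("a0", "a1")
  at <- trend_dispersion(co, pmax(mu, 1e-8))
  alpha <- exp((1 - delta) * log(alpha_raw) + delta * log(at))
  alpha <- pmin(pmax(alpha, alpha_min), alpha_max)
  obj <- list(alpha_raw = setNames(alpha_raw, rownames(k)), trend = co,
              alpha = setNames(alpha, rownames(k)), mu = setNames(mu, rownames(k)),
              delta = delta, alpha_min = alpha_min, alpha_max = alpha_max)
  class(obj) <- "dispersion_model"
  obj
}

#' @export
print.dispersion_model <- function(x, ...) {
  cat("dispersion_model: trend a0 =", fmt_num(x$trend[1]), ", a1 =",
      fmt_num(x$trend[2]), "; median final alpha =",
      fmt_num(median(x$alpha)), "\n")
  invisible(x)
}

#' Negative-binomial Wald test between two conditions
#'
#' Per gene, an NB GLM with log link, intercept + condition indicator and
#' log size-factor offsets is fit by expected-information IRLS at the fixed
#' final dispersion; the Wald statistic is the log2 fold change over its
#' standard error, with a two-sided normal p-value and BH adjustment.
#' All-zero genes get log2fc 0 and p 1; non-converged genes get NA p and are
#' excluded from the BH denominator.
#'
#' @param cm A `count_matrix`.
#' @param contrast Character of length 2, `c(B, A)`: fold changes are B vs A.
#' @param model A `dispersion_model`.
#' @param sf Size factors.
#' @param max_iter IRLS iteration cap.
#' @return A `de_result` data.frame: `gene`, `base_mean`, `log2fc`, `se`,
#'   `wald_stat`, `pvalue`, `padj`, `converged`.
#' @export
nb_wald_test <- function(cm, contrast, model, sf = size_factors(cm),
                         max_iter = 50L) {
  stopifnot(length(contrast) == 2L)
  sel <- cm$condition %in% contrast
  if (sum(cm$condition == contrast[1]) < 2L ||
      sum(cm$condition == contrast[2]) < 2L)
    stop_ctx("each contrasted condition needs >= 2 samples")
  k <- cm$counts[, sel, drop = FALSE]
  x <- as.numeric(cm$condition[sel] == contrast[1])   # 1 = condition B
  s <- sf[colnames(k)]
  alpha <- model$alpha[rownames(k)]
  G <- nrow(k); n <- ncol(k)
  q <- sweep(k, 2, s, "/")
  base_mean <- rowMeans(q)
  # initialize at (log mean A, log mean B - log mean A) with a small floor
  mA <- pmax(rowMeans(q[, x == 0, drop = FALSE]), 1e-8)
  mB <- pmax(rowMeans(q[, x == 1, drop = FALSE]), 1e-8)
  b0 <- log(mA); b1 <- log(mB) - log(mA)
  S <- matrix(s, G, n, byrow = TRUE)
  X <- matrix(x, G, n, byrow = TRUE)
  converged <- rep(FALSE, G)
  active <- base_mean > 0
  for (it in seq_len(max_iter)) {
    eta <- b0 + outer(b1, rep(1, n)) * X
    mu <- S * exp(eta)
    W <- mu / (1 + alpha * mu)          # expected-information weight
    Z <- eta + (k - mu) / mu            # working response
    S00 <- rowSums(W); S01 <- rowSums(W * X)
    T0 <- rowSums(W * Z); T1 <- rowSums(W * X * Z)
    det <- S00 * S01 - S01^2            # S11 == S01 for a 0/1 indicator
    nb0 <- (S01 * T0 - S01 * T1) / det
    nb1 <- (S00 * T1 - S01 * T0) / det
    step_ok <- is.finite(nb0) & is.finite(nb1) & active
    d <- pmax(abs(nb0 - b0), abs(nb1 - b1))
    newly <- step_ok & d < 1e-8
    converged <- converged | newly
    b0[step_ok] <- nb0[step_ok]; b1[step_ok] <- nb1[step_ok]
    if (all(converged | !active)) break
  }
  # guard against runaway coefficients (separation at zero group counts)
  converged <- converged & abs(b1) < 50
  eta <- b0 + outer(b1, rep(1, n)) * X
  mu <- S * exp(eta)
  W <- mu / (1 + alpha * mu)
  S00 <- rowSums(W); S01 <- rowSums(W * X)
  det <- S00 * S01 - S01^2
  se_nat <- sqrt(S00 / det)
  log2fc <- b1 / log(2)
  se <- se_nat / log(2)
  wald <- log2fc / se
  pval <- 2 * pnorm(-abs(wald))
  zero <- base_mean == 0
  log2fc[zero] <- 0; se[zero] <- NA_real_; wald[zero] <- 0; pval[zero] <- 1
  converged[zero] <- TRUE
  n_bad <- sum(!converged)
  if (n_bad > 0)
    log_msg("nb_wald_test: ", n_bad, " gene(s) did not converge; p set to NA")
  pval[!converged] <- NA_real_
  wald[!converged] <- NA_real_
  res <- data.frame(gene = rownames(k), base_mean = base_mean,
                    log2fc = log2fc, se = se, wald_stat = wald,
                    pvalue = pval, padj = bh_adjust(pval),
                    converged = converged, stringsAsFactors = FALSE)
  class(res) <- c("de_result", "data.frame")
  attr(res, "contrast") <- contrast
  res
}

#' @export
print.de_result <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat("de_result:", nrow(x), "genes",
      if (!is.null(ct)) paste0("(", ct[1], " vs ", ct[2], ")"), "\n")
  ok <- !is.na(x$padj)
  cat("  padj < 0.05:", sum(x$padj[ok] < 0.05), "genes\n")
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement, capped at 1; missing
#' values are excluded from the number of tests.
#'
#' @param p Numeric p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted p-values, same length/order as input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_ctx("p-values outside [0, 1]")
  p.adjust(p, method = "BH")
}

#' Variance-stabilizing transformation
#'
#' Closed-form VST for the fitted `a0 + a1/mu` dispersion trend, applied to
#' normalized counts `q`:
#' `v(q) = log2((1 + a1 + 2 a0 q + 2 sqrt(a0 q (1 + a1 + a0 q))) / (4 a0))`.
#' Falls back to `log2(q + 1)` with a warning when the fitted `a0` is not
#' positive (near-Poisson data have no stabilizing asymptote).
#'
#' @param cm A `count_matrix`.
#' @param sf Size factors.
#' @param model A `dispersion_model` (its trend coefficients are used).
#' @return Real matrix, genes x samples.
#' @export
vst_transform <- function(cm, sf = size_factors(cm),
                          model = estimate_dispersions(cm, sf)) {
  q <- sweep(cm$counts, 2, sf, "/")
  a0 <- model$trend[["a0"]]; a1 <- model$trend[["a1"]]
  if (a0 <= 0) {
    warning("vst_transform: trend a0 <= 0, falling back to log2(q + 1)",
            call. = FALSE)
    return(log2(q + 1))
  }
  log2((1 + a1 + 2 * a0 * q + 2 * sqrt(a0 * q * (1 + a1 + a0 * q))) / (4 * a0))
}

#' Call differentially expressed genes
#'
#' Up: `padj < fdr` and `log2fc >= lfc_threshold`; down: `padj < fdr` and
#' `log2fc <= -lfc_threshold`. The FDR cutoff is strict, the fold-change
#' boundary inclusive.
#'
#' @param res A `de_result`.
#' @param fdr FDR cutoff (default 0.05).
#' @param lfc_threshold Absolute log2 fold-change threshold (default 1).
#' @return List with character vectors `up` and `down`.
#' @export
call_de <- function(res, fdr = 0.05, lfc_threshold = 1.0) {
  ok <- !is.na(res$padj)
  list(up = res$gene[ok & res$padj < fdr & res$log2fc >= lfc_threshold],
       down = res$gene[ok & res$padj < fdr & res$log2fc <= -lfc_threshold])
}

#' Euclidean sample-to-sample distance matrix
#'
#' @param vst Transformed expression matrix (genes x samples).
#' @return Symmetric matrix of Euclidean distances between sample columns.
#' @export
sample_distance_matrix <- function(vst) {
  if (ncol(vst) < 2L) stop_ctx("need >= 2 samples")
  as.matrix(dist(t(vst), method = "euclidean"))
}
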