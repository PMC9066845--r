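test_that("low-count filter removes genes below the cumulative threshold", {
  k <- matrix(c(1L, 0L, 0L, 1L, 1L, 0L, 4L, 6L, 0L, 0L, 0L, 0L), 3, 4,
              byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"), paste0("s", 1:4)))
  cm <- count_matrix(k, rep(c("A", "B"), each = 2))
  expect_equal(rownames(filter_low_counts(cm)$counts), c("gA", "gB"))
  expect_equal(rownames(filter_low_counts(cm, 0)$counts), rownames(k))
  zero <- count_matrix(matrix(0L, 2, 2, dimnames = list(c("a", "b"),
                                                        c("s1", "s2"))),
                       c("A", "B"))
  expect_error(filter_low_counts(zero), "all genes removed")
})

test_that("size factors reproduce median-of-ratios by hand and by DESeq2", {
  k <- matrix(c(2L, 8L, 4L, 16L), 2, 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(size_factors(k), c(s1 = 0.5, s2 = 2.0))
  # identical columns -> unit factors
  k2 <- matrix(rep(c(3L, 9L, 27L), 2), 3, 2,
               dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_equal(unname(size_factors(k2)), c(1, 1))
  # scaling one column by c scales its factor by c (2-sample all-gene case)
  k3 <- k2; k3[, 2] <- k3[, 2] * 5L
  expect_equal(unname(size_factors(k3)[2] / size_factors(k3)[1]), 5)
  # independent oracle: DESeq2's median-of-ratios on a random matrix
  set.seed(42)
  k4 <- matrix(rnbinom(600, mu = 100, size = 10), 100, 6,
               dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
  # (DESeq2 interpolates the even-count median on the log scale, hence the
  # tiny tolerance rather than exact identity)
  expect_equal(unname(size_factors(k4)),
               unname(DESeq2::estimateSizeFactorsForMatrix(k4)),
               tolerance = 1e-4)
  expect_error(size_factors(matrix(c(0L, 1L, 1L, 0L), 2, 2,
    dimnames = list(c("a", "b"), c("s1", "s2")))), "nonzero")
})

test_that("dispersion estimation recovers Poisson and NB regimes", {
  # Poisson data: no overdispersion, shrunken estimates stay tiny
  set.seed(7)
  k <- matrix(rpois(2000 * 6, lambda = 100), 2000, 6,
              dimnames = list(sprintf("g%04d", 1:2000), paste0("s", 1:6)))
  cm <- count_matrix(k, rep(c("A", "B"), each = 3))
  d <- estimate_dispersions(cm)
  expect_lte(median(d$alpha), 0.05)
  expect_lte(median(d$alpha),
             median(trend_disp <- pmax(d$trend[1] + d$trend[2] / d$mu, 1e-8)))
  # zero within-condition variance clamps to alpha_min
  kc <- matrix(c(5L, 5L, 5L, 5L, 7L, 7L, 7L, 7L), 2, 4, byrow = TRUE,
               dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  dc <- estimate_dispersions(count_matrix(kc, rep(c("A", "B"), each = 2)))
  expect_equal(unname(dc$alpha_raw), c(1e-8, 1e-8))
  # NB alpha = 0.2 recovered at n = 6 + 6
  cmn <- small_counts(n_genes = 2000, reps = 6, alpha = 0.2, seed = 8)
  dn <- estimate_dispersions(cmn)
  expect_gte(median(dn$alpha), 0.1)
  expect_lte(median(dn$alpha), 0.4)
})

test_that("NB Wald test is unbiased under the null and recovers planted lfc", {
  cm0 <- small_counts(n_genes = 2000, reps = 3, alpha = 0.05, seed = 21)
  de0 <- nb_wald_test(cm0, c("B", "A"), estimate_dispersions(cm0))
  expect_lte(abs(mean(de0$log2fc)), 0.05)
  # planted 4-fold change
  lfc <- rep(c(2, 0), c(100, 1900))
  cm1 <- small_counts(n_genes = 2000, reps = 3, alpha = 0.05, lfc = lfc,
                      seed = 22)
  de1 <- nb_wald_test(cm1, c("B", "A"), estimate_dispersions(cm1))
  m <- mean(de1$log2fc[1:100])
  expect_gte(m, 1.7); expect_lte(m, 2.3)
  # label swap negates fold changes, preserves p-values
  de1r <- nb_wald_test(cm1, c("A", "B"), estimate_dispersions(cm1))
  expect_equal(de1r$log2fc, -de1$log2fc, tolerance = 1e-6)
  expect_equal(de1r$pvalue, de1$pvalue, tolerance = 1e-6)
  # Wald statistic identity
  ok <- !is.na(de1$se) & de1$se > 0
  expect_equal(de1$wald_stat[ok], de1$log2fc[ok] / de1$se[ok])
})

test_that("fold-change estimates agree with DESeq2 on the same data", {
  lfc <- rep(c(1.5, 0, -1.5), c(50, 400, 50))
  cm <- small_counts(n_genes = 500, reps = 3, alpha = 0.05, lfc = lfc,
                     seed = 30)
  de <- nb_wald_test(cm, c("B", "A"), estimate_dispersions(cm))
  dds <- DESeq2::DESeqDataSetFromMatrix(
    cm$counts, data.frame(condition = factor(cm$condition, c("A", "B"))),
    ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::results(dds, contrast = c("condition", "B", "A"))
  expect_gte(cor(de$log2fc, ref$log2FoldChange), 0.98)
  expect_lte(median(abs(de$log2fc - ref$log2FoldChange)), 0.1)
})

test_that("scale invariance: scaling a sample moves its size factor only", {
  cm <- small_counts(n_genes = 500, reps = 2, alpha = 0.05, seed = 31)
  de1 <- nb_wald_test(cm, c("B", "A"), estimate_dispersions(cm))
  k2 <- cm$counts; k2[, 1] <- k2[, 1] * 3L
  cm2 <- count_matrix(k2, cm$condition)
  expect_equal(unname(size_factors(cm2)[1] / size_factors(cm)[1]) /
                 unname(size_factors(cm2)[2] / size_factors(cm)[2]),
               3, tolerance = 0.02)
  de2 <- nb_wald_test(cm2, c("B", "A"), estimate_dispersions(cm2))
  expect_lte(median(abs(de2$log2fc - de1$log2fc)), 0.05)
})

test_that("BH adjustment matches the hand example and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(1)
  p <- sort(runif(50))
  expect_false(is.unsorted(bh_adjust(p)))
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # NAs excluded from the denominator
  expect_equal(bh_adjust(c(0.02, NA, 0.04))[c(1, 3)],
               p.adjust(c(0.02, 0.04), "BH"))
})

test_that("VST matches its closed form, is monotone, and goes log2 at scale", {
  cm <- small_counts(n_genes = 300, reps = 3, alpha = 0.1, seed = 40)
  d <- estimate_dispersions(cm)
  a0 <- d$trend[["a0"]]; a1 <- d$trend[["a1"]]
  expect_gt(a0, 0)  # overdispersed regime has a stabilizing asymptote
  v <- function(q) log2((1 + a1 + 2 * a0 * q +
                           2 * sqrt(a0 * q * (1 + a1 + a0 * q))) / (4 * a0))
  expect_equal(v(0), log2((1 + a1) / (4 * a0)))
  q <- 0:10000
  expect_true(all(diff(v(q)) > 0))
  # slope approaches log2 for large q
  expect_equal(v(2e6) - v(1e6), 1, tolerance = 1e-3)
  # applied to a count matrix it reproduces the per-cell closed form
  sf <- size_factors(cm)
  vm <- vst_transform(cm, sf, d)
  expect_equal(vm[3, 2], unname(v(cm$counts[3, 2] / sf[2])))
})

test_that("DE calling respects thresholds exactly at the boundaries", {
  res <- data.frame(gene = c("a", "b", "c", "d"),
                    base_mean = 10, log2fc = c(2, 1, 3, -1),
                    se = 0.1, wald_stat = 1,
                    pvalue = c(0.001, 0.001, 0.05, 0.001),
                    padj = c(0.01, 0.01, 0.05, 0.01))
  class(res) <- c("de_result", "data.frame")
  calls <- call_de(res, fdr = 0.05, lfc_threshold = 1)
  expect_equal(calls$up, c("a", "b"))  # boundary lfc = 1 inclusive
  expect_equal(calls$down, "d")        # padj = 0.05 strictly excluded for c
  expect_length(intersect(calls$up, calls$down), 0)
})

test_that("sample distances are Euclidean, symmetric, and metric", {
  m <- cbind(s1 = c(0, 0), s2 = c(3, 4), s3 = c(6, 8))
  dm <- sample_distance_matrix(m)
  expect_equal(dm["s1", "s2"], 5)
  expect_equal(dm["s1", "s3"], 10)
  expect_equal(dm, t(dm))
  expect_equal(diag(dm), c(s1 = 0, s2 = 0, s3 = 0))
  # duplicated sample has zero distance
  m2 <- cbind(m, s4 = m[, "s2"])
  expect_equal(sample_distance_matrix(m2)["s2", "s4"], 0)
  # triangle inequality on random data
  set.seed(2)
  m3 <- matrix(rnorm(50), 10, 5, dimnames = list(NULL, paste0("x", 1:5)))
  d3 <- sample_distance_matrix(m3)
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    expect_lte(d3[i, j], d3[i, k] + d3[k, j] + 1e-12)
})

test_that("type-I error of the DE pipeline is controlled on a null dataset", {
  cm <- small_counts(n_genes = 2000, reps = 3, alpha = 0.1, seed = 50)
  de <- nb_wald_test(cm, c("B", "A"), estimate_dispersions(cm))
  frac <- mean(de$padj < 0.05, na.rm = TRUE)
  mc_se <- sqrt(0.05 * 0.95 / 2000)
  expect_lte(frac, 0.05 + 2 * mc_se)
})
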