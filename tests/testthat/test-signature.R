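test_that("signature construction requires both DE and promoter binding", {
  de <- data.frame(gene = c("A", "B", "C"),
                   base_mean = 100, log2fc = c(2, 0.5, 3), se = 0.1,
                   wald_stat = 1, pvalue = c(1e-4, 1e-4, 0.1),
                   padj = c(0.01, 0.01, 0.2), stringsAsFactors = FALSE)
  class(de) <- c("de_result", "data.frame")
  pmap <- list(A = data.frame(peak = 1L, name = "p1", tss_distance = -200),
               B = data.frame(peak = 2L, name = "p2", tss_distance = 300))
  sig <- build_signature(de, pmap)
  expect_equal(sig$gene, "A")      # B fails lfc, C fails FDR
  expect_equal(sig$weight, 1)
  expect_equal(sig$peak_id, "p1")
  expect_equal(sig$tss_distance, -200)
  expect_warning(empty <- build_signature(de, list()), "no gene")
  expect_equal(nrow(empty), 0L)
  # invariant to input gene order
  sig2 <- build_signature(de[3:1, ], pmap[c("B", "A")])
  expect_equal(sig2, sig)
  # magnitude weighting behind the flag
  sig3 <- build_signature(de, pmap, weight_by = "log2fc")
  expect_equal(sig3$weight, 2)
})

test_that("planted direct targets are recovered with high precision/recall", {
  st <- simulate_study(seed = 7)
  cm <- filter_low_counts(st$cm)
  sf <- size_factors(cm)
  disp <- estimate_dispersions(cm, sf)
  de <- nb_wald_test(cm, c("S65W", "WT"), disp, sf)
  sig <- build_signature(de, map_peaks_to_genes(st$peaks, st$ann, 5000))
  tr <- st$truth
  expect_gte(mean(tr$direct_targets %in% sig$gene), 0.9)
  expect_gte(mean(sig$gene %in% tr$direct_targets), 0.9)
  # signed weights follow the planted direction
  planted <- st$truth$de_spec
  hit <- intersect(sig$gene, planted$gene)
  expect_equal(sign(sig$weight[match(hit, sig$gene)]),
               sign(planted$log2fc[match(hit, planted$gene)]))
  # signature TSV round trip
  tmp <- tempfile(); write_signature(sig, tmp)
  sig_rt <- read_signature(tmp)
  expect_equal(sig_rt$gene, sig$gene)
  expect_equal(sig_rt$weight, sig$weight)
})

test_that("z-score normalization centers and scales per gene", {
  m <- rbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5), g3 = c(0, 10, 20))
  colnames(m) <- paste0("s", 1:3)
  z <- zscore_normalize(m)
  expect_equal(unname(z["g1", ]), c(-1, 0, 1))  # sample sd
  expect_equal(unname(z["g2", ]), c(0, 0, 0))   # constant gene
  expect_equal(rowMeans(z)[["g3"]], 0)
  expect_equal(sd(z["g3", ]), 1)
})

test_that("signature scores are weighted sums, linear in weights", {
  z <- rbind(U = c(s1 = 2, s2 = 0), D = c(s1 = -1, s2 = 1))
  sig <- toy_signature(up = "U", down = "D")
  sc <- signature_score(z, sig)
  expect_equal(sc, c(s1 = 3, s2 = -1))
  sig2 <- sig; sig2$weight <- sig2$weight * 2
  expect_equal(signature_score(z, sig2), 2 * sc)
  expect_equal(signature_score(z * 0, sig), c(s1 = 0, s2 = 0))
  # missing genes dropped; all missing errors
  sig3 <- toy_signature(up = c("U", "X"), down = "D")
  expect_equal(suppressMessages(signature_score(z, sig3)), sc)
  expect_error(signature_score(z, toy_signature(up = "X", down = "Y")),
               "no signature gene")
})

test_that("EMT score is mesenchymal minus epithelial and antisymmetric", {
  z <- rbind(M1 = c(s1 = 1, s2 = -1), M2 = c(s1 = 1, s2 = -1),
             E1 = c(s1 = -1, s2 = 1))
  emt <- c(M1 = 1, M2 = 1, E1 = -1)
  expect_equal(emt_score(z, emt), c(s1 = 2, s2 = -2))
  expect_equal(emt_score(z, -emt), -emt_score(z, emt))
  expect_error(emt_score(z, c(M1 = 1, M2 = 1)), "both")
})

test_that("hypoxia score dichotomizes at the cohort median with ties low", {
  ex <- rbind(H1 = c(s1 = 1, s2 = 2, s3 = 3, s4 = 4),
              H2 = c(s1 = 5, s2 = 5, s3 = 9, s4 = 2))
  sc <- hypoxia_score(ex, c("H1", "H2"))
  # H1 median 2.5: s1,s2 low, s3,s4 high; H2 median 5: ties at 5 go low
  expect_equal(sc, c(s1 = -2, s2 = -2, s3 = 2, s4 = 0))
  # all-above sample gets +k
  expect_equal(hypoxia_score(ex, "H1")[["s4"]], 1)
})

test_that("planted cohort axes are recovered by the scores", {
  sig <- toy_signature(up = sprintf("U%02d", 1:20),
                       down = sprintf("D%02d", 1:10))
  co <- simulate_cohort(sig, seed = 5)
  z <- zscore_normalize(co$expr)
  es <- emt_score(z, co$emt_set)
  expect_gte(cor(es, co$truth$emt_axis), 0.8)
  sc <- signature_score(z, sig)
  expect_gte(cor(sc, co$truth$activity), 0.9)
  hs <- hypoxia_score(co$expr, co$hypoxia_genes)
  expect_gte(cor(hs, co$truth$hypoxia_axis), 0.8)
})

test_that("hypoxia scores balance out for symmetric even-n cohorts", {
  set.seed(33)
  ex <- matrix(rnorm(20 * 100), 20, 100,
               dimnames = list(sprintf("H%02d", 1:20), sprintf("s%03d", 1:100)))
  sc <- hypoxia_score(ex, rownames(ex))
  expect_equal(sum(sc), 0)  # per gene: exactly n/2 above an even-n median
})

test_that("Pearson correlation matches hand values and calibrates", {
  expect_equal(pearson_correlation(c(a = 1, b = 2, c = 3),
                                   c(a = 2, b = 4, c = 6))$r, 1)
  pc <- pearson_correlation(c(a = 1, b = 2, c = 3), c(a = 1, b = 3, c = 2))
  expect_equal(pc$r, 0.5)
  expect_error(pearson_correlation(c(a = 1, b = 1, c = 1),
                                   c(a = 1, b = 2, c = 3)), "variance")
  set.seed(17)
  rs <- vapply(1:50, function(i) {
    x <- setNames(rnorm(50), paste0("s", 1:50))
    y <- setNames(rnorm(50), paste0("s", 1:50))
    pearson_correlation(x, y)$r
  }, 0)
  expect_gte(mean(abs(rs) < 0.4), 0.98)
})

test_that("group comparison uses exact Mann-Whitney for tiny samples", {
  sc <- c(a = 1, b = 2, c = 3, d = 4)
  gt <- compare_groups(sc, c(a = "x", b = "x", c = "y", d = "y"))
  expect_equal(gt$test, "mann-whitney")
  expect_equal(gt$statistic, 0)
  expect_equal(gt$p, 1/3)  # exact enumeration of C(4,2) orderings
  # identical groups: U = n1 n2 / 2
  sc2 <- c(a = 1, b = 2, c = 1, d = 2)
  gt2 <- suppressWarnings(compare_groups(sc2, c(a = "x", b = "x",
                                                c = "y", d = "y")))
  expect_gte(gt2$p, 0.99)
  # three groups -> Kruskal-Wallis
  sc3 <- setNames(1:9, letters[1:9])
  g3 <- setNames(rep(c("p", "q", "r"), each = 3), letters[1:9])
  expect_equal(compare_groups(sc3, g3)$test, "kruskal-wallis")
  expect_error(compare_groups(sc, c(a = "x", b = "x", c = "x", d = "x")),
               "2 non-empty")
})

test_that("Mann-Whitney U statistics from the two orientations sum to n1*n2", {
  set.seed(18)
  for (i in 1:5) {
    x <- rnorm(7); y <- rnorm(9)
    sc <- setNames(c(x, y), paste0("s", 1:16))
    lab <- setNames(rep(c("x", "y"), c(7, 9)), names(sc))
    u1 <- compare_groups(sc, lab)$statistic
    lab2 <- setNames(rep(c("y", "x"), c(7, 9)), names(sc))
    # swapping labels gives the complementary U
    u2 <- compare_groups(sc, factor(lab, levels = c("y", "x")))$statistic
    expect_equal(u1 + u2, 7 * 9)
  }
})

test_that("pooled-variance t test matches the hand example and symmetry", {
  tt <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$t, -3.6742, tolerance = 1e-4)
  expect_equal(tt$df, 4)
  expect_equal(two_sample_t(c(1, 2), c(1, 2))$t,
               -two_sample_t(c(1, 2), c(1, 2))$t)  # 0 by symmetry
  same <- two_sample_t(c(2, 2), c(2, 2))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  expect_error(two_sample_t(c(1, 1), c(2, 2)), "zero pooled variance")
  sw <- two_sample_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(sw$t, -tt$t)
})
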