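# Synthetic-data generators with recorded ground truth. All generators are
# pure functions of (parameters, seed): the RNG state is scoped locally so
# identical calls give bit-identical output.

#' Generate a synthetic genome annotation
#'
#' Genes are laid on `n_chroms` chromosomes at fixed spacing, with random
#' strand, 2-5 exons and terminal UTR annotations, so promoter windows and
#' gene-body features behave like a sparse real annotation.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_chroms Number of chromosomes (default 2).
#' @param gene_span Gene length in bp (default 10000).
#' @param spacing Distance between successive gene starts in bp (default
#'   30000; must exceed `gene_span`).
#' @param seed Integer seed.
#' @return A `genome_annotation` with `chrom_lengths` set.
#' @export
make_genome <- function(n_genes = 2000L, n_chroms = 2L, gene_span = 10000L,
                        spacing = 30000L, seed = 1L) {
  stopifnot(n_genes > 0, n_chroms > 0, gene_span > 0)
  if (spacing < gene_span) stop_ctx("make_genome: spacing < gene_span")
  with_seed(seed, {
    per <- ceiling(n_genes / n_chroms)
    idx <- seq_len(n_genes) - 1L
    chrom <- paste0("chr", idx %/% per + 1L)
    pos <- idx %% per
    start <- 10000L + pos * as.integer(spacing)
    end <- start + as.integer(gene_span)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    gid <- sprintf("G%04d", seq_len(n_genes))
    genes <- data.frame(gene_id = gid, symbol = gid, chrom = chrom,
                        strand = strand, start = start, end = end,
                        stringsAsFactors = FALSE)
    exons <- utr5 <- utr3 <- list()
    for (i in seq_len(n_genes)) {
      n_ex <- sample(2:5, 1)
      cuts <- sort(sample(seq(200L, gene_span - 200L, by = 50L),
                          2L * (n_ex - 1L)))
      es <- start[i] + c(0L, cuts[seq(2, length(cuts), by = 2)])
      ee <- start[i] + c(cuts[seq(1, length(cuts), by = 2)], gene_span)
      exons[[i]] <- data.frame(gene_id = gid[i], start = es, end = ee,
                               stringsAsFactors = FALSE)
      u_len <- sample(80:150, 2)
      first <- c(es[1], min(ee[1], es[1] + u_len[1]))
      last <- c(max(es[n_ex], ee[n_ex] - u_len[2]), ee[n_ex])
      if (strand[i] == "+") {
        utr5[[i]] <- data.frame(gene_id = gid[i], start = first[1],
                                end = first[2], stringsAsFactors = FALSE)
        utr3[[i]] <- data.frame(gene_id = gid[i], start = last[1],
                                end = last[2], stringsAsFactors = FALSE)
      } else {
        utr5[[i]] <- data.frame(gene_id = gid[i], start = last[1],
                                end = last[2], stringsAsFactors = FALSE)
        utr3[[i]] <- data.frame(gene_id = gid[i], start = first[1],
                                end = first[2], stringsAsFactors = FALSE)
      }
    }
    cl <- tapply(end, chrom, max) + as.integer(spacing)
    ann <- list(genes = genes, exons = do.call(rbind, exons),
                utr5 = do.call(rbind, utr5), utr3 = do.call(rbind, utr3),
                chrom_lengths = setNames(as.integer(cl), names(cl)))
    class(ann) <- "genome_annotation"
    ann
  })
}

#' Simulate a multi-condition RNA-seq count experiment
#'
#' Counts are negative-binomial with mean
#' `s_j * mu_g * 2^lfc` (the planted log2 fold change applies in the
#' condition named by `de_spec`) and constant dispersion `alpha`
#' (`variance = mu + alpha mu^2`). The default design mirrors a 4-condition,
#' 2-replicate experiment.
#'
#' @param ann A `genome_annotation` supplying gene symbols.
#' @param conditions Condition labels (default EV, WT, S65P, S65W).
#' @param reps Replicates per condition (default 2).
#' @param de_spec data.frame with columns `gene`, `condition`, `log2fc`
#'   giving the planted effects (empty for a null dataset).
#' @param base_mean_range Range for log-uniform baseline means.
#' @param alpha NB dispersion (default 0.05).
#' @param lib_size_factors Optional per-sample library factors; default
#'   mild log-normal variation.
#' @param seed Integer seed.
#' @return List with `cm` (a `count_matrix`) and `truth` (planted effects,
#'   baseline means, library factors, seed).
#' @export
simulate_counts <- function(ann, conditions = c("EV", "WT", "S65P", "S65W"),
                            reps = 2L,
                            de_spec = data.frame(gene = character(0),
                                                 condition = character(0),
                                                 log2fc = numeric(0)),
                            base_mean_range = c(10, 1000), alpha = 0.05,
                            lib_size_factors = NULL, seed = 1L) {
  stopifnot(reps >= 2L)
  genes <- ann$genes$symbol
  n_s <- length(conditions) * reps
  cond <- rep(conditions, each = reps)
  samples <- paste0(cond, "_r", rep(seq_len(reps), length(conditions)))
  with_seed(seed, {
    mu <- exp(runif(length(genes), log(base_mean_range[1]),
                    log(base_mean_range[2])))
    if (is.null(lib_size_factors))
      lib_size_factors <- exp(rnorm(n_s, 0, 0.1))
    lfc <- matrix(0, length(genes), n_s,
                  dimnames = list(genes, samples))
    if (nrow(de_spec)) {
      for (i in seq_len(nrow(de_spec))) {
        gi <- match(de_spec$gene[i], genes)
        if (is.na(gi)) stop_ctx("de_spec gene not in annotation: ",
                                de_spec$gene[i])
        lfc[gi, cond == de_spec$condition[i]] <- de_spec$log2fc[i]
      }
    }
    m <- sweep(mu * 2^lfc, 2, lib_size_factors, "*")
    k <- matrix(rnbinom(length(m), mu = m, size = 1 / alpha),
                nrow(m), ncol(m), dimnames = dimnames(m))
    list(cm = count_matrix(k, cond),
         truth = list(de_spec = de_spec, base_mean = setNames(mu, genes),
                      lib_size_factors = setNames(lib_size_factors, samples),
                      alpha = alpha, seed = seed))
  })
}

#' Simulate ChIP-seq peaks with planted promoter binding
#'
#' Each target gene gets one 400-bp peak whose summit falls inside
#' TSS +/- `window`; background peaks are placed with a controlled fraction
#' promoter-proximal (summit within 3 kb of some TSS) and the rest uniform
#' over non-promoter space.
#'
#' @param ann A `genome_annotation` (needs `chrom_lengths`).
#' @param target_genes Symbols receiving a planted promoter peak.
#' @param window Half-width of the planting window in bp (default 5000).
#' @param n_background Number of background peaks (default 500).
#' @param frac_promoter_background Fraction of background peaks placed
#'   promoter-proximal (default 0.1).
#' @param exclude_genes Genes whose TSS +/- `window` neighbourhood
#'   background summits must avoid (keeps truth categories disjoint: a
#'   gene without a planted peak stays peak-free at the declared window).
#' @param seed Integer seed.
#' @return List with `peaks` (a `peak_set`) and `truth` (per-target summit
#'   positions, seed).
#' @export
simulate_peaks <- function(ann, target_genes, window = 5000L,
                           n_background = 500L,
                           frac_promoter_background = 0.1,
                           exclude_genes = character(0), seed = 1L) {
  if (window <= 0) stop_ctx("simulate_peaks: window must be > 0")
  g <- ann$genes
  if (!all(target_genes %in% g$symbol))
    stop_ctx("simulate_peaks: target gene not in annotation")
  half <- 200L
  with_seed(seed, {
    ti <- match(target_genes, g$symbol)
    tss <- tss_position(g[ti, , drop = FALSE])
    summit <- tss + sample(seq(-window + 1L, window - 1L), length(ti),
                           replace = TRUE)
    summit <- pmax(summit, half)
    tp <- peaks(chrom = g$chrom[ti], start = summit - half,
                end = summit + half,
                name = paste0("target_", g$symbol[ti]),
                score = runif(length(ti), 50, 500),
                summit_offset = rep(half, length(ti)))
    bg <- NULL
    if (n_background > 0) {
      all_tss <- tss_position(g)
      excl <- g$symbol %in% c(exclude_genes, target_genes)
      is_prom <- runif(n_background) < frac_promoter_background
      bchrom <- character(n_background); bsummit <- integer(n_background)
      avoid <- function(ch, pos) {
        near <- which(g$chrom == ch & excl)
        length(near) == 0 || all(abs(all_tss[near] - pos) > window)
      }
      for (i in seq_len(n_background)) {
        if (is_prom[i]) {
          repeat {
            j <- sample(which(!excl), 1)
            pos <- all_tss[j] + sample(seq(-3000L, 3000L), 1)
            if (avoid(g$chrom[j], pos)) { bchrom[i] <- g$chrom[j]
              bsummit[i] <- pos; break }
          }
        } else {
          repeat {
            ch <- sample(names(ann$chrom_lengths), 1)
            pos <- sample.int(ann$chrom_lengths[[ch]] - 2L * half, 1) + half
            near <- abs(all_tss[g$chrom == ch] - pos)
            if (all(near > 3000L + half) && avoid(ch, pos)) { bchrom[i] <- ch
              bsummit[i] <- pos; break }
          }
        }
      }
      bsummit <- pmax(bsummit, half)
      bg <- peaks(chrom = bchrom, start = bsummit - half,
                  end = bsummit + half,
                  name = paste0("bg_", seq_len(n_background)),
                  score = runif(n_background, 20, 200),
                  summit_offset = rep(half, n_background))
    }
    pk <- if (is.null(bg)) tp else {
      both <- rbind(as.data.frame(tp), as.data.frame(bg))
      class(both) <- c("peak_set", "data.frame"); both
    }
    list(peaks = pk,
         truth = list(targets = setNames(summit, target_genes),
                      is_promoter_background = if (n_background > 0) is_prom
                      else logical(0), seed = seed))
  })
}

#' Simulate a patient cohort with planted signature, EMT, hypoxia and
#' survival structure
#'
#' Each sample carries a latent signature-activity axis (shifted upward in
#' tumors), plus EMT and hypoxia axes correlated with the standardized
#' activity at the requested levels. Signature genes express
#' `sign(weight) * activity`, EMT genes `+/- EMT axis`, hypoxia genes the
#' hypoxia axis, background genes nothing -- all plus unit Gaussian noise.
#' Survival is exponential with hazard proportional to
#' `exp(cox_beta * standardized activity)`, with uniform censoring
#' calibrated to the requested censored fraction.
#'
#' @param sig A `signature` (non-empty).
#' @param n Cohort size (default 300).
#' @param tumor_frac Fraction of tumor samples (default 0.7).
#' @param tumor_shift Upward shift of tumor activity, in SD units (default 1.5).
#' @param r_emt,r_hypoxia Latent correlations with activity (default 0.6).
#' @param cox_beta True log hazard ratio per SD of activity (default 0.7).
#' @param censor_frac Target censored fraction (default 0.3).
#' @param n_emt Genes per EMT side (default 38, i.e. a 76-gene signed set).
#' @param n_hypoxia Hypoxia signature size (default 50).
#' @param n_background Background genes (default 200).
#' @param seed Integer seed.
#' @return List: `expr` (genes x samples), `clinical` (sample, time, event,
#'   group), `emt_set` (signed weights), `hypoxia_genes`, `truth` (latent
#'   axes and parameters).
#' @export
simulate_cohort <- function(sig, n = 300L, tumor_frac = 0.7,
                            tumor_shift = 1.5, r_emt = 0.6, r_hypoxia = 0.6,
                            cox_beta = 0.7, censor_frac = 0.3, n_emt = 38L,
                            n_hypoxia = 50L, n_background = 200L, seed = 1L) {
  if (!nrow(sig)) stop_ctx("simulate_cohort: empty signature")
  with_seed(seed, {
    samples <- sprintf("S%03d", seq_len(n))
    tumor <- rbinom(n, 1, tumor_frac)
    act <- rnorm(n) + tumor_shift * tumor
    a_std <- as.numeric(scale(act))
    mix <- function(r) r * a_std + sqrt(1 - r^2) * rnorm(n)
    emt_axis <- mix(r_emt)
    hyp_axis <- mix(r_hypoxia)
    mes <- sprintf("MES%02d", seq_len(n_emt))
    epi <- sprintf("EPI%02d", seq_len(n_emt))
    hyp <- sprintf("HYP%02d", seq_len(n_hypoxia))
    bgg <- sprintf("BGG%03d", seq_len(n_background))
    rows <- c(sig$gene, mes, epi, hyp, bgg)
    expr <- matrix(rnorm(length(rows) * n), length(rows), n,
                   dimnames = list(rows, samples))
    expr[sig$gene, ] <- expr[sig$gene, ] +
      outer(sign(sig$weight), act)
    expr[mes, ] <- expr[mes, ] + rep(1, n_emt) %o% emt_axis
    expr[epi, ] <- expr[epi, ] - rep(1, n_emt) %o% emt_axis
    expr[hyp, ] <- expr[hyp, ] + rep(1, n_hypoxia) %o% hyp_axis
    tt <- rexp(n, rate = 0.1 * exp(cox_beta * a_std))
    u <- runif(n)
    ratio <- tt / u
    m <- quantile(ratio, 1 - censor_frac, names = FALSE)
    cens <- u * m
    time <- pmin(tt, cens)
    event <- as.integer(tt <= cens)
    clinical <- data.frame(sample = samples, time = time, event = event,
                           group = ifelse(tumor == 1, "tumor", "normal"),
                           stringsAsFactors = FALSE)
    emt_set <- setNames(c(rep(1, n_emt), rep(-1, n_emt)), c(mes, epi))
    list(expr = expr, clinical = clinical, emt_set = emt_set,
         hypoxia_genes = hyp,
         truth = list(activity = setNames(act, samples),
                      emt_axis = setNames(emt_axis, samples),
                      hypoxia_axis = setNames(hyp_axis, samples),
                      tumor = setNames(tumor, samples),
                      cox_beta = cox_beta, r_emt = r_emt,
                      r_hypoxia = r_hypoxia, seed = seed))
  })
}

#' Simulate a complete study (counts, peaks, cohort) with ground truth
#'
#' The `"paperlike"` preset mirrors the study design the pipeline targets:
#' a 4-condition (EV, WT, S65P, S65W) x 2-replicate count experiment on a
#' 2000-gene genome, 30 planted direct targets of the S65W condition
#' (differentially expressed and promoter-bound), 20 DE-only genes, 20
#' peak-only genes, background peaks, and a 300-sample cohort generated
#' from the true direct-target signature.
#'
#' @param preset Currently `"paperlike"`.
#' @param seed Integer seed; stage seeds are derived from it.
#' @return List: `ann`, `cm`, `peaks`, `cohort`, `truth` (with
#'   `direct_targets`, `de_only`, `peak_only`, per-stage seeds).
#' @export
simulate_study <- function(preset = "paperlike", seed = 1L) {
  preset <- match.arg(preset)
  seed <- as.integer(seed)
  ann <- make_genome(n_genes = 2000L, seed = seed)
  syms <- ann$genes$symbol
  direct <- syms[seq(1, 600, by = 20)]          # 30 direct targets
  de_only <- syms[seq(601, 950, length.out = 20)]
  peak_only <- syms[seq(1001, 1350, length.out = 20)]
  lfc_direct <- rep(c(2.5, -2.5), c(20, 10))
  lfc_de_only <- rep(c(2.2, -2.2), c(12, 8))
  de_spec <- data.frame(
    gene = c(direct, de_only),
    condition = "S65W",
    log2fc = c(lfc_direct, lfc_de_only),
    stringsAsFactors = FALSE)
  counts <- simulate_counts(ann, de_spec = de_spec,
                            base_mean_range = c(50, 800), alpha = 0.05,
                            seed = seed + 1L)
  pk <- simulate_peaks(ann, target_genes = c(direct, peak_only),
                       n_background = 500L, exclude_genes = de_only,
                       seed = seed + 2L)
  truth <- list(direct_targets = direct, de_only = de_only,
                peak_only = peak_only, de_spec = de_spec,
                counts = counts$truth, peaks = pk$truth,
                seed = seed)
  list(ann = ann, cm = counts$cm, peaks = pk$peaks, truth = truth)
}
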