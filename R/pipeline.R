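# One-config orchestration of the full analysis: annotate -> DE -> GSEA ->
# signature -> cohort scoring -> survival, with derived per-stage seeds,
# logged parameters and a checksum manifest.

pipeline_defaults <- list(fdr = 0.05, lfc = 1.0, window = 5000L,
                          perms = 1000L, max_size = 5000L, min_size = 5L,
                          seed = 1L)

#' Validate a pipeline configuration
#'
#' Fills defaults (`fdr` 0.05, `lfc` 1, `window` 5000, `perms` 1000,
#' `max_size` 5000, `min_size` 5, `seed` 1), checks every referenced path
#' and parameter range, and reports all problems in a single error.
#'
#' @param config Path to a YAML config file, or an equivalent named list
#'   with elements `paths` (counts, samples, peaks, gtf; optionally gmt,
#'   cohort, clinical, emt, hypoxia), `params` (contrast and any defaults
#'   to override) and `outdir`.
#' @return The validated config (class `pipeline_config`) with defaults
#'   filled.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  problems <- character(0)
  paths <- config$paths
  for (p in c("counts", "samples", "peaks", "gtf")) {
    if (is.null(paths[[p]]))
      problems <- c(problems, paste0("missing required path: ", p))
  }
  for (p in names(paths)) {
    if (!is.null(paths[[p]]) && !file.exists(paths[[p]]))
      problems <- c(problems, paste0("file not found: ", p, " = ", paths[[p]]))
  }
  params <- config$params
  for (nm in names(pipeline_defaults))
    if (is.null(params[[nm]])) params[[nm]] <- pipeline_defaults[[nm]]
  if (is.null(params$contrast))
    problems <- c(problems, "missing params$contrast (e.g. 'S65W,WT')")
  else if (is.character(params$contrast) && length(params$contrast) == 1L)
    params$contrast <- strsplit(params$contrast, ",")[[1]]
  if (length(params$contrast) != 2L && !is.null(params$contrast))
    problems <- c(problems, "contrast must name exactly two conditions")
  chk <- function(nm, lo, hi) {
    v <- params[[nm]]
    if (!is.numeric(v) || v < lo || v > hi)
      problems <<- c(problems, paste0("parameter out of range: ", nm, " = ", v))
  }
  chk("fdr", 1e-10, 1); chk("lfc", 0, Inf); chk("window", 1, Inf)
  chk("perms", 100, Inf); chk("max_size", 1, Inf); chk("min_size", 1, Inf)
  if (is.null(config$outdir)) problems <- c(problems, "missing outdir")
  if (length(problems))
    stop_ctx("invalid pipeline config:\n  - ",
             paste(problems, collapse = "\n  - "))
  out <- list(paths = paths, params = params, outdir = config$outdir)
  class(out) <- "pipeline_config"
  log_msg("effective config: contrast=", paste(params$contrast, collapse = " vs "),
          " fdr=", params$fdr, " lfc=", params$lfc, " window=", params$window,
          " perms=", params$perms, " seed=", params$seed)
  out
}

#' Run the full signature-discovery pipeline
#'
#' Stages: peak annotation; NB-Wald differential expression for the
#' configured contrast; preranked GSEA of the Wald-statistic ranking
#' (when a GMT is configured); direct-target signature construction
#' (DE genes with promoter binding at TSS +/- window); cohort scoring with
#' EMT/hypoxia correlation and tumor-vs-normal tests (when a cohort is
#' configured); and median-split signature survival analysis (when a
#' clinical table is configured). Every stage writes its TSV before the
#' next starts, so a failure preserves completed intermediates; a
#' `manifest.json` records parameters, derived stage seeds and output
#' checksums. Identical config and seed give identical checksums.
#'
#' @param config A `pipeline_config` (or anything [validate_config()]
#'   accepts).
#' @return The manifest, invisibly (list with `outputs`, `params`,
#'   `checksums`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  pp <- config$params
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()
  stage <- function(name, expr) {
    log_msg("stage ", name, ": start")
    tryCatch(expr, error = function(e)
      stop_ctx("pipeline halted at stage '", name, "': ",
               conditionMessage(e)))
  }
  out_path <- function(f) file.path(config$outdir, f)

  ann <- stage("load", read_gene_model(config$paths$gtf))
  pk <- stage("load", read_bed(config$paths$peaks))

  annot <- stage("annotate", {
    a <- annotate_peaks(pk, ann)
    write.table(a[, c("name", "chrom", "start", "end", "category",
                      "nearest_gene", "tss_distance")],
                out_path("annotation.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    s <- annotation_summary(pk, ann)
    write.table(data.frame(category = names(s), fraction = fmt_num(s)),
                out_path("annotation_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    outputs$annotation <- out_path("annotation.tsv")
    outputs$annotation_summary <- out_path("annotation_summary.tsv")
    a
  })

  de <- stage("de", {
    counts <- read_matrix(config$paths$counts, counts = TRUE)
    st <- read.delim(config$paths$samples, stringsAsFactors = FALSE)
    if (!all(c("sample", "condition") %in% names(st)))
      stop_ctx("samples table needs columns sample, condition")
    cm <- count_matrix(counts[, st$sample, drop = FALSE], st$condition)
    cm <- filter_low_counts(cm)
    sf <- size_factors(cm)
    disp <- estimate_dispersions(cm, sf)
    res <- nb_wald_test(cm, pp$contrast, disp, sf)
    calls <- call_de(res, pp$fdr, pp$lfc)
    out <- as.data.frame(res)
    out$call <- "ns"
    out$call[out$gene %in% calls$up] <- "up"
    out$call[out$gene %in% calls$down] <- "down"
    for (cc in c("base_mean", "log2fc", "se", "wald_stat", "pvalue", "padj"))
      out[[cc]] <- fmt_num(out[[cc]])
    write.table(out, out_path("de.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    outputs$de <- out_path("de.tsv")
    vst <- vst_transform(cm, sf, disp)
    write_matrix(sample_distance_matrix(vst), out_path("sample_distances.tsv"))
    outputs$sample_distances <- out_path("sample_distances.tsv")
    res
  })

  if (!is.null(config$paths$gmt)) {
    stage("gsea", {
      sets <- read_gmt(config$paths$gmt)
      ok <- !is.na(de$wald_stat)
      rk <- ranked_list(setNames(de$wald_stat[ok], de$gene[ok]))
      gr <- preranked_gsea(rk, sets, n_perm = pp$perms,
                           max_size = pp$max_size, min_size = pp$min_size,
                           seed = pp$seed + 3L)
      out <- as.data.frame(gr)
      for (cc in c("es", "nes", "pvalue", "fdr")) out[[cc]] <- fmt_num(out[[cc]])
      write.table(out, out_path("gsea.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      outputs$gsea <- out_path("gsea.tsv")
    })
  }

  sig <- stage("signature", {
    pmap <- map_peaks_to_genes(pk, ann, window = pp$window)
    s <- build_signature(de, pmap, fdr = pp$fdr, lfc = pp$lfc)
    if (!nrow(s)) stop_ctx("empty signature")
    write_signature(s, out_path("signature.tsv"))
    outputs$signature <- out_path("signature.tsv")
    s
  })

  if (!is.null(config$paths$cohort)) {
    stage("score", {
      expr <- read_matrix(config$paths$cohort)
      z <- zscore_normalize(expr)
      sc <- signature_score(z, sig)
      tab <- data.frame(sample = names(sc), signature = fmt_num(sc),
                        stringsAsFactors = FALSE)
      assoc <- character(0)
      if (!is.null(config$paths$emt)) {
        es <- emt_score(z, read_signed_set(config$paths$emt))
        tab$emt <- fmt_num(es[tab$sample])
        pc <- pearson_correlation(sc, es)
        assoc <- c(assoc, paste0("signature_emt_pearson_r\t", fmt_num(pc$r),
                                 "\t", fmt_num(pc$p)))
      }
      if (!is.null(config$paths$hypoxia)) {
        hs <- hypoxia_score(expr, names(read_signed_set(config$paths$hypoxia)))
        tab$hypoxia <- fmt_num(hs[tab$sample])
        pc <- pearson_correlation(sc, hs)
        assoc <- c(assoc, paste0("signature_hypoxia_pearson_r\t",
                                 fmt_num(pc$r), "\t", fmt_num(pc$p)))
      }
      if (!is.null(config$paths$clinical)) {
        cl <- read_clinical(config$paths$clinical)
        if (!is.null(cl$group)) {
          gl <- setNames(cl$group, cl$sample)
          common <- intersect(names(sc), names(gl))
          gt <- compare_groups(sc[common], gl[common])
          assoc <- c(assoc, paste0("group_test_", gt$test, "\t",
                                   fmt_num(gt$statistic), "\t", fmt_num(gt$p)))
        }
      }
      write.table(tab, out_path("scores.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      outputs$scores <- out_path("scores.tsv")
      if (length(assoc)) {
        writeLines(c("test\tstatistic\tp", assoc), out_path("associations.tsv"))
        outputs$associations <- out_path("associations.tsv")
      }
    })
  }

  if (!is.null(config$paths$cohort) && !is.null(config$paths$clinical)) {
    stage("survive", {
      expr <- read_matrix(config$paths$cohort)
      cl <- read_clinical(config$paths$clinical)
      sv <- signature_survival(expr, sig, cl)
      out <- data.frame(
        logrank_chi2 = fmt_num(sv$logrank$chisq),
        logrank_p = fmt_num(sv$logrank$p),
        cox_beta = fmt_num(sv$cox$beta), hr = fmt_num(sv$cox$hr),
        ci_low = fmt_num(sv$cox$ci[1]), ci_high = fmt_num(sv$cox$ci[2]),
        cox_p = fmt_num(sv$cox$p), n_high = sv$n_high, n_low = sv$n_low)
      write.table(out, out_path("survival.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      km <- rbind(cbind(stratum = "high", as.data.frame(sv$km_high)),
                  cbind(stratum = "low", as.data.frame(sv$km_low)))
      km$surv <- fmt_num(km$surv); km$time <- fmt_num(km$time)
      write.table(km, out_path("km.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      outputs$survival <- out_path("survival.tsv")
      outputs$km <- out_path("km.tsv")
    })
  }

  manifest <- list(params = pp, outputs = outputs,
                   checksums = as.list(tools::md5sum(unlist(outputs))))
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_msg("pipeline complete: ", length(outputs), " outputs in ",
          config$outdir)
  invisible(manifest)
}
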