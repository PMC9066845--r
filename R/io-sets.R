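#' Read a gene-set collection from a GMT file
#'
#' One set per line: name, description, then member gene symbols, all
#' tab-separated. Duplicate symbols within a line are removed with a warning;
#' duplicate set names across lines are an error.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (class `gene_set_collection`),
#'   with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_ctx("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop_ctx("GMT parse error at line ", bad[1],
             ": need name, description and at least one gene")
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop_ctx("GMT error: duplicate set name ", nm[duplicated(nm)][1])
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(seq_along(fields), function(i) {
    g <- fields[[i]][-(1:2)]
    g <- g[nzchar(g)]
    if (anyDuplicated(g)) {
      warning("GMT set ", nm[i], ": duplicate gene symbols removed",
              call. = FALSE)
      g <- unique(g)
    }
    if (!length(g)) stop_ctx("GMT set ", nm[i], " has no gene symbols")
    g
  })
  names(sets) <- nm
  attr(sets, "descriptions") <- setNames(desc, nm)
  class(sets) <- "gene_set_collection"
  sets
}

#' Write a gene-set collection to GMT
#' @param sets Named list of character vectors.
#' @param path Output file path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- setNames(rep("na", length(sets)), names(sets))
  writeLines(vapply(names(sets), function(n)
    paste(c(n, desc[[n]], sets[[n]]), collapse = "\t"), ""), path)
  invisible(path)
}

#' Read a signed gene set (two-column TSV: gene, weight)
#'
#' Used for signed EMT signatures (positive weight = mesenchymal,
#' negative = epithelial). Weights must be finite and nonzero; symbols unique.
#'
#' @param path Path to a header-bearing TSV with columns `gene` and `weight`.
#' @return Named numeric vector of weights.
#' @export
read_signed_set <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "weight") %in% names(df)))
    stop_ctx("signed gene set needs columns 'gene' and 'weight'")
  w <- as.numeric(df$weight)
  if (any(!is.finite(w)) || any(w == 0))
    stop_ctx("signed gene set weights must be finite and nonzero")
  if (anyDuplicated(df$gene))
    stop_ctx("signed gene set has duplicate symbols")
  setNames(w, df$gene)
}

#' Write a signed gene set
#' @param w Named numeric vector.
#' @param path Output file path.
#' @export
write_signed_set <- function(w, path) {
  write.table(data.frame(gene = names(w), weight = fmt_num(w)), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genes-by-samples matrix from TSV
#'
#' Header row holds sample names; first column holds gene symbols. In counts
#' mode cells must be non-negative integers.
#'
#' @param path Path to the TSV.
#' @param counts If `TRUE`, validate cells as non-negative integers.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_matrix <- function(path, counts = FALSE) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop_ctx("matrix needs a gene column plus >=1 sample")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes))
    stop_ctx("duplicate gene symbol in matrix: ", genes[duplicated(genes)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_ctx("non-numeric cells in matrix")
  if (any(is.na(m))) stop_ctx("missing values in matrix")
  if (counts) {
    if (any(m < 0)) stop_ctx("negative counts in counts matrix")
    if (any(m != round(m)))
      stop_ctx("non-integer value in counts matrix (e.g. ",
               m[which(m != round(m))[1]], ")")
    storage.mode(m) <- "integer"
  }
  rownames(m) <- genes
  m
}

#' Write a genes-by-samples matrix to TSV
#' @param m Matrix with rownames and colnames.
#' @param path Output file path.
#' @param digits If `TRUE`, format floats at 6 significant digits.
#' @export
write_matrix <- function(m, path, digits = !is.integer(m)) {
  vals <- if (digits) apply(m, 2, fmt_num) else m
  df <- data.frame(gene = rownames(m), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table (sample, time, event, optional group/stage)
#'
#' Rows with missing time or event are excluded with a logged count; time
#' must be positive and event must be 0 (censored) or 1 (event).
#'
#' @param path Path to a header-bearing TSV.
#' @return data.frame with columns `sample`, `time`, `event` and any optional
#'   columns present; attribute `n_excluded` records dropped rows.
#' @export
read_clinical <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "time", "event")
  if (!all(need %in% names(df)))
    stop_ctx("clinical table needs columns: ", paste(need, collapse = ", "))
  miss <- is.na(df$time) | is.na(df$event)
  n_excluded <- sum(miss)
  if (n_excluded > 0)
    log_msg("read_clinical: excluded ", n_excluded,
            " sample(s) with missing time/event")
  df <- df[!miss, , drop = FALSE]
  if (any(df$time <= 0)) stop_ctx("clinical time must be > 0")
  if (!all(df$event %in% c(0, 1))) stop_ctx("clinical event must be 0 or 1")
  if (anyDuplicated(df$sample)) stop_ctx("duplicate sample ids in clinical table")
  attr(df, "n_excluded") <- n_excluded
  df
}

#' Write a clinical table
#' @param df Clinical data.frame.
#' @param path Output file path.
#' @export
write_clinical <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
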