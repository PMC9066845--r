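#' Read peak intervals from a BED or narrowPeak file
#'
#' Parses BED3/BED5 and 10-column narrowPeak files into a peak table on the
#' internal 0-based half-open coordinate convention (identical to the BED
#' convention, so coordinates pass through unchanged). Comment lines starting
#' with `#`, `track` or `browser` are skipped. For narrowPeak input the summit
#' offset (column 10) is captured; a value of -1 (no summit called) is treated
#' as absent.
#'
#' @param path Path to a tab-separated BED3+/narrowPeak file.
#' @return A `data.frame` of class `peak_set` with columns `chrom`, `start`,
#'   `end`, `name`, `score`, `strand`, `summit_offset`; rows in file order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_ctx("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_peaks())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  bad <- which(ncol < 3L)
  if (length(bad))
    stop_ctx("BED parse error at line ", lineno[bad[1]],
             ": fewer than 3 columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop_ctx("BED parse error at line ", lineno[bad[1]],
             ": non-integer coordinates")
  bad <- which(start < 0L | end <= start)
  if (length(bad))
    stop_ctx("BED parse error at line ", lineno[bad[1]],
             ": require 0 <= start < end")
  opt <- function(i, as = identity) {
    ifelse(ncol >= i, vapply(fields, function(f) if (length(f) >= i) f[[i]] else NA_character_, ""), NA_character_)
  }
  name <- opt(4L)
  score <- suppressWarnings(as.numeric(opt(5L)))
  strand <- opt(6L)
  strand[!strand %in% c("+", "-", ".")] <- NA_character_
  summit <- rep(NA_integer_, length(lines))
  np <- which(ncol >= 10L)
  if (length(np)) {
    sv <- suppressWarnings(as.integer(vapply(fields[np], `[[`, "", 10L)))
    bad <- np[which(!is.na(sv) & sv >= 0L & sv >= (end[np] - start[np]))]
    if (length(bad))
      stop_ctx("BED parse error at line ", lineno[bad[1]],
               ": summit offset outside peak")
    sv[!is.na(sv) & sv < 0L] <- NA_integer_
    summit[np] <- sv
  }
  peaks(chrom = chrom, start = start, end = end, name = name,
        score = score, strand = strand, summit_offset = summit)
}

#' Construct a peak table
#'
#' @param chrom,start,end Required coordinate vectors (0-based half-open).
#' @param name,score,strand,summit_offset Optional per-peak annotations.
#' @return A `peak_set` data.frame.
#' @export
peaks <- function(chrom, start, end, name = NA_character_, score = NA_real_,
                  strand = NA_character_, summit_offset = NA_integer_) {
  if (any(start < 0L) || any(end <= start))
    stop_ctx("invalid peak: require 0 <= start < end")
  n <- length(chrom)
  name <- rep_len(name, n); score <- rep_len(score, n)
  strand <- rep_len(strand, n)
  so <- as.integer(rep_len(summit_offset, n))
  bad <- !is.na(so) & (so < 0L | so >= (end - start))
  if (any(bad)) stop_ctx("summit offset outside [0, end - start)")
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), name = as.character(name),
                   score = as.numeric(score), strand = as.character(strand),
                   summit_offset = so, stringsAsFactors = FALSE)
  class(df) <- c("peak_set", "data.frame")
  df
}

empty_peaks <- function() {
  peaks(character(0), integer(0), integer(0), character(0), numeric(0),
        character(0), integer(0))
}

#' Write peaks back to BED/narrowPeak
#'
#' Mirrors [read_bed()]: emits narrowPeak (10 columns) when any summit offset
#' is present, BED5/BED6 otherwise. Output is bit-stable for identical input.
#'
#' @param x A `peak_set` data.frame.
#' @param path Output file path.
#' @export
write_bed <- function(x, path) {
  nm <- ifelse(is.na(x$name), ".", x$name)
  sc <- ifelse(is.na(x$score), "0", fmt_num(x$score))
  st <- ifelse(is.na(x$strand), ".", x$strand)
  if (any(!is.na(x$summit_offset))) {
    lines <- paste(x$chrom, x$start, x$end, nm, sc, st, "0", "-1", "-1",
                   ifelse(is.na(x$summit_offset), -1L, x$summit_offset),
                   sep = "\t")
  } else if (all(is.na(x$strand))) {
    lines <- paste(x$chrom, x$start, x$end, nm, sc, sep = "\t")
  } else {
    lines <- paste(x$chrom, x$start, x$end, nm, sc, st, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

# Anchor position used for annotation: summit if present, else midpoint.
peak_anchor <- function(x) {
  mid <- x$start + (x$end - x$start) %/% 2L
  ifelse(is.na(x$summit_offset), mid, x$start + x$summit_offset)
}
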