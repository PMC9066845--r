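#' @keywords internal
"_PACKAGE"

#' @importFrom stats median quantile rnorm runif rnbinom rexp rbinom sd var
#'   pnorm pchisq p.adjust cor.test wilcox.test kruskal.test t.test dist
#'   setNames complete.cases lm coef uniroot
#' @importFrom utils read.delim write.table head
NULL

# Log to stderr with a timestamp; results never go to stdout.
log_msg <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards so generators are pure functions of (params, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Fixed float formatting (6 significant digits) so writers are bit-stable.
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
}

stop_ctx <- function(...) stop(..., call. = FALSE)
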