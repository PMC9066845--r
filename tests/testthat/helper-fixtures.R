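# Shared fixture builders: everything is generated in code at test time.

# A two-gene annotation: G1 on +, G2 on -, with exons and UTRs.
tiny_annotation <- function() {
  tmp <- tempfile(fileext = ".gtf")
  writeLines(c(
    "# synthetic two-gene model",
    paste("chr1", "src", "gene", 10001, 20000, ".", "+", ".",
          'gene_id "G1"; gene_name "G1";', sep = "\t"),
    paste("chr1", "src", "exon", 10001, 10500, ".", "+", ".",
          'gene_id "G1";', sep = "\t"),
    paste("chr1", "src", "exon", 15001, 20000, ".", "+", ".",
          'gene_id "G1";', sep = "\t"),
    paste("chr1", "src", "five_prime_utr", 10001, 10100, ".", "+", ".",
          'gene_id "G1";', sep = "\t"),
    paste("chr1", "src", "three_prime_utr", 19801, 20000, ".", "+", ".",
          'gene_id "G1";', sep = "\t"),
    paste("chr1", "src", "gene", 100001, 110000, ".", "-", ".",
          'gene_id "G2"; gene_name "G2";', sep = "\t"),
    paste("chr1", "src", "exon", 100001, 110000, ".", "-", ".",
          'gene_id "G2";', sep = "\t")
  ), tmp)
  read_gene_model(tmp)
}

# Write a peak_set out as a temp narrowPeak/BED and return the path.
write_tmp_bed <- function(pk) {
  tmp <- tempfile(fileext = ".bed")
  write_bed(pk, tmp)
  tmp
}

# Random peaks on one chromosome for brute-force comparisons.
random_peaks <- function(n, max_pos = 1e6, width = 100L, seed = 1) {
  set.seed(seed)
  s <- sample.int(max_pos, n)
  peaks(chrom = "chr1", start = s, end = s + width,
        name = paste0("p", seq_len(n)))
}

# Brute-force O(n*m) overlap of two peak sets (bp overlap >= min_overlap).
brute_overlap <- function(a, b, min_overlap = 1L) {
  hit <- function(s1, e1, s2, e2)
    pmin(e1, e2) - pmax(s1, s2) >= min_overlap
  ca <- vapply(seq_len(nrow(a)), function(i)
    any(a$chrom[i] == b$chrom &
          hit(a$start[i], a$end[i], b$start, b$end)), TRUE)
  cb <- vapply(seq_len(nrow(b)), function(i)
    any(b$chrom[i] == a$chrom &
          hit(b$start[i], b$end[i], a$start, a$end)), TRUE)
  list(common_a = sum(ca), common_b = sum(cb))
}

# A small deterministic count experiment with planted effects.
small_counts <- function(n_genes = 200, reps = 3, alpha = 0.05,
                         lfc = numeric(n_genes), base = 100, seed = 1) {
  set.seed(seed)
  cond <- rep(c("A", "B"), each = reps)
  mu <- matrix(base, n_genes, 2 * reps)
  mu[, cond == "B"] <- mu[, cond == "B"] * 2^lfc
  k <- matrix(rnbinom(length(mu), mu = mu, size = 1 / alpha),
              n_genes, 2 * reps,
              dimnames = list(sprintf("g%04d", 1:n_genes),
                              paste0(cond, seq_len(2 * reps))))
  count_matrix(k, cond)
}

# A tiny fixed signature object for scoring tests.
toy_signature <- function(up = c("U1", "U2"), down = c("D1")) {
  sig <- data.frame(gene = c(up, down),
                    weight = c(rep(1, length(up)), rep(-1, length(down))),
                    log2fc = c(rep(2, length(up)), rep(-2, length(down))),
                    padj = 1e-4, peak_id = "p", tss_distance = 0,
                    stringsAsFactors = FALSE)
  class(sig) <- c("signature", "data.frame")
  sig
}
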