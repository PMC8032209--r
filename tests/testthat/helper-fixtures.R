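# Shared in-code fixtures. Everything is built programmatically; the default
# synthetic dataset is generated once per test run and reused.

toy_genome <- function(seq, contig = "chrT") {
  genome_seq(stats::setNames(seq, contig))
}

# 3-exon plus-strand toy gene with 10-base exons separated by 5-base introns
toy_model_plus <- function() {
  exon_model("toy+", "chrT", "+",
             starts = c(11L, 26L, 41L), ends = c(20L, 35L, 50L))
}

toy_model_minus <- function() {
  exon_model("toy-", "chrT", "-",
             starts = c(11L, 26L, 41L), ends = c(20L, 35L, 50L))
}

# deterministic 60-base sequence covering the toy exons
toy_seq <- function() {
  set.seed(7)
  paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
}

# naive position-by-position IUPAC scanner (independent oracle)
iupac_expand <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
                  S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
                  D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

naive_iupac_scan <- function(seq, pattern) {
  k <- nchar(pattern); L <- nchar(seq)
  if (k > L) return(integer(0))
  pat <- strsplit(pattern, "")[[1]]
  hits <- integer(0)
  for (s in seq_len(L - k + 1L)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!grepl(substr(seq, s + j - 1L, s + j - 1L),
                 iupac_expand[[pat[j]]], fixed = TRUE)) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

# two-sided Fisher exact p by direct hypergeometric tail enumeration
enum_fisher_p <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p0 <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

# memoised default synthetic dataset (seed 42 study conditions)
default_ds <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_dataset(synth_config())
    cache
  }
})
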