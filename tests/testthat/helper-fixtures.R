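# Shared fixtures and independent oracles for the test suite.

# small transcriptome, built once and reused
tiny_txome <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_transcriptome(12, 3, seed = 101)
    cache
  }
})

# independent Fisher oracle: exhaustive enumeration over all tables with
# the observed margins, probabilities from log-binomial coefficients
fisher_oracle <- function(a, b, c_, d_) {
  m <- a + b; n <- c_ + d_; k <- a + c_
  xs <- max(0, k - n):min(k, m)
  pr <- exp(lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k))
  min(1, sum(pr[pr <= pr[xs == a] * (1 + 1e-7)]))
}

# independent Yates closed form
yates_oracle <- function(a, b, c_, d_) {
  N <- a + b + c_ + d_
  num <- max(0, abs(a * d_ - b * c_) - N / 2)^2 * N
  num / ((a + b) * (c_ + d_) * (a + c_) * (b + d_))
}

# tiny repeat database for assignment tests
demo_repeat_db <- function() {
  data.frame(
    transcript_id = c("RNA18S", "RNA18SP7", "AluY", "AluSx", "L1HS",
                      "simple1"),
    family_id = c("rRNA18S", "rRNA18S", "Alu", "Alu", "L1", "simple_repeat"),
    priority = c(1L, 7L, 1L, 2L, 1L, 1L),
    length = c(1869L, 1800L, 300L, 290L, 6000L, 60L),
    sense = c("+", "+", "+", "+", "+", "both"),
    stringsAsFactors = FALSE)
}

# random read records for dedup tests
random_records <- function(n, seed = 1, n_pos = 50, n_umi = 20) {
  set.seed(seed)
  data.frame(
    read_id = sprintf("r%06d", sample.int(n * 10, n)),
    umi = sample(replicate(n_umi, paste(sample(c("A", "C", "G", "T"), 10,
                                               TRUE), collapse = "")),
                 n, TRUE),
    target = "genome",
    start = sample.int(n_pos, n, TRUE),
    stop = 0L, strand = "+",
    stringsAsFactors = FALSE) -> r
  r$stop <- r$start + 40L
  r
}

# peak frame helper
mk_peaks <- function(start, end, strand = "+", chrom = "chrS",
                     log2fc = 4, neglog10p = 6) {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             log2fc = log2fc, neglog10p = neglog10p,
             stringsAsFactors = FALSE)
}
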