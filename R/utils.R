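# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' All randomness in the package flows through this helper so that every
#' generator and resampling routine is a pure function of (parameters, seed)
#' and never disturbs the caller's RNG state.
#'
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  code
}

# Deterministically derive a sub-seed so that independent stages fed from one
# master seed do not reuse identical RNG streams. Kept below 2^31 - 1.
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) %% 65011 + 1) * 32749 + salt %% 32749)
}

# Overlap length of 0-based half-open intervals (vectorized).
ivl_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

# Convert 0-based half-open coordinates to IRanges (1-based closed).
to_ir <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

# Weighted sampling of `n` indices with replacement from weights `w`
# (O(n log k); avoids the quadratic path of sample(prob=)).
sample_weighted <- function(n, w) {
  if (n == 0L) return(integer(0))
  cw <- cumsum(as.numeric(w))
  tot <- cw[length(cw)]
  if (!is.finite(tot) || tot <= 0) stop("weights must have a positive finite sum")
  findInterval(stats::runif(n) * tot, cw) + 1L
}

# Random fixed-length nucleotide strings (RNA alphabet by default).
random_sequences <- function(n, len, alphabet = c("A", "C", "G", "U")) {
  if (n == 0L) return(character(0))
  chars <- sample(alphabet, n * len, replace = TRUE)
  big <- paste(chars, collapse = "")
  substring(big, seq.int(1L, by = len, length.out = n),
            seq.int(len, by = len, length.out = n))
}

# Random UMI tags (DNA alphabet, fixed length).
random_umis <- function(n, len = 10L) {
  random_sequences(n, len, alphabet = c("A", "C", "G", "T"))
}

#' All k-mers of a given length
#'
#' @param k k-mer length.
#' @param rna if `TRUE` return the RNA alphabet (U instead of T).
#' @return character vector of the 4^k k-mers in lexicographic (A<C<G<T/U)
#'   order, matching the column order of [kmer_count_vector()].
#' @export
all_kmers <- function(k, rna = TRUE) {
  ks <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  if (rna) chartr("T", "U", ks) else ks
}

# Coerce reads (character with ACGU/ACGT, or XStringSet) to DNAStringSet.
as_dna <- function(reads) {
  if (methods::is(reads, "DNAStringSet")) return(reads)
  if (methods::is(reads, "XStringSet")) reads <- as.character(reads)
  Biostrings::DNAStringSet(chartr("U", "T", reads))
}

#' Count overlapping k-mer occurrences in a read pool
#'
#' Occurrences are counted at every offset, so overlapping matches all count;
#' windows containing the masking sentinel (N) seed no k-mer.
#'
#' @param reads character vector (ACGU or ACGT) or `DNAStringSet`.
#' @param k k-mer length.
#' @param rna name the result with the RNA alphabet.
#' @return named integer vector of length 4^k.
#' @export
kmer_count_vector <- function(reads, k, rna = TRUE) {
  x <- as_dna(reads)
  cs <- Biostrings::oligonucleotideFrequency(x, width = k,
                                             simplify.as = "collapsed")
  names(cs) <- all_kmers(k, rna = rna)
  cs
}

# Mask every occurrence of `kmer` in the pool with N so no window across a
# masked stretch can seed a k-mer (prevents chimeric counts at mask edges).
mask_kmer <- function(reads, kmer) {
  x <- as_dna(reads)
  pat <- chartr("U", "T", kmer)
  m <- Biostrings::vmatchPattern(pat, x)
  rl <- IRanges::reduce(methods::as(m, "CompressedIRangesList"))
  if (sum(lengths(rl)) == 0L) return(x)
  val <- IRanges::relist(strrep("N", unlist(IRanges::width(rl))), rl)
  Biostrings::replaceAt(x, rl, val)
}

# Shared stop() wrappers so error classes are greppable in tests.
stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
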