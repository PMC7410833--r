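# RBNS k-mer enrichment statistics (R values and Z-scores).

#' k-mer enrichment profile of a pulldown versus input library
#'
#' R values are per-k-mer pulldown frequency divided by input frequency,
#' counting overlapping occurrences; Z-scores standardize R across all 4^k
#' k-mers. A pseudocount (default 0.5 occurrences added to every k-mer in
#' both libraries before frequency computation) keeps R finite for k-mers
#' absent from the input; it only affects vanishing-frequency tails.
#'
#' @param pulldown,input read pools (character vectors, ACGU/ACGT, or
#'   `DNAStringSet`).
#' @param k k-mer length (5 or 6 in the assay; any k >= 1 accepted).
#' @param pseudocount occurrences added to every k-mer count.
#' @return data frame of class `kmer_profile`: `kmer`, `pulldown_freq`,
#'   `input_freq`, `R`, `Z`, sorted by k-mer. The weighted-mean identity
#'   sum(input_freq * R) = 1 holds exactly by construction.
#' @export
kmer_r_values <- function(pulldown, input, k = 5, pseudocount = 0.5) {
  if (length(pulldown) == 0 || length(input) == 0)
    stop_invalid("empty read set")
  cp <- kmer_count_vector(pulldown, k) + pseudocount
  ci <- kmer_count_vector(input, k) + pseudocount
  fp <- cp / sum(cp)
  fi <- ci / sum(ci)
  R <- fp / fi
  Z <- (R - mean(R)) / stats::sd(R)
  out <- data.frame(kmer = names(cp), pulldown_freq = unname(fp),
                    input_freq = unname(fi), R = unname(R), Z = unname(Z),
                    stringsAsFactors = FALSE)
  class(out) <- c("kmer_profile", "data.frame")
  out
}

#' Select the pulldown concentration with the strongest single k-mer
#'
#' Enrichments from the pulldown library with the highest individual k-mer
#' R value are used for an RBP; by default all concentrations share one
#' input library (per-concentration inputs can be supplied as a list).
#'
#' @param pulldowns named list of pulldown read pools (one per
#'   concentration).
#' @param input input read pool, or list of pools parallel to `pulldowns`.
#' @param k k-mer length.
#' @return list with `profile` (the selected `kmer_profile`), `selected`
#'   (the name/index of the winning library) and `top_r` per library.
#' @export
select_concentration <- function(pulldowns, input, k = 5) {
  stopifnot(length(pulldowns) >= 1)
  profs <- lapply(seq_along(pulldowns), function(i) {
    inp <- if (is.list(input) && !is.null(input[[1]]) &&
               length(input) == length(pulldowns)) input[[i]] else input
    kmer_r_values(pulldowns[[i]], inp, k = k)
  })
  top_r <- vapply(profs, function(p) max(p$R), numeric(1))
  sel <- which.max(top_r)
  nm <- if (!is.null(names(pulldowns))) names(pulldowns)[sel] else sel
  list(profile = profs[[sel]], selected = nm,
       top_r = stats::setNames(top_r, names(pulldowns)))
}

#' eCLIP k-mer Z-scores against region-preserving background peaks
#'
#' Z-scores of the difference between real-peak and background k-mer
#' frequencies, where the background peaks preserve binding region and
#' length (see [sample_background_peaks()]).
#'
#' @param peak_seqs,background_seqs character vectors of peak sequences.
#' @param k k-mer length.
#' @return data frame `kmer`, `fg_freq`, `bg_freq`, `diff`, `Z`.
#' @export
eclip_kmer_zscores <- function(peak_seqs, background_seqs, k = 5) {
  if (length(peak_seqs) < 2)
    stop_invalid("need at least 2 peak sequences for k-mer Z-scores")
  cf <- kmer_count_vector(peak_seqs, k) + 0.5
  cb <- kmer_count_vector(background_seqs, k) + 0.5
  ff <- cf / sum(cf); fb <- cb / sum(cb)
  d <- ff - fb
  s <- stats::sd(d)
  z <- if (s > 0) (d - mean(d)) / s else rep(0, length(d))
  data.frame(kmer = names(cf), fg_freq = unname(ff), bg_freq = unname(fb),
             diff = unname(d), Z = unname(z), stringsAsFactors = FALSE)
}

#' Hypergeometric overlap test between two 5-mer sets
#'
#' Upper-tail hypergeometric probability of observing at least the given
#' intersection when both sets are drawn from the universe of all 4^5 =
#' 1,024 5-mers; the overlap is called significant at p < 0.05.
#'
#' @param set_a,set_b character vectors of k-mers (subsets of the universe).
#' @param universe universe size (default 1024).
#' @return list `p`, `overlap`, `significant`.
#' @export
motif_overlap_test <- function(set_a, set_b, universe = 1024) {
  a <- unique(set_a); b <- unique(set_b)
  if (length(a) == 0 || length(b) == 0)
    return(list(p = 1, overlap = 0L, significant = FALSE))
  ov <- length(intersect(a, b))
  p <- stats::phyper(ov - 1, length(a), universe - length(a), length(b),
                     lower.tail = FALSE)
  list(p = p, overlap = ov, significant = p < 0.05)
}
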