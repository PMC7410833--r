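# Iterative masked motif-logo discovery for RBNS pools and eCLIP peak
# sequences.

#' Iteratively extract enriched k-mers with masking
#'
#' One round of the logo algorithm's inner loop: take the most enriched
#' k-mer on the current (masked) libraries, give it weight R - 1 (its
#' excess enrichment over the input), mask all its occurrences in both the
#' pulldown and input libraries so that shifted "shadow" k-mers are not
#' counted again, and recompute. Iteration stops when the Z-score of the
#' candidate k-mer -- always computed from the ORIGINAL, unmasked R values
#' -- falls below `z_threshold`. Ties on R go to the lexicographically
#' smallest k-mer so runs are reproducible.
#'
#' @param pulldown,input read pools.
#' @param k k-mer length (default 5).
#' @param z_threshold stopping threshold on the original Z-score.
#' @param max_iter safety bound on iterations.
#' @return data frame `kmer`, `weight` in acceptance order (possibly empty).
#' @export
iterative_top_kmers <- function(pulldown, input, k = 5, z_threshold = 3,
                                max_iter = 40) {
  orig <- kmer_r_values(pulldown, input, k = k)
  z0 <- stats::setNames(orig$Z, orig$kmer)
  pd <- as_dna(pulldown); inp <- as_dna(input)
  acc <- list()
  for (it in seq_len(max_iter)) {
    prof <- kmer_r_values(pd, inp, k = k)
    top <- prof$kmer[which.max(prof$R)]
    if (z0[[top]] < z_threshold) break
    w <- prof$R[prof$kmer == top] - 1
    if (!is.finite(w) || w <= 0) break
    n_occ <- sum(Biostrings::vcountPattern(chartr("U", "T", top), pd))
    if (n_occ == 0) break
    acc[[length(acc) + 1L]] <- data.frame(kmer = top, weight = w,
                                          stringsAsFactors = FALSE)
    pd <- mask_kmer(pd, top)
    inp <- mask_kmer(inp, top)
  }
  if (length(acc) == 0)
    return(data.frame(kmer = character(0), weight = numeric(0)))
  out <- do.call(rbind, acc)
  rownames(out) <- NULL
  out
}

# mismatches between `kmer` placed at `offset` relative to `seed`
# (member position i aligns seed position i + offset); only overlapping
# positions are compared.
offset_mismatches <- function(kmer, seed, offset) {
  k <- nchar(seed)
  i <- seq_len(k)
  j <- i + offset
  keep <- j >= 1 & j <= k
  if (!any(keep)) return(Inf)
  a <- strsplit(kmer, "")[[1]][i[keep]]
  b <- strsplit(seed, "")[[1]][j[keep]]
  sum(a != b)
}

# Align accepted k-mers to motif seeds: each k-mer joins the first motif
# (in creation order) whose seed it matches with mismatches + |offset|
# <= max_cost, at the lowest-cost offset (ties: smaller |offset|, then
# upstream); otherwise it seeds a new motif.
align_kmers <- function(accepted, max_cost = 2) {
  motifs <- list()
  for (r in seq_len(nrow(accepted))) {
    km <- accepted$kmer[r]; w <- accepted$weight[r]
    placed <- FALSE
    for (m in seq_along(motifs)) {
      seed <- motifs[[m]]$seed
      offs <- -(nchar(seed) - 1):(nchar(seed) - 1)
      cost <- vapply(offs, function(o)
        offset_mismatches(km, seed, o) + abs(o), numeric(1))
      ord <- order(cost, abs(offs), offs)
      if (cost[ord[1]] <= max_cost) {
        motifs[[m]]$members <- rbind(
          motifs[[m]]$members,
          data.frame(kmer = km, weight = w, offset = offs[ord[1]],
                     stringsAsFactors = FALSE))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      motifs[[length(motifs) + 1L]] <- list(
        seed = km,
        members = data.frame(kmer = km, weight = w, offset = 0L,
                             stringsAsFactors = FALSE))
    }
  }
  motifs
}

# Position weight matrix from aligned weighted k-mers: covered positions
# contribute the k-mer's weight to its nucleotide; unaligned flank
# positions contribute 25% of the weight to each nucleotide; outermost
# positions with > trim_frac unaligned weight are trimmed.
pwm_from_members <- function(members, trim_frac = 0.75) {
  k <- nchar(members$kmer[1])
  lo <- min(members$offset) + 1L
  hi <- max(members$offset) + k
  cols <- lo:hi
  nts <- c("A", "C", "G", "U")
  pwm <- matrix(0, nrow = 4, ncol = length(cols),
                dimnames = list(nts, NULL))
  unaligned <- numeric(length(cols))
  total_w <- sum(members$weight)
  for (r in seq_len(nrow(members))) {
    chars <- strsplit(chartr("T", "U", members$kmer[r]), "")[[1]]
    span <- members$offset[r] + seq_len(k)   # seed coordinates covered
    for (ci in seq_along(cols)) {
      pos <- cols[ci]
      hit <- match(pos, span)
      if (!is.na(hit)) {
        pwm[chars[hit], ci] <- pwm[chars[hit], ci] + members$weight[r]
      } else {
        pwm[, ci] <- pwm[, ci] + members$weight[r] / 4
        unaligned[ci] <- unaligned[ci] + members$weight[r]
      }
    }
  }
  keep <- seq_along(cols)
  while (length(keep) > 1 && unaligned[keep[1]] / total_w > trim_frac)
    keep <- keep[-1]
  while (length(keep) > 1 &&
         unaligned[keep[length(keep)]] / total_w > trim_frac)
    keep <- keep[-length(keep)]
  pwm <- pwm[, keep, drop = FALSE]
  sweep(pwm, 2, colSums(pwm), "/")
}

make_logo <- function(members, fraction) {
  obj <- list(kmers = members, pwm = pwm_from_members(members),
              fraction = fraction)
  class(obj) <- "motif_logo"
  obj
}

#' Consensus sequence of a motif logo
#'
#' @param logo a `motif_logo`.
#' @return character: the column-wise argmax of the position weight matrix.
#' @export
logo_consensus <- function(logo) {
  paste(rownames(logo$pwm)[apply(logo$pwm, 2, which.max)], collapse = "")
}

#' @export
print.motif_logo <- function(x, ...) {
  cat(sprintf("motif logo: %s (%d aligned %d-mers, %.1f%% of weight)\n",
              logo_consensus(x), nrow(x$kmers), nchar(x$kmers$kmer[1]),
              100 * x$fraction))
  invisible(x)
}

# Does `kmer` align to any member of `set` within the motif-joining cost?
kmer_matches_any <- function(kmer, set, max_cost) {
  if (length(set) == 0) return(FALSE)
  k <- nchar(kmer)
  offs <- -(k - 1):(k - 1)
  for (s in set) {
    cost <- vapply(offs, function(o)
      offset_mismatches(kmer, s, o) + abs(o), numeric(1))
    if (min(cost) <= max_cost) return(TRUE)
  }
  FALSE
}

# Shared logo pipeline: run the iterative extraction on the full data and
# on the two robustness subsets, keep only k-mers whose motif was
# recovered in both subsets, then align and build PWMs with full-data
# weights. Validation tolerates alignment cost 1 (one shift or one
# mismatch) rather than demanding exact k-mer identity: masking makes
# the choice among shifted variants of one motif (e.g. UGCAU vs GCAUG
# for a planted UGCAUG) a coin flip between subsets, so variants of the
# same motif must corroborate each other, while looser tolerance would
# let unrelated noise k-mers vouch for one another in null pools.
build_logos_core <- function(full_pd, full_in, h1_pd, h1_in, h2_pd, h2_in,
                             k, z_threshold, max_cost = 2, half_cost = 1) {
  acc_full <- iterative_top_kmers(full_pd, full_in, k, z_threshold)
  if (nrow(acc_full) == 0) return(list())
  acc1 <- iterative_top_kmers(h1_pd, h1_in, k, z_threshold)
  acc2 <- iterative_top_kmers(h2_pd, h2_in, k, z_threshold)
  valid <- vapply(acc_full$kmer, function(km)
    kmer_matches_any(km, acc1$kmer, half_cost) &&
      kmer_matches_any(km, acc2$kmer, half_cost), logical(1))
  acc <- acc_full[valid, , drop = FALSE]
  if (nrow(acc) == 0) return(list())
  motifs <- align_kmers(acc, max_cost = max_cost)
  total_w <- sum(acc$weight)
  lapply(motifs, function(m)
    make_logo(m$members, fraction = sum(m$members$weight) / total_w))
}

#' Build RBNS motif logos by the iterative masking procedure
#'
#' Implements the full logo algorithm for k = 5: iterative extraction with
#' masking (weights R - 1, stopping at original Z < `z_threshold`),
#' alignment of accepted 5-mers to the most enriched 5-mer with a new motif
#' started when mismatches plus offsets exceed two, PWMs with 25%
#' pseudocounts at unaligned flanks and trimming of positions with > 75%
#' unaligned weight. For robustness the pulldown and input pools are each
#' split in half and only 5-mers recovered independently in both halves
#' enter the final logos.
#'
#' @param pulldown,input read pools.
#' @param k k-mer length (default 5).
#' @param z_threshold stopping Z threshold (default 3).
#' @param max_cost mismatches + offsets allowed within one motif.
#' @return list of `motif_logo` objects (empty when nothing reaches the
#'   threshold).
#' @export
build_rbns_logos <- function(pulldown, input, k = 5, z_threshold = 3,
                             max_cost = 2) {
  n_pd <- length(pulldown); n_in <- length(input)
  if (n_pd < 2 || n_in < 2) stop_invalid("read pools too small to split")
  h1 <- seq_len(n_pd %/% 2)
  i1 <- seq_len(n_in %/% 2)
  build_logos_core(pulldown, input,
                   pulldown[h1], input[i1],
                   pulldown[-h1], input[-i1],
                   k = k, z_threshold = z_threshold, max_cost = max_cost)
}

#' Build eCLIP motif logos from replicate peak sequences
#'
#' The RBNS half-split is replaced by the two replicate peak sequence sets
#' (the full run uses their concatenation) and the input library by
#' region-preserving background sequences; the Z threshold defaults to 2.8.
#' Only 5-mers recovered in both replicate runs are retained. Run once per
#' region class (all peaks, 3'UTR, CDS, intron) by subsetting the inputs.
#'
#' @param peak_seqs_rep1,peak_seqs_rep2 peak sequences per replicate
#'   (already extended 50 nt upstream of the peak 5' end; see
#'   [peak_sequences()]).
#' @param background_seqs matched background sequences (see
#'   [sample_background_peaks()]).
#' @param k k-mer length.
#' @param z_threshold stopping Z threshold (default 2.8).
#' @param max_cost mismatches + offsets allowed within one motif.
#' @return list of `motif_logo` objects.
#' @export
build_eclip_logos <- function(peak_seqs_rep1, peak_seqs_rep2,
                              background_seqs, k = 5, z_threshold = 2.8,
                              max_cost = 2) {
  if (length(peak_seqs_rep1) == 0 || length(peak_seqs_rep2) == 0)
    return(list())
  build_logos_core(c(peak_seqs_rep1, peak_seqs_rep2), background_seqs,
                   peak_seqs_rep1, background_seqs,
                   peak_seqs_rep2, background_seqs,
                   k = k, z_threshold = z_threshold, max_cost = max_cost)
}
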