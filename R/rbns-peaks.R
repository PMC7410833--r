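# Peak sequences, region-preserving backgrounds, RBNS+/- classification
# and matched-control construction for splicing-effect comparisons.

#' Extract peak sequences with a 5' upstream extension
#'
#' Each peak is extended `upstream` nt upstream of its 5' end (to the left
#' on the plus strand, to the right on the minus strand) before sequence
#' extraction; minus-strand sequences are reverse-complemented. Sequences
#' are returned in the RNA alphabet.
#'
#' @param peaks data frame `start`, `end`, `strand` (0-based half-open).
#' @param annotation a `transcriptome` (or any list with `genome`, a
#'   `DNAStringSet` of length 1).
#' @param upstream extension length (default 50 nt).
#' @return character vector of sequences.
#' @export
peak_sequences <- function(peaks, annotation, upstream = 50L) {
  if (nrow(peaks) == 0) return(character(0))
  genome <- annotation$genome[[1]]
  L <- length(genome)
  plus <- peaks$strand != "-"
  s <- ifelse(plus, pmax(0L, peaks$start - upstream), peaks$start)
  e <- ifelse(plus, peaks$end, pmin(L, peaks$end + upstream))
  v <- Biostrings::Views(genome, start = s + 1L, end = e)
  seqs <- Biostrings::DNAStringSet(v)
  seqs[!plus] <- Biostrings::reverseComplement(seqs[!plus])
  chartr("T", "U", as.character(seqs))
}

#' Region-preserving background peaks
#'
#' For each peak, draws a background interval of the same length within the
#' same gene and region label: UTR/exonic peaks are placed uniformly within
#' a random instance of the same region track; CDS and intronic peaks
#' preserve the distance from the peak start to the closest region
#' boundary (mirroring the sequence constraints imposed by splice sites).
#' Peaks whose region class offers no candidate position are excluded and
#' reported in the `dropped` attribute.
#'
#' @param peaks data frame `start`, `end`, `strand`, `gene_id`, `label`.
#' @param tracks region tracks from [region_tracks()].
#' @param seed integer seed.
#' @return data frame of background peaks (same columns), with attribute
#'   `dropped` holding the row indices that found no background.
#' @export
sample_background_peaks <- function(peaks, tracks, seed = 1) {
  with_seed(seed, {
    out <- peaks
    dropped <- integer(0)
    boundary_labels <- c("cds", "proximal_intron", "distal_intron",
                         "five_ss", "three_ss", "intron")
    for (i in seq_len(nrow(peaks))) {
      len <- peaks$end[i] - peaks$start[i]
      cand <- tracks[tracks$gene_id == peaks$gene_id[i] &
                     tracks$label == peaks$label[i] &
                     tracks$strand == peaks$strand[i] &
                     (tracks$end - tracks$start) >= len, , drop = FALSE]
      if (nrow(cand) == 0) { dropped <- c(dropped, i); next }
      tr <- cand[sample.int(nrow(cand), 1), ]
      if (peaks$label[i] %in% boundary_labels) {
        # preserve distance of the peak start to the closest boundary
        src <- tracks[tracks$gene_id == peaks$gene_id[i] &
                      tracks$label == peaks$label[i] &
                      tracks$start <= peaks$start[i] &
                      tracks$end > peaks$start[i], , drop = FALSE]
        d_left <- if (nrow(src)) peaks$start[i] - src$start[1] else 0L
        d_right <- if (nrow(src)) src$end[1] - peaks$start[i] else len
        if (d_left <= d_right) ns <- tr$start + d_left
        else ns <- tr$end - d_right
        ns <- min(max(ns, tr$start), tr$end - len)
      } else {
        ns <- tr$start +
          floor(stats::runif(1) * (tr$end - tr$start - len + 1))
      }
      out$start[i] <- as.integer(ns)
      out$end[i] <- as.integer(ns + len)
    }
    if (length(dropped)) out <- out[-dropped, , drop = FALSE]
    attr(out, "dropped") <- dropped
    out
  })
}

#' Classify peaks by presence of the top in vitro 5-mer
#'
#' A peak is RBNS+ when the extended peak sequence (including the 50-nt
#' upstream extension applied by [peak_sequences()]) contains at least one
#' occurrence of the top RBNS 5-mer, RBNS- otherwise.
#'
#' @param peak_seqs character vector of (extended) peak sequences.
#' @param top_kmer the top RBNS 5-mer.
#' @return logical vector: `TRUE` = RBNS+.
#' @export
classify_peaks_by_motif <- function(peak_seqs, top_kmer) {
  grepl(chartr("T", "U", top_kmer), chartr("T", "U", peak_seqs),
        fixed = TRUE)
}

#' Matched control exons by expression and inclusion deciles
#'
#' For each case exon (e.g. eCLIP+ skipped exons), draws without
#' replacement one control exon from the same decile of wild-type gene
#' expression AND the same decile of wild-type inclusion level psi. Decile
#' boundaries are computed on the pooled case + candidate values, so the
#' matched set's joint (expression-decile, psi-decile) histogram equals the
#' case histogram exactly whenever matching is feasible; cases whose decile
#' cell has no remaining candidate are dropped and reported.
#'
#' @param cases data frame with columns `expr` and `psi` (one row per case
#'   exon; restrict to psi between 0.05 and 0.95 beforehand).
#' @param candidates data frame with the same columns (control pool).
#' @param seed integer seed.
#' @param n_bins number of quantile bins (default 10 = deciles).
#' @return data frame of matched controls (rows of `candidates`), with
#'   attributes `dropped` (case row indices left unmatched) and `cells`
#'   (the decile-cell labels of the matched controls).
#' @export
matched_controls <- function(cases, candidates, seed = 1, n_bins = 10) {
  if (nrow(candidates) == 0) {
    warning("no candidate control exons available")
    out <- candidates
    attr(out, "dropped") <- seq_len(nrow(cases))
    return(out)
  }
  bin_of <- function(x, br) {
    findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  }
  br_e <- unique(stats::quantile(c(cases$expr, candidates$expr),
                                 probs = seq(0, 1, length.out = n_bins + 1)))
  br_p <- unique(stats::quantile(c(cases$psi, candidates$psi),
                                 probs = seq(0, 1, length.out = n_bins + 1)))
  cell_case <- paste(bin_of(cases$expr, br_e), bin_of(cases$psi, br_p))
  cell_cand <- paste(bin_of(candidates$expr, br_e), bin_of(candidates$psi, br_p))
  with_seed(seed, {
    used <- rep(FALSE, nrow(candidates))
    picks <- integer(0)
    dropped <- integer(0)
    for (i in seq_len(nrow(cases))) {
      avail <- which(!used & cell_cand == cell_case[i])
      if (length(avail) == 0) { dropped <- c(dropped, i); next }
      j <- avail[sample.int(length(avail), 1)]
      used[j] <- TRUE
      picks <- c(picks, j)
    }
    out <- candidates[picks, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "dropped") <- dropped
    attr(out, "cells") <- cell_cand[picks]
    if (length(dropped))
      warning(sprintf("%d case exons had no matching control and were dropped",
                      length(dropped)))
    out
  })
}

#' Compare splicing-change magnitudes between peak classes
#'
#' One-sided Wilcoxon rank-sum test that |dpsi| is larger for exons with a
#' peak than for matched exons without one; when that comparison is
#' significant and motif annotations are supplied, the peak group is split
#' by presence of the top RBNS 5-mer and RBNS+ is re-tested against RBNS-.
#'
#' @param peak_dpsi,nopeak_dpsi inclusion-level differences for the two
#'   groups.
#' @param peak_has_motif optional logical vector parallel to `peak_dpsi`.
#' @param alpha significance level gating the motif split (default 0.05).
#' @return list with `p`, `n`, `significant`, sorted |dpsi| vectors for CDF
#'   plotting, and (when applicable) `motif_p` with the RBNS+/- group
#'   sizes.
#' @export
splicing_effect_compare <- function(peak_dpsi, nopeak_dpsi,
                                    peak_has_motif = NULL, alpha = 0.05) {
  n <- c(peak = length(peak_dpsi), nopeak = length(nopeak_dpsi))
  if (any(n < 2)) {
    return(list(p = NA_real_, n = n, significant = FALSE,
                note = "group size < 2: test not applicable"))
  }
  p <- suppressWarnings(stats::wilcox.test(abs(peak_dpsi), abs(nopeak_dpsi),
                                           alternative = "greater")$p.value)
  res <- list(p = p, n = n, significant = is.finite(p) && p < alpha,
              cdf_peak = sort(abs(peak_dpsi)),
              cdf_nopeak = sort(abs(nopeak_dpsi)))
  if (res$significant && !is.null(peak_has_motif)) {
    mp <- abs(peak_dpsi[peak_has_motif])
    mn <- abs(peak_dpsi[!peak_has_motif])
    res$n_motif <- c(rbns_pos = length(mp), rbns_neg = length(mn))
    res$motif_p <- if (length(mp) >= 2 && length(mn) >= 2)
      suppressWarnings(stats::wilcox.test(mp, mn,
                                          alternative = "greater")$p.value)
    else NA_real_
  }
  res
}
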