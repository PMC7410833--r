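# Normalized RNA splicing maps around knockdown-responsive events, with
# resampled native-event percentile bands.

#' Split a splicing-event table into significant and native sets
#'
#' Significant events satisfy p < `p_cut`, FDR < `fdr_cut` and
#' |dpsi| > `dpsi_cut`, and are split by direction into KD-included
#' (dpsi > 0) and KD-excluded (dpsi < 0). Native events are the
#' non-significant events whose control inclusion lies strictly between
#' `native_band[1]` and `native_band[2]`.
#'
#' @param events event table (needs `p`, `fdr`, `dpsi`, `psi_control`).
#' @param p_cut,fdr_cut,dpsi_cut significance thresholds (defaults 0.05,
#'   0.1, 0.05).
#' @param native_band control-psi band for native events (default
#'   0.05-0.95).
#' @return list of data frames `included`, `excluded`, `native` (disjoint).
#' @export
filter_events <- function(events, p_cut = 0.05, fdr_cut = 0.1,
                          dpsi_cut = 0.05, native_band = c(0.05, 0.95)) {
  need <- c("p", "fdr", "dpsi", "psi_control")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop_invalid("event table lacks column '%s'", miss[1])
  sig <- events$p < p_cut & events$fdr < fdr_cut & abs(events$dpsi) > dpsi_cut
  native <- !sig & events$psi_control > native_band[1] &
    events$psi_control < native_band[2]
  list(included = events[sig & events$dpsi > 0, , drop = FALSE],
       excluded = events[sig & events$dpsi < 0, , drop = FALSE],
       native = events[native, , drop = FALSE])
}

#' Meta-region genomic positions for a skipped-exon event
#'
#' Four splice-site-anchored blocks, each `windows$exon` exonic plus
#' `windows$intron` intronic nt: the (biologically) upstream exon's 3' end,
#' the 3' splice site and 5' splice site of the alternative exon, and the
#' downstream exon's 5' end. Positions extending past the underlying
#' feature (short exons or introns) are NA (masked, not zero-filled). On
#' the minus strand the vector is reversed so position 1 is always the most
#' upstream.
#'
#' @param event one event row (`strand`, `exon_start`, `exon_end`,
#'   `upstream_start`, `upstream_end`, `downstream_start`,
#'   `downstream_end`; upstream/downstream are genomic left/right).
#' @param windows list with `exon` and `intron` half-window widths (nt).
#' @return integer vector of 0-based genomic positions with NAs at masked
#'   positions; length 4 * (exon + intron).
#' @export
meta_positions <- function(event, windows = list(exon = 50L, intron = 300L)) {
  we <- windows$exon; wi <- windows$intron
  ues <- event$upstream_start; uee <- event$upstream_end
  es <- event$exon_start; ee <- event$exon_end
  des <- event$downstream_start; dee <- event$downstream_end
  blk <- function(pos, valid) ifelse(valid, pos, NA_integer_)
  pA <- c(blk(seq(uee - we, uee - 1L), seq(uee - we, uee - 1L) >= ues),
          blk(seq(uee, uee + wi - 1L), seq(uee, uee + wi - 1L) < es))
  pB <- c(blk(seq(es - wi, es - 1L), seq(es - wi, es - 1L) >= uee),
          blk(seq(es, es + we - 1L), seq(es, es + we - 1L) < ee))
  pC <- c(blk(seq(ee - we, ee - 1L), seq(ee - we, ee - 1L) >= es),
          blk(seq(ee, ee + wi - 1L), seq(ee, ee + wi - 1L) < des))
  pD <- c(blk(seq(des - wi, des - 1L), seq(des - wi, des - 1L) >= ee),
          blk(seq(des, des + we - 1L), seq(des, des + we - 1L) < dee))
  pos <- c(pA, pB, pC, pD)
  if (identical(event$strand, "-")) pos <- rev(pos)
  as.integer(pos)
}

#' Input-normalized eCLIP density over one event's meta-region
#'
#' Per-position value is IP minus input density in reads per million
#' (the default combiner; a ratio-based combiner can be supplied), oriented
#' so that the vector runs 5' to 3' along the transcript.
#'
#' @param ip_rpm,input_rpm per-base densities in reads per million
#'   (1-based vectors over the chromosome).
#' @param event one event row (see [meta_positions()]).
#' @param windows window configuration.
#' @param combiner function(ip, input) -> numeric; default subtraction.
#' @return numeric vector with NA at masked positions.
#' @export
event_density <- function(ip_rpm, input_rpm, event,
                          windows = list(exon = 50L, intron = 300L),
                          combiner = `-`) {
  pos <- meta_positions(event, windows)
  ok <- !is.na(pos) & pos >= 0L & pos < length(ip_rpm)
  out <- rep(NA_real_, length(pos))
  out[ok] <- combiner(ip_rpm[pos[ok] + 1L], input_rpm[pos[ok] + 1L])
  out
}

#' Event-by-position density matrix
#'
#' @param ip_cov,input_cov per-base read coverage vectors (raw counts).
#' @param events event table.
#' @param ip_total,input_total library totals for RPM normalization.
#' @inheritParams event_density
#' @return numeric matrix (events x positions).
#' @export
event_density_matrix <- function(ip_cov, input_cov, events,
                                 ip_total, input_total,
                                 windows = list(exon = 50L, intron = 300L),
                                 combiner = `-`) {
  ip_rpm <- ip_cov / ip_total * 1e6
  input_rpm <- input_cov / input_total * 1e6
  t(vapply(seq_len(nrow(events)), function(i)
    event_density(ip_rpm, input_rpm, events[i, , drop = FALSE], windows,
                  combiner),
    numeric(4L * (windows$exon + windows$intron))))
}

#' Splicing map with a resampled native-event percentile band
#'
#' The map is the per-position mean density over the significant events,
#' normalized by subtracting the mean over all native events. The
#' background band is built from `n_samplings` random samplings (with
#' replacement) of native events of matched size: by default the 0.5th and
#' 99.5th percentiles of the resampled means.
#'
#' @param event_mat density matrix of the significant event class.
#' @param native_mat density matrix of the native events.
#' @param n_samplings number of samplings (default 1000).
#' @param seed integer seed.
#' @param probs lower/upper band percentiles (default c(0.005, 0.995)).
#' @param min_events minimum event count; below it the map is refused with
#'   an error reporting the count (default 100, the skipped-exon minimum;
#'   use 50 for alternative splice-site classes).
#' @return object of class `splicing_map`: list with `map`, `band_lo`,
#'   `band_hi`, `native_mean`, `n_events`, `n_samplings`.
#' @export
splicing_map <- function(event_mat, native_mat, n_samplings = 1000,
                         seed = 1, probs = c(0.005, 0.995),
                         min_events = 100) {
  n_ev <- nrow(event_mat)
  if (n_ev < min_events)
    stop_invalid("too few events for a splicing map: %d < %d", n_ev,
                 min_events)
  native_mean <- colMeans(native_mat, na.rm = TRUE)
  map <- colMeans(event_mat, na.rm = TRUE) - native_mean
  n_nat <- nrow(native_mat)
  D0 <- native_mat; D0[is.na(D0)] <- 0
  C <- !is.na(native_mat); storage.mode(C) <- "double"
  # matched-size samplings are drawn with replacement so the resampled
  # means have the same variance as an independent event set of that size
  # (without-replacement draws shrink the variance by the finite-population
  # factor and make the band anti-conservative)
  W <- with_seed(seed, {
    t(vapply(seq_len(n_samplings), function(b)
      tabulate(sample.int(n_nat, n_ev, replace = TRUE), n_nat),
      numeric(n_nat)))
  })
  sums <- W %*% D0
  cnts <- W %*% C
  means <- sweep(sums / pmax(cnts, 1), 2, native_mean)
  means[cnts == 0] <- NA
  qs <- apply(means, 2, stats::quantile, probs = probs, na.rm = TRUE,
              names = FALSE)
  out <- list(map = map, band_lo = qs[1, ], band_hi = qs[2, ],
              native_mean = native_mean, n_events = n_ev,
              n_samplings = n_samplings)
  class(out) <- "splicing_map"
  out
}

#' @export
print.splicing_map <- function(x, ...) {
  esc <- mean(x$map < x$band_lo | x$map > x$band_hi, na.rm = TRUE)
  cat(sprintf("splicing map: %d events, %d positions, %d samplings; %.1f%% of positions outside band\n",
              x$n_events, length(x$map), x$n_samplings, 100 * esc))
  invisible(x)
}

#' Pearson correlation between two splicing maps
#'
#' Computed on the concatenation of the KD-included and KD-excluded map
#' vectors; a class is used only when both sides have a map for it (a map
#' is absent when its event count fell below the class minimum). With no
#' shared class the correlation is not applicable (NA).
#'
#' @param a,b lists with elements `included` and/or `excluded`, each a
#'   `splicing_map` or NULL.
#' @return Pearson r, or NA.
#' @export
map_correlation <- function(a, b) {
  va <- c(); vb <- c()
  for (cls in c("included", "excluded")) {
    if (!is.null(a[[cls]]) && !is.null(b[[cls]])) {
      va <- c(va, a[[cls]]$map)
      vb <- c(vb, b[[cls]]$map)
    }
  }
  if (length(va) == 0) return(NA_real_)
  ok <- is.finite(va) & is.finite(vb)
  if (sum(ok) < 3) return(NA_real_)
  stats::cor(va[ok], vb[ok])
}

#' Cross-RBP splicing map and class-average envelope
#'
#' Computes the splicing map of RBP B's eCLIP densities over the events
#' responsive to knockdown of RBP A (the computation is [splicing_map()]
#' with B's density matrices), and summarizes a binding class by the mean
#' map across members with a percentile spread (default 10th-90th).
#'
#' @param member_maps list of `splicing_map` objects for the class members.
#' @param probs spread percentiles (default c(0.1, 0.9)).
#' @return list `mean`, `lo`, `hi` per position, `n_members`.
#' @export
class_map_envelope <- function(member_maps, probs = c(0.1, 0.9)) {
  if (length(member_maps) == 0) return(NULL)
  M <- do.call(rbind, lapply(member_maps, `[[`, "map"))
  qs <- apply(M, 2, stats::quantile, probs = probs, na.rm = TRUE,
              names = FALSE)
  list(mean = colMeans(M, na.rm = TRUE), lo = qs[1, ], hi = qs[2, ],
       n_members = length(member_maps))
}

#' Average number of RBPs with a peak, per position around exons
#'
#' For each exon, two splice-site blocks (`windows$intron` intronic +
#' `windows$exon` exonic nt at each boundary) are scanned for overlap with
#' each RBP's reproducible peaks; the per-position indicator is averaged
#' over exons and summed over RBPs (so the profile is additive over RBP
#' sets). Spliceosomal RBPs are excluded by name via `exclude`. Computed
#' separately for skipped and constitutive exon sets by calling twice.
#'
#' @param peak_sets named list of peak data frames (`start`, `end`,
#'   `strand`).
#' @param exons data frame `start`, `end`, `strand`.
#' @param windows window configuration (`exon`, `intron`).
#' @param exclude RBP names to drop (e.g. spliceosome machinery).
#' @return numeric vector of length 2 * (exon + intron): mean RBP-with-peak
#'   count per position.
#' @export
rbp_per_exon_profile <- function(peak_sets, exons,
                                 windows = list(exon = 50L, intron = 300L),
                                 exclude = character(0)) {
  if (nrow(exons) == 0) stop_invalid("empty exon set")
  peak_sets <- peak_sets[setdiff(names(peak_sets), exclude)]
  we <- windows$exon; wi <- windows$intron
  len <- 2L * (we + wi)
  chrom_len <- max(exons$end, vapply(peak_sets, function(p)
    if (nrow(p)) max(p$end) else 0L, numeric(1))) + wi + 1L
  pos_mat <- t(vapply(seq_len(nrow(exons)), function(i) {
    es <- exons$start[i]; ee <- exons$end[i]
    p <- c(seq(es - wi, es + we - 1L), seq(ee - we, ee + wi - 1L))
    if (exons$strand[i] == "-") p <- rev(p)
    p
  }, numeric(len)))
  total <- numeric(len)
  for (nm in names(peak_sets)) {
    pk <- peak_sets[[nm]]
    for (st in c("+", "-")) {
      sel_p <- pk[pk$strand == st, , drop = FALSE]
      sel_e <- which(exons$strand == st)
      if (nrow(sel_p) == 0 || length(sel_e) == 0) next
      ind <- logical(chrom_len)
      for (j in seq_len(nrow(sel_p)))
        ind[max(1L, sel_p$start[j] + 1L):min(chrom_len, sel_p$end[j])] <- TRUE
      sub <- pos_mat[sel_e, , drop = FALSE]
      hit <- matrix(FALSE, nrow(sub), ncol(sub))
      ok <- sub >= 0 & sub < chrom_len
      hit[ok] <- ind[sub[ok] + 1L]
      total <- total + colSums(hit) / nrow(exons)
    }
  }
  total
}
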