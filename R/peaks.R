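# Peak reproducibility filtering, blacklist removal and priority-order
# transcript-region annotation.

# canonical region labels, in the two stated priority orders
WITHIN_GENE_PRIORITY <- c("trna", "mirna", "mirna_proximal", "cds",
                          "three_utr", "five_utr", "five_ss", "three_ss",
                          "proximal_intron", "distal_intron",
                          "noncoding_exon")
CROSS_GENE_PRIORITY <- c("trna", "mirna", "cds", "three_utr", "five_utr",
                         "mirna_proximal", "noncoding_exon", "five_ss",
                         "three_ss", "proximal_intron", "distal_intron")

#' Region labels in within-gene priority order
#' @return character vector of the 11 annotation labels.
#' @export
region_labels <- function() WITHIN_GENE_PRIORITY

#' Merge replicate peaks into reproducible, significantly enriched peaks
#'
#' Overlapping peaks (>= 1 nt, same strand and chromosome) from two
#' biological replicates are merged (interval union; per-replicate scores
#' retained) and scored by the geometric means of log2(fold enrichment) and
#' of -log10(p) across replicates. Reproducibility is decided by an
#' injectable scorer at the given threshold; the default is a
#' rank-consistency surrogate: peaks are ranked within each replicate by
#' fold enrichment, and the `idr_threshold` fraction of candidates with
#' the largest rank-percentile discordance |u - v| is flagged
#' irreproducible and removed (with identical replicates nothing is
#' discordant and everything is retained). The surrogate controls the
#' flagged fraction, not a model posterior; a full
#' irreproducible-discovery-rate implementation can be injected via
#' `scorer`. The final filter keeps merged peaks with fold enrichment
#' >= `fold_cut` and p <= `p_cut`.
#'
#' @param rep1,rep2 data frames with `chrom`, `start`, `end`, `strand`,
#'   `log2fc`, `neglog10p` (0-based half-open coordinates).
#' @param idr_threshold reproducibility cutoff (default 0.01).
#' @param scorer `function(l2fc_rep1, l2fc_rep2, idr_threshold)` returning a
#'   logical keep vector over merged candidates, or `NULL` for the default.
#' @param fold_cut,p_cut final thresholds (defaults: fold >= 8, p <= 0.001).
#' @return data frame of reproducible peaks with merged and per-replicate
#'   scores.
#' @export
reproducible_peaks <- function(rep1, rep2, idr_threshold = 0.01,
                               scorer = NULL, fold_cut = 8, p_cut = 1e-3) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      log2fc = numeric(0), neglog10p = numeric(0),
                      log2fc_rep1 = numeric(0), log2fc_rep2 = numeric(0),
                      neglog10p_rep1 = numeric(0), neglog10p_rep2 = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(rep1) == 0 || nrow(rep2) == 0) return(empty)
  if (length(intersect(unique(rep1$chrom), unique(rep2$chrom))) == 0)
    stop_invalid("replicate peak sets share no chromosome: different reference?")

  hits <- overlap_hits(rep1, rep2)
  if (nrow(hits) == 0) return(empty)
  gm <- function(x, y) sqrt(pmax(0, x) * pmax(0, y))
  cand <- data.frame(
    chrom = rep1$chrom[hits$q],
    start = pmin(rep1$start[hits$q], rep2$start[hits$s]),
    end = pmax(rep1$end[hits$q], rep2$end[hits$s]),
    strand = rep1$strand[hits$q],
    log2fc_rep1 = rep1$log2fc[hits$q], log2fc_rep2 = rep2$log2fc[hits$s],
    neglog10p_rep1 = rep1$neglog10p[hits$q],
    neglog10p_rep2 = rep2$neglog10p[hits$s],
    stringsAsFactors = FALSE)
  cand$log2fc <- gm(cand$log2fc_rep1, cand$log2fc_rep2)
  cand$neglog10p <- gm(cand$neglog10p_rep1, cand$neglog10p_rep2)
  # one candidate per rep1 peak: best-scoring partner
  ord <- order(hits$q, -cand$log2fc)
  cand <- cand[ord, , drop = FALSE]
  cand <- cand[!duplicated(hits$q[ord]), , drop = FALSE]

  if (is.null(scorer)) scorer <- rank_consistency_scorer
  keep <- scorer(cand$log2fc_rep1, cand$log2fc_rep2, idr_threshold)
  out <- cand[keep & cand$log2fc >= log2(fold_cut) &
                cand$neglog10p >= -log10(p_cut), , drop = FALSE]
  rownames(out) <- NULL
  out[, names(empty)]
}

# Default reproducibility surrogate: flag the idr_threshold fraction of
# candidates with the most discordant fold-enrichment rank percentiles.
rank_consistency_scorer <- function(l1, l2, idr_threshold) {
  n <- length(l1)
  if (n == 0) return(logical(0))
  u <- rank(l1, ties.method = "average") / n
  v <- rank(l2, ties.method = "average") / n
  d <- abs(u - v)
  d <= stats::quantile(d, 1 - min(1, idr_threshold)) + 1e-12
}

# strand- and chrom-aware interval overlap hits between two peak frames
overlap_hits <- function(a, b, minoverlap = 1L) {
  ha <- paste(a$chrom, a$strand); hb <- paste(b$chrom, b$strand)
  ov <- IRanges::findOverlaps(to_ir(a$start, a$end), to_ir(b$start, b$end),
                              minoverlap = minoverlap)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  keep <- ha[q] == hb[s]
  data.frame(q = q[keep], s = s[keep])
}

#' Remove peaks overlapping blacklist regions
#'
#' A peak is removed when it overlaps any blacklist interval by >= 1 nt
#' (half-open intervals; strand is ignored, as blacklist artefacts are
#' positional). The blacklist itself is an input file; the function makes
#' no assumption about how many regions it holds.
#'
#' @param peaks peak data frame (`chrom`, `start`, `end`, ...).
#' @param blacklist data frame `chrom`, `start`, `end`.
#' @return the surviving peaks.
#' @export
remove_blacklist <- function(peaks, blacklist) {
  if (nrow(peaks) == 0 || is.null(blacklist) || nrow(blacklist) == 0)
    return(peaks)
  ov <- IRanges::findOverlaps(to_ir(peaks$start, peaks$end),
                              to_ir(blacklist$start, blacklist$end),
                              minoverlap = 1L)
  q <- S4Vectors::queryHits(ov)
  same <- peaks$chrom[q] == blacklist$chrom[S4Vectors::subjectHits(ov)]
  drop <- unique(q[same])
  if (length(drop)) peaks[-drop, , drop = FALSE] else peaks
}

#' Derive annotatable region tracks from a transcriptome
#'
#' Expands the per-transcript features into the label tracks consumed by
#' [annotate_peak()]: direct labels (trna, mirna, cds, three_utr, five_utr,
#' noncoding_exon) pass through; introns contribute 5' and 3' splice-site
#' windows (`ss_window` nt of intron adjacent to the exon), proximal-intron
#' windows (within `proximal_window` nt of either splice site) and a distal
#' track for the interior; miRNA genes contribute `mirna_window`-nt
#' mirna_proximal flanks. Tracks may overlap; [annotate_peak()] resolves
#' them by priority.
#'
#' @param annotation a `transcriptome`.
#' @param ss_window splice-site window width (nt, default 100).
#' @param proximal_window proximal-intron extent (nt, default 500).
#' @param mirna_window miRNA-proximal extent (nt, default 500).
#' @return data frame `gene_id`, `label`, `start`, `end`, `strand`.
#' @export
region_tracks <- function(annotation, ss_window = 100L,
                          proximal_window = 500L, mirna_window = 500L) {
  f <- annotation$features
  direct <- f[f$region != "intron", , drop = FALSE]
  out <- list(data.frame(gene_id = direct$gene_id, label = direct$region,
                         start = direct$start, end = direct$end,
                         strand = direct$strand, stringsAsFactors = FALSE))
  ins <- f[f$region == "intron", , drop = FALSE]
  if (nrow(ins) > 0) {
    s <- ins$start; e <- ins$end; plus <- ins$strand == "+"
    row4 <- function(label, st, en) {
      keep <- en > st
      data.frame(gene_id = ins$gene_id[keep], label = label,
                 start = st[keep], end = en[keep],
                 strand = ins$strand[keep], stringsAsFactors = FALSE)
    }
    don_s <- ifelse(plus, s, pmax(s, e - ss_window))
    don_e <- ifelse(plus, pmin(e, s + ss_window), e)
    acc_s <- ifelse(plus, pmax(s, e - ss_window), s)
    acc_e <- ifelse(plus, e, pmin(e, s + ss_window))
    out <- c(out, list(
      row4("five_ss", don_s, don_e),
      row4("three_ss", acc_s, acc_e),
      row4("proximal_intron", s, pmin(e, s + proximal_window)),
      row4("proximal_intron", pmax(s, e - proximal_window), e),
      row4("distal_intron", s + proximal_window, e - proximal_window)))
  }
  mir <- f[f$region == "mirna", , drop = FALSE]
  if (nrow(mir) > 0) {
    out <- c(out, list(
      data.frame(gene_id = mir$gene_id, label = "mirna_proximal",
                 start = pmax(0L, mir$start - mirna_window), end = mir$start,
                 strand = mir$strand, stringsAsFactors = FALSE),
      data.frame(gene_id = mir$gene_id, label = "mirna_proximal",
                 start = mir$end, end = mir$end + mirna_window,
                 strand = mir$strand, stringsAsFactors = FALSE)))
  }
  res <- do.call(rbind, out)
  res <- res[res$end > res$start, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Annotate peaks with a single region label by priority
#'
#' Each peak receives exactly one of the 11 region labels. Overlap is >= 1
#' nt on half-open intervals and same-strand only. Within a single gene the
#' label is chosen in the order tRNA > miRNA > miRNA-proximal > CDS > 3'UTR
#' > 5'UTR > 5' splice site > 3' splice site > proximal intron > distal
#' intron > noncoding exonic; when the peak overlaps several genes, each
#' gene is first reduced to its best within-gene label and the final label
#' is chosen among those in the cross-gene order tRNA > miRNA > CDS > 3'UTR
#' > 5'UTR > miRNA-proximal > noncoding exonic > 5'ss > 3'ss > proximal >
#' distal intron. Peaks overlapping no gene are labelled "intergenic".
#'
#' @param peaks data frame `start`, `end`, `strand` (plus anything else).
#' @param tracks region tracks from [region_tracks()] (or constructed
#'   directly: `gene_id`, `label`, `start`, `end`, `strand`).
#' @return character vector of labels, one per peak.
#' @export
annotate_peak <- function(peaks, tracks) {
  n <- nrow(peaks)
  labels <- rep("intergenic", n)
  if (n == 0 || nrow(tracks) == 0) return(labels)
  ov <- IRanges::findOverlaps(to_ir(peaks$start, peaks$end),
                              to_ir(tracks$start, tracks$end),
                              minoverlap = 1L)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  keep <- peaks$strand[q] == tracks$strand[s]
  q <- q[keep]; s <- s[keep]
  if (length(q) == 0) return(labels)
  wr <- match(tracks$label[s], WITHIN_GENE_PRIORITY)
  cr <- match(tracks$label[s], CROSS_GENE_PRIORITY)
  if (anyNA(wr)) stop_invalid("unknown region label in tracks")
  hit <- data.frame(q = q, gene = tracks$gene_id[s], wr = wr, cr = cr)
  for (pi in unique(hit$q)) {
    h <- hit[hit$q == pi, , drop = FALSE]
    # best label within each overlapped gene
    best <- do.call(rbind, lapply(split(h, h$gene), function(g) {
      g[which.min(g$wr), , drop = FALSE]
    }))
    lab <- if (nrow(best) == 1) WITHIN_GENE_PRIORITY[best$wr]
           else CROSS_GENE_PRIORITY[min(best$cr)]
    labels[pi] <- lab
  }
  labels
}

#' Fraction of peaks per region label
#'
#' @param labels character vector of labels from [annotate_peak()].
#' @return named numeric vector over all observed labels (canonical 11
#'   first), nonnegative and summing to 1. Serves as the input vector for
#'   external clustering of binding profiles.
#' @export
region_fraction_vector <- function(labels) {
  if (length(labels) == 0) stop_invalid("empty peak set")
  lev <- union(WITHIN_GENE_PRIORITY, unique(labels))
  tab <- table(factor(labels, levels = lev))
  as.vector(tab) / length(labels) -> fr
  names(fr) <- lev
  fr
}
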