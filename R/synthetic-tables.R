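# Simulators for knockdown RNA-seq style tables and ChIP peak sets.

#' Simulate knockdown splicing-event and gene-expression tables
#'
#' Produces an rMATS-style skipped-exon table and a differential-expression
#' table with planted effects taken from the supplied ground truth. Control
#' inclusion levels are drawn from a Beta(2, 2) distribution (the native-psi
#' distribution is a documented modelling choice, configurable through
#' `psi_shape`). Null events carry p ~ Uniform(0, 1); planted events draw p
#' from Beta(0.05, 1) truncated to <= 1e-4 so that the stated significance
#' thresholds (p < 0.05, FDR < 0.1, |dpsi| > 0.05) are met by construction
#' whenever the planted |dpsi| >= 0.06. FDR is Benjamini-Hochberg across
#' the table.
#'
#' @param annotation a `transcriptome`.
#' @param truth a `binding_truth` (its `regulation` rows become the first
#'   events of the table).
#' @param n_events number of skipped-exon events (>= 1).
#' @param seed integer seed.
#' @param psi_shape two Beta shape parameters for control inclusion levels.
#' @param de_lfc |log2 fold-change| planted on regulated genes in the
#'   expression table (knockdown-decreased).
#' @return list of class `kd_sim` with data frames `events` (`event_id`,
#'   `gene_id`, `type`, `strand`, exon and flanking-exon coordinates,
#'   `psi_control`, `psi_kd`, `dpsi`, `p`, `fdr`, `regulated`) and
#'   `expression` (`gene_id`, `tpm_a`, `tpm_b`, `log2fc`, `p`, `padj`).
#' @export
simulate_kd_tables <- function(annotation, truth, n_events = 500, seed = 1,
                               psi_shape = c(2, 2), de_lfc = 2) {
  stopifnot(inherits(annotation, "transcriptome"),
            inherits(truth, "binding_truth"))
  if (n_events < 1) stop_invalid("n_events must be >= 1")
  n_events <- as.integer(n_events)
  with_seed(seed, {
    cand <- se_candidates(annotation)
    reg <- truth$regulation
    n_reg <- if (is.null(reg) || nrow(reg) == 0) 0L else min(nrow(reg), n_events)
    # null events are drawn from exons WITHOUT planted regulation, so that
    # native background sets are unbound by construction
    null_pool <- cand
    if (n_reg > 0) {
      reg_key <- paste(reg$gene_id, reg$exon_start, reg$exon_end)
      null_pool <- cand[!paste(cand$gene_id, cand$exon_start,
                               cand$exon_end) %in% reg_key, , drop = FALSE]
      if (nrow(null_pool) == 0) null_pool <- cand
    }
    picks <- null_pool[sample(nrow(null_pool), n_events, replace = TRUE),
                       , drop = FALSE]
    if (n_reg > 0) picks[seq_len(n_reg), ] <- reg[seq_len(n_reg),
                                                  names(picks), drop = FALSE]
    ev <- data.frame(event_id = sprintf("SE%05d", seq_len(n_events)),
                     type = "SE", picks, stringsAsFactors = FALSE)
    regulated <- seq_len(n_events) <= n_reg

    psi_c <- stats::rbeta(n_events, psi_shape[1], psi_shape[2])
    dpsi_t <- rep(0, n_events)
    if (n_reg > 0) {
      # leave room for the planted shift so the thresholds are met exactly
      psi_c[regulated] <- stats::runif(n_reg, 0.1, 0.9)
      dpsi_t[regulated] <- reg$dpsi[seq_len(n_reg)]
    }
    psi_kd <- pmin(1, pmax(0, psi_c + dpsi_t +
                             ifelse(regulated, 0, stats::rnorm(n_events, 0, 0.01))))
    p <- stats::runif(n_events)
    if (n_reg > 0) {
      u <- stats::runif(n_reg)
      p[regulated] <- 1e-4 * u^(1 / 0.05)
    }
    ev$psi_control <- round(psi_c, 4)
    ev$psi_kd <- round(psi_kd, 4)
    ev$dpsi <- round(psi_kd - psi_c, 4)
    ev$p <- p
    ev$fdr <- stats::p.adjust(p, method = "BH")
    ev$regulated <- regulated

    tx <- annotation$transcripts
    gx <- stats::aggregate(cbind(tpm_a, tpm_b) ~ gene_id, data = tx, FUN = sum)
    de_genes <- unique(ev$gene_id[regulated])
    is_de <- gx$gene_id %in% de_genes
    gx$log2fc <- stats::rnorm(nrow(gx), 0, 0.3)
    gx$log2fc[is_de] <- -de_lfc + stats::rnorm(sum(is_de), 0, 0.1)
    gp <- stats::runif(nrow(gx))
    gp[is_de] <- 1e-4 * stats::runif(sum(is_de))^(1 / 0.05)
    gx$p <- gp
    gx$padj <- stats::p.adjust(gp, method = "BH")

    out <- list(events = ev, expression = gx)
    class(out) <- "kd_sim"
    out
  })
}

#' Simulate a ChIP experiment: promoter-biased peaks and a signal track
#'
#' Peaks are placed with per-base odds `promoter_bias` : 1 of landing inside
#' 1-kb windows around annotated TSSs; the accompanying signal track is
#' piecewise constant and nonnegative, with elevated signal over the peaks.
#'
#' @param annotation a `transcriptome` (must contain at least one gene).
#' @param promoter_bias odds multiplier for promoter bases (>= 1).
#' @param seed integer seed.
#' @param n_peaks number of peaks.
#' @param peak_len peak length (nt).
#' @param bin signal-track bin width (nt).
#' @return list of class `chip_sim` with `peaks` (BED-like data frame) and
#'   `track` (`chrom`, `start`, `end`, `value`), plus the promoter windows.
#' @export
simulate_chip <- function(annotation, promoter_bias = 5, seed = 1,
                          n_peaks = 300, peak_len = 200L, bin = 100L) {
  stopifnot(inherits(annotation, "transcriptome"))
  if (nrow(annotation$genes) == 0) stop_invalid("annotation contains no genes")
  if (promoter_bias < 1) stop_invalid("promoter_bias must be >= 1")
  with_seed(seed, {
    L <- annotation$chrom_len
    prom <- promoter_windows(annotation)
    w <- rep(1, L)
    for (i in seq_len(nrow(prom)))
      w[(prom$start[i] + 1L):prom$end[i]] <- promoter_bias
    starts <- sample_weighted(n_peaks, w[seq_len(L - peak_len)]) - 1L
    peaks <- data.frame(chrom = annotation$chrom, start = starts,
                        end = starts + peak_len,
                        name = sprintf("chip%04d", seq_len(n_peaks)),
                        score = round(stats::runif(n_peaks, 10, 1000), 1),
                        strand = ".", stringsAsFactors = FALSE)
    peaks <- peaks[order(peaks$start), , drop = FALSE]
    rownames(peaks) <- NULL

    nb <- ceiling(L / bin)
    bs <- (seq_len(nb) - 1L) * bin
    be <- pmin(bs + bin, L)
    val <- round(stats::rexp(nb, rate = 1), 3)
    pk_ir <- to_ir(peaks$start, peaks$end)
    bin_ir <- to_ir(bs, be)
    ov <- IRanges::countOverlaps(bin_ir, pk_ir, minoverlap = 1L)
    val <- val + 5 * (ov > 0)
    track <- data.frame(chrom = annotation$chrom, start = bs, end = be,
                        value = val, stringsAsFactors = FALSE)
    out <- list(peaks = peaks, track = track, promoters = prom)
    class(out) <- "chip_sim"
    out
  })
}

#' 1-kb promoter windows around annotated TSSs
#'
#' @param annotation a `transcriptome`.
#' @param flank half-width of the window (nt) on each side of the TSS.
#' @return data frame `gene_id`, `start`, `end` (clipped to the chromosome).
#' @export
promoter_windows <- function(annotation, flank = 1000L) {
  g <- annotation$genes
  data.frame(gene_id = g$gene_id,
             start = pmax(0L, g$tss - flank),
             end = pmin(annotation$chrom_len, g$tss + flank),
             stringsAsFactors = FALSE)
}

# mean signal of a piecewise-constant track over a 0-based half-open window
track_mean <- function(track, start, end) {
  if (end <= start) return(NA_real_)
  ov <- ivl_overlap(track$start, track$end, start, end)
  keep <- ov > 0
  if (!any(keep)) return(0)
  sum(track$value[keep] * ov[keep]) / (end - start)
}
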