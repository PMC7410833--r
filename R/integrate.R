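# Statistics linking RBP binding to expression change, chromatin
# association and subcellular localization.

#' Classify differential-expression strength
#'
#' For genes already called significant: strong when |log2 fold-change|
#' >= 2, moderate when between 1 and 2, weak when <= 1.
#'
#' @param log2fc log2 fold-changes.
#' @return factor with levels weak, moderate, strong.
#' @export
de_classify <- function(log2fc) {
  a <- abs(log2fc)
  out <- ifelse(a >= 2, "strong", ifelse(a > 1, "moderate", "weak"))
  factor(out, levels = c("weak", "moderate", "strong"))
}

#' Classify splicing-change strength
#'
#' For events already past the |dpsi| > 0.05 significance filter: strong
#' when |dpsi| >= 0.30, moderate when 0.15 <= |dpsi| < 0.30, weak when
#' 0.05 < |dpsi| < 0.15. Events with |dpsi| <= 0.05 are not classified
#' (NA).
#'
#' @param dpsi inclusion-level differences.
#' @return factor with levels weak, moderate, strong (NA below threshold).
#' @export
splicing_classify <- function(dpsi) {
  a <- abs(dpsi)
  out <- ifelse(a >= 0.30, "strong",
                ifelse(a >= 0.15, "moderate",
                       ifelse(a > 0.05, "weak", NA_character_)))
  factor(out, levels = c("weak", "moderate", "strong"))
}

#' Tandem-UTR significance from four pairwise comparisons
#'
#' Of the four knockdown-versus-control pairwise comparisons, significance
#' requires |Bayes factor| >= `bf_cut` and p < `p_cut` on both grouped
#' orderings: the higher-read knockdown replicate versus the lower-read
#' control replicate, and the lower-read knockdown versus the higher-read
#' control.
#'
#' @param comparisons data frame with one row per pairwise comparison:
#'   `kd_reads`, `cn_reads` (library sizes of the replicates compared),
#'   `bayes_factor`, `p`. All four comparisons must be present.
#' @param bf_cut,p_cut thresholds (defaults 5 and 0.05).
#' @return logical: significant or not.
#' @export
miso_tandem_filter <- function(comparisons, bf_cut = 5, p_cut = 0.05) {
  if (is.null(comparisons) || nrow(comparisons) != 4 ||
      anyNA(comparisons[, c("kd_reads", "cn_reads", "bayes_factor", "p")]))
    stop_invalid("all four pairwise comparisons must be supplied")
  pick <- function(kd_high, cn_high) {
    kd <- if (kd_high) max(comparisons$kd_reads) else min(comparisons$kd_reads)
    cn <- if (cn_high) max(comparisons$cn_reads) else min(comparisons$cn_reads)
    i <- which(comparisons$kd_reads == kd & comparisons$cn_reads == cn)[1]
    if (is.na(i)) stop_invalid("grouped comparison missing from the table")
    comparisons[i, ]
  }
  g1 <- pick(kd_high = TRUE, cn_high = FALSE)   # more-reads KD vs fewer CN
  g2 <- pick(kd_high = FALSE, cn_high = TRUE)   # fewer-reads KD vs more CN
  all(abs(c(g1$bayes_factor, g2$bayes_factor)) >= bf_cut,
      c(g1$p, g2$p) < p_cut)
}

#' Overlap between region-enriched genes and differentially expressed genes
#'
#' Two-sided test of independence on the 2x2 table of bound x DE within an
#' abundance-matched background (genes whose region passed the 10-read
#' eligibility rule for this data set). Yates-corrected chi-square when all
#' observed and expected cells exceed 5, Fisher's exact test otherwise.
#' The comparison is run only when more than `min_de` genes in the
#' background changed significantly; up- and down-regulated sets are
#' tested separately by the caller. Bonferroni adjustment is applied over
#' `n_comparisons` (the number of comparisons actually executed in the
#' family; skipped comparisons are not counted).
#'
#' @param bound_genes genes with significant region-level enrichment.
#' @param de_genes genes significantly changed upon knockdown (one
#'   direction).
#' @param background eligible background gene universe.
#' @param min_de minimum DE-set size to run the comparison (default 10,
#'   exclusive).
#' @param n_comparisons size of the Bonferroni family (default 1).
#' @return list `p`, `p_bonferroni`, `table`, `skipped`, `reason`.
#' @export
expression_overlap <- function(bound_genes, de_genes, background,
                               min_de = 10, n_comparisons = 1) {
  if (length(background) == 0) stop_invalid("empty background gene set")
  bound <- intersect(unique(bound_genes), background)
  de <- intersect(unique(de_genes), background)
  if (length(de) <= min_de) {
    return(list(p = NA_real_, p_bonferroni = NA_real_, table = NULL,
                skipped = TRUE,
                reason = sprintf("DE set has %d genes (<= %d)",
                                 length(de), min_de)))
  }
  a <- length(intersect(bound, de))
  b <- length(bound) - a
  c_ <- length(de) - a
  d_ <- length(background) - a - b - c_
  p <- fisher_or_yates(a, b, c_, d_)
  list(p = p, p_bonferroni = min(1, p * n_comparisons),
       table = matrix(c(a, b, c_, d_), 2, byrow = TRUE,
                      dimnames = list(c("bound", "unbound"),
                                      c("DE", "notDE"))),
       skipped = FALSE, reason = NULL)
}

#' Kolmogorov-Smirnov comparison of fold-changes across enrichment classes
#'
#' Two-sided KS test of the knockdown fold-change distribution of each
#' eCLIP-enriched gene category against the reference (unenriched)
#' category. Degenerate categories (< 2 genes) are skipped.
#'
#' @param log2fc per-gene fold-changes.
#' @param category per-gene enrichment category (factor or character).
#' @param reference name of the reference category.
#' @return data frame `category`, `n`, `p` (NA when skipped).
#' @export
ks_by_enrichment <- function(log2fc, category, reference = "not_enriched") {
  category <- as.character(category)
  ref <- log2fc[category == reference & is.finite(log2fc)]
  cats <- setdiff(unique(category), reference)
  res <- lapply(cats, function(cc) {
    x <- log2fc[category == cc & is.finite(log2fc)]
    p <- if (length(x) >= 2 && length(ref) >= 2)
      suppressWarnings(stats::ks.test(x, ref)$p.value) else NA_real_
    data.frame(category = cc, n = length(x), p = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Base-level Jaccard index between two interval sets
#'
#' @param a,b data frames `start`, `end` (0-based half-open; same
#'   reference). Empty sets give 0 by convention.
#' @return |intersection| / |union| in bases.
#' @export
jaccard_index <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  ia <- IRanges::reduce(to_ir(a$start, a$end))
  ib <- IRanges::reduce(to_ir(b$start, b$end))
  inter <- sum(IRanges::width(IRanges::intersect(ia, ib)))
  uni <- sum(IRanges::width(IRanges::union(ia, ib)))
  if (uni == 0) 0 else inter / uni
}

#' Pairwise Jaccard matrices at promoter and non-promoter compartments
#'
#' Peak sets are first intersected with the promoter space (1-kb windows
#' around TSSs) or its complement, then compared pairwise by base-level
#' Jaccard index.
#'
#' @param peak_sets named list of peak data frames.
#' @param promoters data frame `start`, `end` (e.g. [promoter_windows()]).
#' @param chrom_len chromosome length (for the complement).
#' @return list of two symmetric matrices `promoter`, `non_promoter`.
#' @export
jaccard_matrix <- function(peak_sets, promoters, chrom_len) {
  prom <- IRanges::reduce(to_ir(promoters$start, promoters$end))
  nonprom <- IRanges::gaps(prom, start = 1L, end = chrom_len)
  clip <- function(p, space) {
    ir <- IRanges::intersect(IRanges::reduce(to_ir(p$start, p$end)), space)
    data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  }
  n <- length(peak_sets)
  mk <- function(space) {
    clipped <- lapply(peak_sets, clip, space = space)
    m <- matrix(0, n, n, dimnames = list(names(peak_sets), names(peak_sets)))
    for (i in seq_len(n)) for (j in i:n) {
      m[i, j] <- m[j, i] <- jaccard_index(clipped[[i]], clipped[[j]])
    }
    m
  }
  list(promoter = mk(prom), non_promoter = mk(nonprom))
}

#' ChIP signal enrichment at eCLIP peaks versus flanking regions
#'
#' For each eCLIP peak (restricted by the caller to gene bodies, i.e.
#' excluding 1-kb windows around TSS and TTS), the mean ChIP signal within
#' the peak is compared with the mean over flanking regions ten times the
#' peak length on each side (truncated at chromosome ends and flagged).
#' Across peaks, a one-sided Wilcoxon rank-sum test asks whether the
#' in-peak signal exceeds the flanking signal; the stated significance
#' level is p <= 0.001 with no multiple-comparison correction.
#'
#' @param track signal track data frame `start`, `end`, `value`
#'   (piecewise constant, nonnegative).
#' @param peaks eCLIP peak data frame `start`, `end`.
#' @param chrom_len chromosome length.
#' @param flank_mult flank length as a multiple of the peak length
#'   (default 10).
#' @return list `p`, `peak_signal`, `flank_signal`, `truncated`,
#'   `significant`.
#' @export
chip_at_eclip <- function(track, peaks, chrom_len, flank_mult = 10) {
  n <- nrow(peaks)
  if (n == 0) return(list(p = NA_real_, significant = FALSE))
  mid <- numeric(n); fl <- numeric(n); trunc_flag <- logical(n)
  for (i in seq_len(n)) {
    s <- peaks$start[i]; e <- peaks$end[i]; len <- e - s
    mid[i] <- track_mean(track, s, e)
    ls <- max(0L, s - flank_mult * len)
    re <- min(chrom_len, e + flank_mult * len)
    trunc_flag[i] <- (s - flank_mult * len < 0) ||
      (e + flank_mult * len > chrom_len)
    w1 <- s - ls; w2 <- re - e
    m1 <- if (w1 > 0) track_mean(track, ls, s) else NA_real_
    m2 <- if (w2 > 0) track_mean(track, e, re) else NA_real_
    fl[i] <- sum(c(m1 * w1, m2 * w2), na.rm = TRUE) / sum(c(w1, w2))
  }
  if (all(mid == 0) && all(fl == 0))
    return(list(p = NA_real_, peak_signal = mid, flank_signal = fl,
                truncated = trunc_flag, significant = FALSE,
                note = "all-zero signal track"))
  p <- if (all(mid == fl)) 0.5
       else suppressWarnings(stats::wilcox.test(mid, fl,
                                                alternative = "greater")$p.value)
  list(p = p, peak_signal = mid, flank_signal = fl, truncated = trunc_flag,
       significant = is.finite(p) && p <= 0.001)
}

#' Resampled dependence between TSS binding and knockdown response
#'
#' In each of `n_rounds` rounds, every TSS-bound gene is paired with an
#' expression-matched (same TPM decile) unbound gene sampled without
#' replacement; the 2x2 table of binding x differential expression is
#' tested by a one-tailed Fisher's exact test and the odds ratio
#' (a/b)/(c/d) recorded. Dependence is declared when the null is rejected
#' at `alpha` in at least `min_hits` of the rounds.
#'
#' @param bound_genes TSS-bound gene ids.
#' @param de_genes differentially expressed gene ids (fold-change > 1.5 or
#'   < 2/3 with adjusted p < 0.05, per the stated definition; the filter
#'   is applied by the caller).
#' @param expression data frame `gene_id`, `tpm` for the whole universe.
#' @param n_rounds number of resampling rounds (default 100).
#' @param seed integer seed.
#' @param alpha per-round significance level (default 0.05).
#' @param min_hits rounds required for a dependence verdict (default 95).
#' @param n_bins expression bins for matching (default 10 = deciles).
#' @return list `dependent`, `n_significant`, `odds_ratios`, `p_values`;
#'   `dependent = NA` when matching is infeasible.
#' @export
chip_kd_dependence <- function(bound_genes, de_genes, expression,
                               n_rounds = 100, seed = 1, alpha = 0.05,
                               min_hits = 95, n_bins = 10) {
  genes <- expression$gene_id
  is_bound <- genes %in% bound_genes
  is_de <- genes %in% de_genes
  if (!any(is_bound) || all(is_bound))
    return(list(dependent = NA, n_significant = NA_integer_,
                odds_ratios = numeric(0), p_values = numeric(0),
                reason = "no bound/unbound contrast available"))
  br <- unique(stats::quantile(expression$tpm,
                               probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- findInterval(expression$tpm, br, rightmost.closed = TRUE,
                      all.inside = TRUE)
  bidx <- which(is_bound)
  feasible <- all(vapply(split(seq_along(genes), bin), function(ii) {
    sum(is_bound[ii]) <= sum(!is_bound[ii]) || sum(is_bound[ii]) == 0
  }, logical(1)))
  if (!feasible)
    return(list(dependent = NA, n_significant = NA_integer_,
                odds_ratios = numeric(0), p_values = numeric(0),
                reason = "expression-matched sampling infeasible"))
  with_seed(seed, {
    pvals <- numeric(n_rounds); ors <- numeric(n_rounds)
    for (r in seq_len(n_rounds)) {
      ctrl <- integer(0)
      for (bb in unique(bin[bidx])) {
        need <- sum(bin[bidx] == bb)
        pool <- which(!is_bound & bin == bb)
        ctrl <- c(ctrl, pool[sample.int(length(pool), need)])
      }
      a <- sum(is_de[bidx]); b <- length(bidx) - a
      cc <- sum(is_de[ctrl]); dd <- length(ctrl) - cc
      pvals[r] <- stats::fisher.test(matrix(c(a, b, cc, dd), 2, byrow = TRUE),
                                     alternative = "greater")$p.value
      ors[r] <- if (b > 0 && cc > 0 && dd > 0) (a / b) / (cc / dd) else NA_real_
    }
    nsig <- sum(pvals < alpha)
    list(dependent = nsig >= min_hits, n_significant = nsig,
         odds_ratios = ors, p_values = pvals)
  })
}

#' Association between localization labels and eCLIP relative information
#'
#' For each (RNA class, localization label) pair, a one-sided Wilcoxon
#' rank-sum test of whether RBPs carrying the label have higher relative
#' information for the class than RBPs without it. Pairs with an empty
#' side are skipped (NA).
#'
#' @param info matrix of relative information (RBPs x RNA classes).
#' @param labels logical matrix (RBPs x localization labels).
#' @return matrix of p-values (RNA classes x labels).
#' @export
localization_association <- function(info, labels) {
  stopifnot(nrow(info) == nrow(labels))
  out <- matrix(NA_real_, ncol(info), ncol(labels),
                dimnames = list(colnames(info), colnames(labels)))
  for (j in seq_len(ncol(labels))) {
    lab <- labels[, j]
    if (sum(lab) < 2 || sum(!lab) < 2) next
    for (i in seq_len(ncol(info))) {
      out[i, j] <- suppressWarnings(
        stats::wilcox.test(info[lab, i], info[!lab, i],
                           alternative = "greater")$p.value)
    }
  }
  out
}

#' Count spliced and unspliced reads against annotated junctions
#'
#' A spliced read maps across an annotated splice junction with its
#' alignment gap exactly matching an annotated intron and extending at
#' least `min_overhang` nt into each flanking exon. An unspliced read is a
#' contiguous read spanning an exon-intron boundary with at least
#' `min_overhang` nt on each side. The two classes are mutually exclusive
#' for any single read; reads shorter than 2 * `min_overhang` are never
#' classified.
#'
#' @param reads data frame `start`, `end`, and optionally `gap_start`,
#'   `gap_end` (NA for contiguous reads).
#' @param introns data frame `start`, `end` of annotated introns.
#' @param min_overhang minimum anchor length (default 10 nt).
#' @return list `spliced`, `unspliced`, `neither` (counts), and the
#'   per-read classification.
#' @export
spliced_unspliced_counts <- function(reads, introns, min_overhang = 10L) {
  n <- nrow(reads)
  gs <- if (!is.null(reads$gap_start)) reads$gap_start else rep(NA, n)
  ge <- if (!is.null(reads$gap_end)) reads$gap_end else rep(NA, n)
  cls <- rep("neither", n)
  has_gap <- !is.na(gs) & !is.na(ge)
  rl <- ifelse(has_gap, (gs - reads$start) + (reads$end - ge),
               reads$end - reads$start)
  long_enough <- rl >= 2L * min_overhang
  # spliced: gap matches an annotated intron, anchors >= min_overhang
  if (any(has_gap)) {
    key <- paste(introns$start, introns$end)
    match_j <- paste(gs, ge) %in% key
    cls[has_gap & long_enough & match_j &
          (gs - reads$start) >= min_overhang &
          (reads$end - ge) >= min_overhang] <- "spliced"
  }
  # unspliced: contiguous over an exon-intron boundary with both anchors
  contig <- !has_gap & long_enough
  if (any(contig) && nrow(introns) > 0) {
    ci <- which(contig)
    bounds <- c(introns$start, introns$end)
    for (i in ci) {
      anchored <- bounds - reads$start[i] >= min_overhang &
        reads$end[i] - bounds >= min_overhang
      if (any(anchored)) cls[i] <- "unspliced"
    }
  }
  list(spliced = sum(cls == "spliced"), unspliced = sum(cls == "unspliced"),
       neither = sum(cls == "neither"), classification = cls)
}

#' Classify an RBP's compartment from its nuclear:cytoplasmic ratio
#'
#' @param ratio nuclear:cytoplasmic staining ratio (> 0).
#' @return "nuclear" (ratio >= 2), "cytoplasmic" (<= 0.5) or "neither".
#' @export
classify_localization <- function(ratio) {
  ifelse(ratio >= 2, "nuclear", ifelse(ratio <= 0.5, "cytoplasmic",
                                       "neither"))
}
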