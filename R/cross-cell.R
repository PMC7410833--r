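# Cross-cell-type preservation of binding, saturation analyses and
# covered-base accounting on the highest-expressed isoform.

#' Categorize genes by cross-cell expression difference
#'
#' Classification on relative TPM difference between two cell types:
#' unchanged (fold-difference <= 1.2), weak (<= 2), moderate (<= 5) or
#' strong (> 5), each requiring TPM >= `tpm_expressed` in both cells;
#' cell-type-specific (TPM < `tpm_absent` in one cell and >= `tpm_expressed`
#' in the other); everything else (including missing values) is "other".
#'
#' @param tpm_a,tpm_b expression (TPM) in the two cell types.
#' @param fold_bounds upper fold-difference bounds for
#'   unchanged/weak/moderate.
#' @param tpm_expressed,tpm_absent TPM boundaries (defaults 1 and 0.1).
#' @return factor with levels unchanged, weak, moderate, strong, specific,
#'   other (mutually exclusive and exhaustive).
#' @export
classify_expression_category <- function(tpm_a, tpm_b,
                                         fold_bounds = c(1.2, 2, 5),
                                         tpm_expressed = 1,
                                         tpm_absent = 0.1) {
  n <- max(length(tpm_a), length(tpm_b))
  a <- rep_len(as.numeric(tpm_a), n); b <- rep_len(as.numeric(tpm_b), n)
  fd <- pmax(a, b) / pmin(a, b)
  both <- !is.na(a) & !is.na(b) & a >= tpm_expressed & b >= tpm_expressed
  out <- rep("other", n)
  out[both & fd > fold_bounds[3]] <- "strong"
  out[both & fd <= fold_bounds[3]] <- "moderate"
  out[both & fd <= fold_bounds[2]] <- "weak"
  out[both & fd <= fold_bounds[1]] <- "unchanged"
  spec <- !is.na(a) & !is.na(b) &
    ((a < tpm_absent & b >= tpm_expressed) |
     (b < tpm_absent & a >= tpm_expressed))
  out[spec] <- "specific"
  factor(out, levels = c("unchanged", "weak", "moderate", "strong",
                         "specific", "other"))
}

#' Preservation of peaks in a second cell type
#'
#' For each peak called in cell A, computes the fold enrichment of the same
#' interval in cell B from B's IP and input coverage, categorizes the
#' peak's gene by cross-cell expression, and summarizes per category the
#' fraction of peaks at least `fold_cut`-fold enriched versus not enriched
#' (fold <= 1) in B. Distributions of B-enrichment are compared between
#' categories by two-sided Kolmogorov-Smirnov tests.
#'
#' @param peaks data frame `start`, `end`, `gene_id` (0-based half-open).
#' @param cov_b list with per-base count vectors `ip`, `input` and totals
#'   `ip_total`, `input_total` for cell B.
#' @param expression data frame `gene_id`, `tpm_a`, `tpm_b`.
#' @param fold_cut preservation threshold (default 4).
#' @return list with `per_peak` (`fold_b`, `category`), `summary`
#'   (per-category n, `frac_preserved`, `frac_not_enriched`) and `ks`
#'   (pairwise KS p-values).
#' @export
cross_cell_preservation <- function(peaks, cov_b, expression, fold_cut = 4) {
  stopifnot(nrow(peaks) > 0)
  ipc <- region_sums(cov_b$ip, peaks$start, peaks$end)
  inc <- region_sums(cov_b$input, peaks$start, peaks$end)
  fold_b <- (ipc / cov_b$ip_total) / (inc / cov_b$input_total)
  i <- match(peaks$gene_id, expression$gene_id)
  category <- classify_expression_category(expression$tpm_a[i],
                                           expression$tpm_b[i])
  per_peak <- data.frame(peaks, fold_b = fold_b, category = category,
                         stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(split(per_peak, per_peak$category), function(d) {
    if (nrow(d) == 0) return(NULL)
    data.frame(category = d$category[1], n = nrow(d),
               frac_preserved = mean(d$fold_b >= fold_cut, na.rm = TRUE),
               frac_not_enriched = mean(d$fold_b <= 1, na.rm = TRUE))
  }))
  rownames(summ) <- NULL
  cats <- as.character(unique(per_peak$category))
  ks <- list()
  if (length(cats) > 1) {
    for (i1 in seq_len(length(cats) - 1)) for (i2 in (i1 + 1):length(cats)) {
      x <- per_peak$fold_b[per_peak$category == cats[i1]]
      y <- per_peak$fold_b[per_peak$category == cats[i2]]
      x <- x[is.finite(x)]; y <- y[is.finite(y)]
      if (length(x) >= 2 && length(y) >= 2) {
        p <- suppressWarnings(stats::ks.test(x, y)$p.value)
        ks[[length(ks) + 1L]] <- data.frame(cat1 = cats[i1], cat2 = cats[i2],
                                            p = p)
      }
    }
  }
  list(per_peak = per_peak, summary = summ,
       ks = if (length(ks)) do.call(rbind, ks) else NULL)
}

# sums of a per-base vector over 0-based half-open windows
region_sums <- function(v, start, end) {
  cs <- c(0, cumsum(as.numeric(v)))
  cs[pmin(end, length(v)) + 1L] - cs[pmax(start, 0L) + 1L]
}

#' Saturation of discovery with increasing numbers of data sets
#'
#' Shuffles the order of data sets `n_shuffles` times and accumulates the
#' number of unique items (genes, events, ...) over prefixes of each
#' shuffle. Every curve is monotone non-decreasing and ends exactly at the
#' size of the union of all sets.
#'
#' @param sets list of vectors of item identifiers (one per data set).
#' @param n_shuffles number of random orderings (default 100).
#' @param seed integer seed.
#' @return list with `curves` (n_shuffles x n_sets matrix of cumulative
#'   unique counts), `mean`, `sd`, `min`, `max` per subsample size.
#' @export
saturation_curve <- function(sets, n_shuffles = 100, seed = 1) {
  stopifnot(length(sets) >= 1)
  K <- length(sets)
  with_seed(seed, {
    curves <- matrix(0L, nrow = n_shuffles, ncol = K)
    for (b in seq_len(n_shuffles)) {
      perm <- sample.int(K)
      all <- unlist(sets[perm], use.names = FALSE)
      newc <- cumsum(!duplicated(all))
      ends <- cumsum(lengths(sets[perm]))
      curves[b, ] <- ifelse(ends > 0, newc[pmax(ends, 1L)], 0L)
    }
    list(curves = curves, mean = colMeans(curves),
         sd = apply(curves, 2, stats::sd),
         min = apply(curves, 2, min), max = apply(curves, 2, max))
  })
}

#' Covered-base fraction per transcript region type
#'
#' For cumulative unions over an ordered list of peak sets, computes the
#' fraction of bases of each region type covered by at least one peak,
#' using the highest-expressed isoform of each gene (ties broken by
#' transcript id). Splice-site regions are the 100-nt intronic windows,
#' proximal introns extend 100-500 nt from the splice sites and distal
#' introns beyond 500 nt. Peaks count on the gene's strand only.
#'
#' @param peak_sets ordered list of peak data frames (`start`, `end`,
#'   `strand`).
#' @param annotation a `transcriptome`.
#' @param region_types subset of pre_mrna, exon, five_utr, cds, three_utr,
#'   intron, splice_site, proximal_intron, distal_intron.
#' @param expression optional data frame `tx_id`, `tpm` overriding the
#'   annotation's `tpm_a` for isoform selection.
#' @return list with `fractions` (length(peak_sets) x length(region_types)
#'   matrix) and `fold_increase` (ratio of successive rows).
#' @export
base_coverage_by_region <- function(peak_sets, annotation,
                                    region_types = c("pre_mrna", "exon",
                                                     "intron"),
                                    expression = NULL) {
  known <- c("pre_mrna", "exon", "five_utr", "cds", "three_utr", "intron",
             "splice_site", "proximal_intron", "distal_intron")
  bad <- setdiff(region_types, known)
  if (length(bad)) stop_invalid("unknown region type: %s", bad[1])

  tx <- annotation$transcripts
  tpm <- if (is.null(expression)) tx$tpm_a
         else expression$tpm[match(tx$tx_id, expression$tx_id)]
  ord <- order(tx$gene_id, -tpm, tx$tx_id)
  rep_tx <- tx$tx_id[ord][!duplicated(tx$gene_id[ord])]

  ex <- annotation$exons[annotation$exons$tx_id %in% rep_tx, , drop = FALSE]
  fe <- annotation$features[annotation$features$tx_id %in% rep_tx, , drop = FALSE]
  gstrand <- annotation$genes$strand[match(ex$gene_id, annotation$genes$gene_id)]
  fstrand <- fe$strand

  per_strand_ranges <- function(type, st) {
    sel_ex <- ex[gstrand == st, , drop = FALSE]
    sel_fe <- fe[fstrand == st, , drop = FALSE]
    ir <- switch(type,
      pre_mrna = {
        sp <- do.call(rbind, lapply(split(sel_ex, sel_ex$tx_id), function(e)
          data.frame(start = min(e$start), end = max(e$end))))
        to_ir(sp$start, sp$end)
      },
      exon = to_ir(sel_ex$start, sel_ex$end),
      five_utr = feat_ir(sel_fe, "five_utr"),
      cds = feat_ir(sel_fe, "cds"),
      three_utr = feat_ir(sel_fe, "three_utr"),
      intron = feat_ir(sel_fe, "intron"),
      splice_site = intron_windows(sel_fe, 0L, 100L),
      proximal_intron = intron_windows(sel_fe, 100L, 500L),
      distal_intron = intron_windows(sel_fe, 500L, Inf))
    IRanges::reduce(ir)
  }

  strands <- c("+", "-")
  regions <- lapply(region_types, function(ty)
    lapply(stats::setNames(strands, strands), per_strand_ranges, type = ty))
  names(regions) <- region_types
  totals <- vapply(regions, function(r)
    sum(vapply(r, function(x) sum(IRanges::width(x)), numeric(1))), numeric(1))

  K <- length(peak_sets)
  fr <- matrix(0, nrow = K, ncol = length(region_types),
               dimnames = list(NULL, region_types))
  acc <- NULL
  for (k in seq_len(K)) {
    acc <- rbind(acc, peak_sets[[k]][, c("start", "end", "strand")])
    for (ty in region_types) {
      cov <- 0
      for (st in strands) {
        pk <- acc[acc$strand == st, , drop = FALSE]
        if (nrow(pk) == 0) next
        pir <- IRanges::reduce(to_ir(pk$start, pk$end))
        cov <- cov + sum(IRanges::width(IRanges::intersect(pir,
                                                           regions[[ty]][[st]])))
      }
      fr[k, ty] <- if (totals[[ty]] > 0) cov / totals[[ty]] else 0
    }
  }
  fi <- if (K > 1) fr[-1, , drop = FALSE] / fr[-K, , drop = FALSE] else NULL
  list(fractions = fr, fold_increase = fi, totals = totals)
}

feat_ir <- function(fe, region) {
  f <- fe[fe$region == region, , drop = FALSE]
  to_ir(f$start, f$end)
}

# intronic windows between `from` and `to` nt of either splice site
intron_windows <- function(fe, from, to) {
  f <- fe[fe$region == "intron", , drop = FALSE]
  if (nrow(f) == 0) return(IRanges::IRanges())
  s <- f$start; e <- f$end
  res <- list()
  add <- function(st, en) {
    keep <- en > st
    if (any(keep)) res[[length(res) + 1L]] <<- to_ir(st[keep], en[keep])
  }
  if (is.infinite(to)) {
    add(s + from, e - from)
  } else {
    add(s + from, pmin(s + to, e))
    add(pmax(e - to, s), e - from)
  }
  ir <- if (length(res)) do.call(c, res) else IRanges::IRanges()
  if (is.infinite(to) || from == 0L) return(IRanges::reduce(ir))
  IRanges::setdiff(IRanges::reduce(ir), intron_windows(fe, 0L, from))
}
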