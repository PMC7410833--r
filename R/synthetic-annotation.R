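# Synthetic transcriptome, repeat-family database and planted ground truth.
#
# The generator lays genes on a single linear chromosome ("chrS") using
# 0-based half-open coordinates throughout (BED convention). It is the root
# of every other simulation in the package: eCLIP read sets, knockdown
# tables, ChIP peaks and localization tables are all drawn against this
# annotation so that downstream estimators can be checked against planted
# truth.

#' Generate a synthetic transcriptome and repeat-family database
#'
#' Builds a deterministic (seeded) gene annotation on one synthetic
#' chromosome. The first few gene slots follow a fixed plan so that every
#' region label used by [annotate_peak()] is instantiated whenever
#' `n_genes >= 5`: a protein-coding host gene with a long first intron
#' containing an embedded miRNA gene (tRNA-, miRNA-, splice-site-, proximal-
#' and distal-intron conflicts), a tRNA gene, a noncoding gene, and a
#' standalone miRNA; remaining slots are protein-coding genes, every third
#' of which carries a second, exon-skipping isoform. The repeat database
#' holds `n_repeat_families` multi-copy families, each with a priority-1
#' primary transcript and lower-priority pseudogenes, plus one combined
#' simple-repeat family; antisense counterparts are derived at assignment
#' time (see [assign_family()]).
#'
#' @param n_genes number of genes to lay down (>= 1).
#' @param n_repeat_families number of multi-copy element families (>= 1),
#'   not counting the simple-repeat family.
#' @param seed integer seed; the annotation is a pure function of the
#'   arguments and the seed.
#' @return an object of class `transcriptome`: a list with elements
#'   `chrom`, `chrom_len`, `genome` (a `DNAStringSet` of length 1), and data
#'   frames `genes`, `transcripts`, `exons`, `features` (per-transcript
#'   region tracks: five_utr, cds, three_utr, intron, noncoding_exon, trna,
#'   mirna) and `repeat_db` (`transcript_id`, `family_id`, `priority`,
#'   `length`, `sense`). All coordinates 0-based half-open.
#' @examples
#' txome <- make_transcriptome(n_genes = 12, n_repeat_families = 3, seed = 1)
#' table(txome$genes$gene_type)
#' @export
make_transcriptome <- function(n_genes = 50, n_repeat_families = 5, seed = 1) {
  if (!is.numeric(n_genes) || n_genes < 1)
    stop_invalid("n_genes must be >= 1 (got %s)", format(n_genes))
  if (!is.numeric(n_repeat_families) || n_repeat_families < 1)
    stop_invalid("n_repeat_families must be >= 1")
  n_genes <- as.integer(n_genes)

  with_seed(seed, {
    genes <- list(); txs <- list(); exons <- list(); feats <- list()
    cursor <- 2000L
    gid <- 0L

    new_gene_id <- function() {
      gid <<- gid + 1L
      sprintf("G%03d", gid)
    }

    add_coding_gene <- function(strand, first_intron_long = FALSE,
                                second_isoform = FALSE) {
      g <- new_gene_id()
      n_ex <- sample(4:6, 1)
      ex_len <- sample(120:280, n_ex, replace = TRUE)
      in_len <- sample(c(260:420, 650:900), n_ex - 1, replace = TRUE)
      if (first_intron_long) in_len[1] <- sample(1600:2600, 1)
      else in_len[sample(n_ex - 1, 1)] <- sample(1500:2400, 1)
      starts <- cursor + cumsum(c(0L, head(ex_len, -1) + in_len))
      ends <- starts + ex_len
      gstart <- starts[1]; gend <- ends[n_ex]
      utr5 <- sample(60:110, 1); utr3 <- sample(150:220, 1)
      tx1 <- paste0(g, ".t1")
      res <- tx_rows(tx1, g, starts, ends, strand, utr5, utr3, coding = TRUE)
      exons[[length(exons) + 1L]] <<- res$exons
      feats[[length(feats) + 1L]] <<- res$features
      tx_tbl <- data.frame(tx_id = tx1, gene_id = g, stringsAsFactors = FALSE)
      if (second_isoform && n_ex >= 4) {
        skip <- sample(2:(n_ex - 1), 1)
        tx2 <- paste0(g, ".t2")
        res2 <- tx_rows(tx2, g, starts[-skip], ends[-skip], strand,
                        utr5, utr3, coding = TRUE)
        exons[[length(exons) + 1L]] <<- res2$exons
        feats[[length(feats) + 1L]] <<- res2$features
        tx_tbl <- rbind(tx_tbl,
                        data.frame(tx_id = tx2, gene_id = g,
                                   stringsAsFactors = FALSE))
      }
      txs[[length(txs) + 1L]] <<- tx_tbl
      genes[[length(genes) + 1L]] <<- gene_row(g, "protein_coding", strand,
                                               gstart, gend)
      cursor <<- gend + sample(1000:3000, 1)
      list(gene_id = g, intron1 = c(ends[1], starts[2]), strand = strand)
    }

    add_single_exon_gene <- function(type, len, strand, start = NULL) {
      g <- new_gene_id()
      s <- if (is.null(start)) cursor else start
      e <- s + len
      tx <- paste0(g, ".t1")
      exons[[length(exons) + 1L]] <<-
        data.frame(tx_id = tx, gene_id = g, exon_rank = 1L,
                   start = s, end = e, stringsAsFactors = FALSE)
      lab <- switch(type, tRNA = "trna", miRNA = "mirna", "noncoding_exon")
      feats[[length(feats) + 1L]] <<-
        data.frame(tx_id = tx, gene_id = g, region = lab,
                   start = s, end = e, strand = strand,
                   stringsAsFactors = FALSE)
      txs[[length(txs) + 1L]] <<-
        data.frame(tx_id = tx, gene_id = g, stringsAsFactors = FALSE)
      genes[[length(genes) + 1L]] <<- gene_row(g, type, strand, s, e)
      if (is.null(start)) cursor <<- e + sample(1000:2500, 1)
      g
    }

    add_noncoding_gene <- function(strand) {
      g <- new_gene_id()
      ex_len <- sample(150:400, 2)
      in_len <- sample(300:700, 1)
      s1 <- cursor; e1 <- s1 + ex_len[1]
      s2 <- e1 + in_len; e2 <- s2 + ex_len[2]
      tx <- paste0(g, ".t1")
      exons[[length(exons) + 1L]] <<-
        data.frame(tx_id = tx, gene_id = g, exon_rank = 1:2,
                   start = c(s1, s2), end = c(e1, e2),
                   stringsAsFactors = FALSE)
      feats[[length(feats) + 1L]] <<-
        data.frame(tx_id = tx, gene_id = g,
                   region = c("noncoding_exon", "intron", "noncoding_exon"),
                   start = c(s1, e1, s2), end = c(e1, s2, e2),
                   strand = strand, stringsAsFactors = FALSE)
      txs[[length(txs) + 1L]] <<-
        data.frame(tx_id = tx, gene_id = g, stringsAsFactors = FALSE)
      genes[[length(genes) + 1L]] <<- gene_row(g, "noncoding", strand, s1, e2)
      cursor <<- e2 + sample(1000:2500, 1)
      g
    }

    # fixed plan for the first slots, then plain coding genes
    host <- add_coding_gene(strand = "+", first_intron_long = TRUE,
                            second_isoform = TRUE)
    if (gid < n_genes) {
      # miRNA embedded in the host gene's long first intron
      mid <- floor(mean(host$intron1))
      add_single_exon_gene("miRNA", 80L, host$strand, start = mid)
    }
    if (gid < n_genes) add_single_exon_gene("tRNA", 75L, sample(c("+", "-"), 1))
    if (gid < n_genes) add_noncoding_gene(sample(c("+", "-"), 1))
    if (gid < n_genes) add_single_exon_gene("miRNA", 80L, sample(c("+", "-"), 1))
    k <- 0L
    while (gid < n_genes) {
      k <- k + 1L
      add_coding_gene(strand = sample(c("+", "-"), 1),
                      second_isoform = (k %% 3L == 0L))
    }

    genes <- do.call(rbind, genes)
    transcripts <- do.call(rbind, txs)
    exons <- do.call(rbind, exons)
    features <- do.call(rbind, feats)
    rownames(genes) <- rownames(transcripts) <- rownames(exons) <-
      rownames(features) <- NULL

    # baseline expression per transcript and cell type (TPM-like); some genes
    # are planted strongly differential or cell-type-specific so that the
    # cross-cell preservation categories are all populated.
    ntx <- nrow(transcripts)
    tpm_a <- stats::rlnorm(ntx, meanlog = 3, sdlog = 1)
    tpm_b <- tpm_a * 2^stats::rnorm(ntx, 0, 0.15)
    gnum <- as.integer(factor(transcripts$gene_id, levels = genes$gene_id))
    strong <- gnum %% 7L == 5L
    specific <- gnum %% 11L == 7L
    tpm_b[strong] <- tpm_a[strong] * 8
    tpm_b[specific] <- 0.01
    tpm_a[specific] <- pmax(tpm_a[specific], 1.5)
    transcripts$tpm_a <- round(tpm_a, 4)
    transcripts$tpm_b <- round(tpm_b, 4)

    chrom_len <- max(genes$end) + 2000L
    genome <- Biostrings::DNAStringSet(paste(
      sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
      collapse = ""))
    names(genome) <- "chrS"

    obj <- list(chrom = "chrS", chrom_len = chrom_len, genome = genome,
                genes = genes, transcripts = transcripts, exons = exons,
                features = features,
                repeat_db = make_repeat_db(n_repeat_families))
    class(obj) <- "transcriptome"
    obj
  })
}

gene_row <- function(g, type, strand, start, end) {
  data.frame(gene_id = g, gene_type = type, strand = strand,
             start = start, end = end,
             tss = if (strand == "+") start else end,
             tts = if (strand == "+") end else start,
             stringsAsFactors = FALSE)
}

# Exon/feature rows for a coding transcript. Exon coordinates are genomic
# (sorted); transcript order is reversed on the minus strand. The 5'UTR
# occupies the first utr5 nt of the transcript, the 3'UTR the last utr3 nt,
# and the CDS everything between; introns are the genomic gaps.
tx_rows <- function(tx_id, gene_id, starts, ends, strand, utr5, utr3, coding) {
  n <- length(starts)
  ex <- data.frame(tx_id = tx_id, gene_id = gene_id, exon_rank = seq_len(n),
                   start = starts, end = ends, stringsAsFactors = FALSE)
  ord <- if (strand == "+") seq_len(n) else rev(seq_len(n))
  lens <- (ends - starts)[ord]
  total <- sum(lens)
  stopifnot(utr5 + utr3 < total)
  # transcript-coordinate breakpoints of region boundaries
  segs <- data.frame(region = c("five_utr", "cds", "three_utr"),
                     from = c(0L, utr5, total - utr3),
                     to = c(utr5, total - utr3, total))
  rows <- list()
  off <- 0L
  for (i in seq_len(n)) {
    es <- starts[ord[i]]; ee <- ends[ord[i]]
    for (j in seq_len(nrow(segs))) {
      lo <- max(segs$from[j], off); hi <- min(segs$to[j], off + lens[i])
      if (hi > lo) {
        # map transcript coords [lo, hi) back onto this exon
        if (strand == "+") {
          rows[[length(rows) + 1L]] <- data.frame(
            tx_id = tx_id, gene_id = gene_id, region = segs$region[j],
            start = es + (lo - off), end = es + (hi - off), strand = strand,
            stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            tx_id = tx_id, gene_id = gene_id, region = segs$region[j],
            start = ee - (hi - off), end = ee - (lo - off), strand = strand,
            stringsAsFactors = FALSE)
        }
      }
    }
    off <- off + lens[i]
  }
  if (n > 1) {
    rows[[length(rows) + 1L]] <- data.frame(
      tx_id = tx_id, gene_id = gene_id, region = "intron",
      start = ends[-n], end = starts[-1], strand = strand,
      stringsAsFactors = FALSE)
  }
  list(exons = ex, features = do.call(rbind, rows))
}

# Multi-copy element families: a primary transcript plus pseudogenes with
# decreasing priority per family, and one combined simple-repeat family.
make_repeat_db <- function(n_families) {
  base_names <- c("RNA18S", "Alu", "L1", "snRNA_U1", "YRNA")
  fams <- if (n_families <= length(base_names)) base_names[seq_len(n_families)]
          else c(base_names, sprintf("repfam%02d", seq_len(n_families - 5)))
  rows <- list()
  for (i in seq_along(fams)) {
    n_pseudo <- 1L + (i %% 3L)
    len_primary <- sample(c(300:800, 1800:7000), 1)
    ids <- c(paste0(fams[i], "_primary"),
             sprintf("%s_pseudo%d", fams[i], seq_len(n_pseudo)))
    lens <- c(len_primary,
              pmax(150L, as.integer(len_primary * stats::runif(n_pseudo, 0.4, 0.9))))
    rows[[i]] <- data.frame(transcript_id = ids, family_id = fams[i],
                            priority = seq_along(ids), length = lens,
                            sense = "+", stringsAsFactors = FALSE)
  }
  simple <- data.frame(transcript_id = sprintf("simple_rep%d", 1:3),
                       family_id = "simple_repeat", priority = 1:3,
                       length = 60L, sense = "both", stringsAsFactors = FALSE)
  db <- rbind(do.call(rbind, rows), simple)
  rownames(db) <- NULL
  db
}

#' @export
print.transcriptome <- function(x, ...) {
  cat(sprintf("transcriptome: %d genes / %d transcripts on %s (%d nt), %d repeat families\n",
              nrow(x$genes), nrow(x$transcripts), x$chrom, x$chrom_len,
              length(unique(x$repeat_db$family_id))))
  invisible(x)
}

#' Construct planted ground truth for the simulators
#'
#' Bundles the quantities the generators plant and the downstream estimators
#' are expected to recover: regionally enriched elements (fold `lambda`),
#' per-repeat-family selection weights, an RBNS motif with selection factor
#' `s`, and exon-level splicing regulation (`dpsi`). Enriched elements are
#' placed in the proximal intron downstream of selected skipped exons so the
#' planted splicing-map signal and the planted eCLIP enrichment coincide.
#'
#' @param annotation a `transcriptome`.
#' @param n_elements number of planted enriched elements.
#' @param lambda fold enrichment of planted elements (>= 1).
#' @param family_weights named numeric vector of per-family IP selection
#'   weights (>= 0); families absent from the vector get weight 1.
#' @param motif planted RBNS consensus (RNA alphabet).
#' @param s RBNS per-occurrence selection factor (>= 1).
#' @param n_regulated number of skipped exons with planted regulation.
#' @param dpsi planted inclusion-level change, recycled over regulated exons
#'   (each in \[-1, 1\]).
#' @param n_utr_elements additionally plant elements spanning the 3'UTR of
#'   this many regulated genes (ties planted differential expression to
#'   planted region-level binding).
#' @param seed integer seed.
#' @return an object of class `binding_truth`.
#' @export
binding_truth <- function(annotation, n_elements = 3, lambda = 8,
                          family_weights = NULL, motif = "UGCAUG", s = 10,
                          n_regulated = 10, dpsi = 0.3,
                          n_utr_elements = 0, seed = 1) {
  stopifnot(inherits(annotation, "transcriptome"))
  if (any(lambda < 1)) stop_invalid("lambda must be >= 1")
  if (s < 1) stop_invalid("s must be >= 1")
  if (any(abs(dpsi) > 1)) stop_invalid("dpsi must lie in [-1, 1]")
  with_seed(seed, {
    cand <- se_candidates(annotation)
    n_reg <- min(n_regulated, nrow(cand))
    reg <- cand[sample(nrow(cand), n_reg), , drop = FALSE]
    reg$dpsi <- rep_len(dpsi, n_reg)
    # planted elements: proximal intron downstream (3') of regulated exons
    n_el <- min(n_elements, n_reg)
    el <- reg[seq_len(n_el), , drop = FALSE]
    el_start <- ifelse(el$strand == "+", el$exon_end + 40L,
                       el$exon_start - 240L)
    elements <- data.frame(start = el_start, end = el_start + 200L,
                           strand = el$strand,
                           lambda = rep_len(lambda, n_el),
                           stringsAsFactors = FALSE)
    n_utr <- min(n_utr_elements, n_reg)
    if (n_utr > 0) {
      utr_genes <- unique(reg$gene_id)[seq_len(min(n_utr,
                                                   length(unique(reg$gene_id))))]
      fu <- annotation$features
      fu <- fu[fu$region == "three_utr" & fu$gene_id %in% utr_genes &
                 grepl("\\.t1$", fu$tx_id), , drop = FALSE]
      if (nrow(fu) > 0)
        elements <- rbind(elements,
                          data.frame(start = fu$start, end = fu$end,
                                     strand = fu$strand,
                                     lambda = rep_len(lambda, nrow(fu)),
                                     stringsAsFactors = FALSE))
    }
    if (is.null(family_weights)) {
      fams <- unique(annotation$repeat_db$family_id)
      family_weights <- stats::setNames(rep(1, length(fams)), fams)
      family_weights[fams[1]] <- 6
    }
    obj <- list(elements = elements, family_weights = family_weights,
                motif = motif, s = s, regulation = reg)
    class(obj) <- "binding_truth"
    obj
  })
}

#' Neutral (null) ground truth: no enrichment anywhere
#'
#' Convenience constructor for null-calibration runs: lambda = 1 elements,
#' uniform family weights, s = 1 motif selection and no planted regulation.
#'
#' @inheritParams binding_truth
#' @return a `binding_truth` with all effects at their neutral values.
#' @export
null_truth <- function(annotation) {
  stopifnot(inherits(annotation, "transcriptome"))
  fams <- unique(annotation$repeat_db$family_id)
  obj <- list(elements = data.frame(start = integer(0), end = integer(0),
                                    strand = character(0), lambda = numeric(0)),
              family_weights = stats::setNames(rep(1, length(fams)), fams),
              motif = "UGCAUG", s = 1,
              regulation = data.frame())
  class(obj) <- "binding_truth"
  obj
}

# Internal skipped-exon candidates: internal exons of coding transcripts,
# with their flanking exons, on the primary isoform.
se_candidates <- function(annotation) {
  ex <- annotation$exons
  ex <- ex[grepl("\\.t1$", ex$tx_id), , drop = FALSE]
  out <- list()
  for (tx in unique(ex$tx_id)) {
    e <- ex[ex$tx_id == tx, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    n <- nrow(e)
    if (n < 3) next
    g <- e$gene_id[1]
    st <- annotation$genes$strand[match(g, annotation$genes$gene_id)]
    if (annotation$genes$gene_type[match(g, annotation$genes$gene_id)] !=
        "protein_coding") next
    i <- 2:(n - 1)
    out[[tx]] <- data.frame(
      gene_id = g, tx_id = tx, strand = st,
      exon_start = e$start[i], exon_end = e$end[i],
      upstream_start = e$start[i - 1], upstream_end = e$end[i - 1],
      downstream_start = e$start[i + 1], downstream_end = e$end[i + 1],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
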