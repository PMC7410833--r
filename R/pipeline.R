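# Run configuration and the end-to-end pipeline driver.

#' Build a run configuration
#'
#' All thresholds default to the study values: reproducible peaks at fold
#' >= 8 and p <= 0.001 with reproducibility cutoff 0.01; region-level
#' significance at fold >= 4 and p <= 1e-5 with the 10-read eligibility
#' rule; RBNS logo Z threshold 3 and eCLIP logo threshold 2.8; event
#' significance p < 0.05, FDR < 0.1, |dpsi| > 0.05 with the native-psi
#' band 0.05-0.95; 1,000 native-event samplings and 100 resampling rounds.
#' Generator sizes control the synthetic inputs of [run_pipeline()].
#' Configurations round-trip losslessly through YAML.
#'
#' @param ... named overrides of any default.
#' @return list of class `atlas_config`.
#' @export
atlas_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # thresholds (study defaults)
    peak_fold = 8, peak_p = 1e-3, idr_threshold = 0.01,
    region_fold = 4, region_p = 1e-5, region_min_reads = 10,
    rbns_z = 3, eclip_z = 2.8,
    event_p = 0.05, event_fdr = 0.1, dpsi_cut = 0.05,
    native_band = c(0.05, 0.95),
    n_samplings = 1000L, n_rounds = 100L,
    min_events_se = 100L, min_events_ss = 50L,
    windows = list(exon = 50L, intron = 300L),
    # synthetic-data generator sizes (see the methods vignette for the
    # rationale behind each value)
    n_genes = 80L, n_repeat_families = 4L,
    depth = 200000L, dup_rate = 0.05,
    lambda = 16, n_elements = 110L, n_regulated = 110L, dpsi = 0.3,
    n_utr_elements = 20L,
    rbns_motif = "UGCAUG", rbns_s = 10, rbns_reads = 30000L,
    rbns_read_len = 20L,
    n_events = 600L, promoter_bias = 5, chip_peaks = 300L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop_invalid("unknown config field '%s'", unknown[1])
  cfg[names(over)] <- over
  class(cfg) <- "atlas_config"
  cfg
}

#' Read/write configurations as YAML
#'
#' @param path YAML file path.
#' @return an `atlas_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(atlas_config, vals)
}

#' @rdname read_config
#' @param config an `atlas_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Generates a seeded synthetic data set (annotation, eCLIP libraries,
#' RBNS pools, knockdown tables, ChIP peaks) and runs every analysis
#' stage: repeat-family quantification with relative information,
#' region-level enrichment, reproducible peak calling with priority
#' annotation, RBNS enrichment and motif logos with RBNS+/- peak
#' classification, the splicing map with its resampled band, saturation,
#' and the binding-function overlap statistics. All outputs are TSV/BED
#' files plus a JSON manifest (inputs, configuration, seed, file digests)
#' that makes reruns byte-identical: the same configuration and seed give
#' the same manifest and files.
#'
#' @param config an `atlas_config`.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = atlas_config(), out_dir) {
  stopifnot(inherits(config, "atlas_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  ## inputs --------------------------------------------------------------
  ann <- make_transcriptome(config$n_genes, config$n_repeat_families,
                            seed = seed)
  truth <- binding_truth(ann, n_elements = config$n_elements,
                         lambda = config$lambda,
                         motif = config$rbns_motif, s = config$rbns_s,
                         n_regulated = config$n_regulated,
                         dpsi = config$dpsi,
                         n_utr_elements = config$n_utr_elements,
                         seed = derive_seed(seed, 1L))
  sim <- simulate_eclip(ann, truth, depth = config$depth,
                        dup_rate = config$dup_rate,
                        seed = derive_seed(seed, 2L))
  note("simulated eCLIP: %d/%d/%d records (ip1/ip2/input)",
       nrow(sim$ip1), nrow(sim$ip2), nrow(sim$input))

  ## repeat-family quantification ----------------------------------------
  dd <- lapply(sim, dedup_pcr)
  note("dedup: %d/%d/%d records retained", nrow(dd$ip1), nrow(dd$ip2),
       nrow(dd$input))
  fam_ip1 <- count_families(dd$ip1, ann$repeat_db)
  fam_ip2 <- count_families(dd$ip2, ann$repeat_db)
  fam_in <- count_families(dd$input, ann$repeat_db)
  fq <- family_quant(fam_ip1, fam_in, nrow(dd$ip1), nrow(dd$input),
                     ip_counts2 = fam_ip2, ip_total2 = nrow(dd$ip2))
  write_tsv(fq, file.path(out_dir, "family_quant.tsv"))

  ## region-level enrichment ---------------------------------------------
  tracks <- region_tracks(ann)
  rg <- tracks[tracks$label %in% c("cds", "three_utr", "five_utr",
                                   "proximal_intron", "distal_intron"), ]
  cnt <- function(recs) {
    g <- recs[recs$target == "genome", , drop = FALSE]
    ov <- overlap_hits(data.frame(chrom = "chrS", start = rg$start,
                                  end = rg$end, strand = rg$strand),
                       data.frame(chrom = "chrS", start = g$start,
                                  end = g$stop, strand = g$strand))
    tabulate(ov$q, nbins = nrow(rg))
  }
  key <- paste(rg$gene_id, rg$label)
  agg <- function(x) as.vector(rowsum(x, key)[unique(key), ])
  reg <- data.frame(region = unique(key),
                    ip = agg(cnt(dd$ip1) + cnt(dd$ip2)),
                    input = agg(cnt(dd$input)))
  qr <- quantify_region(reg$ip, reg$input,
                        nrow(dd$ip1) + nrow(dd$ip2), nrow(dd$input),
                        min_reads = config$region_min_reads,
                        fold_cut = config$region_fold,
                        p_cut = config$region_p)
  reg <- cbind(reg, qr)
  write_tsv(reg, file.path(out_dir, "region_enrichment.tsv"))
  bound_genes <- unique(sub(" .*", "", reg$region[reg$significant]))
  elig_genes <- unique(sub(" .*", "", reg$region[reg$eligible]))
  note("region enrichment: %d/%d regions significant",
       sum(reg$significant), nrow(reg))

  ## reproducible peaks ---------------------------------------------------
  cand <- candidate_windows(ann, truth, derive_seed(seed, 3L))
  rep_peaks <- lapply(list(dd$ip1, dd$ip2), function(ip)
    score_windows(cand, ip, dd$input))
  peaks <- reproducible_peaks(rep_peaks[[1]], rep_peaks[[2]],
                              idr_threshold = config$idr_threshold,
                              fold_cut = config$peak_fold,
                              p_cut = config$peak_p)
  gene_hits <- overlap_hits(peaks,
                            data.frame(chrom = "chrS", start = ann$genes$start,
                                       end = ann$genes$end,
                                       strand = ann$genes$strand))
  peaks$gene_id <- rep(NA_character_, nrow(peaks))
  peaks$gene_id[gene_hits$q] <- ann$genes$gene_id[gene_hits$s]
  peaks$label <- annotate_peak(peaks, tracks)
  write_peaks_bed(peaks, file.path(out_dir, "peaks.bed"))
  if (nrow(peaks) > 0) {
    fr <- region_fraction_vector(peaks$label)
    write_tsv(data.frame(label = names(fr), fraction = as.numeric(fr)),
              file.path(out_dir, "region_fractions.tsv"))
  }
  note("peaks: %d candidates -> %d reproducible", nrow(cand), nrow(peaks))

  ## RBNS ------------------------------------------------------------------
  rb <- simulate_rbns(config$rbns_motif, config$rbns_s, config$rbns_reads,
                      read_len = config$rbns_read_len,
                      seed = derive_seed(seed, 4L))
  prof <- kmer_r_values(rb$pulldown, rb$input, k = 5)
  top <- prof[order(-prof$R), ][1:25, ]
  write_tsv(top, file.path(out_dir, "rbns_top_kmers.tsv"))
  logos <- build_rbns_logos(rb$pulldown, rb$input, k = 5,
                            z_threshold = config$rbns_z)
  if (length(logos)) {
    pw <- as.data.frame(t(logos[[1]]$pwm))
    pw$position <- seq_len(nrow(pw))
    write_tsv(pw, file.path(out_dir, "rbns_logo1_pwm.tsv"))
  }
  top_kmer <- prof$kmer[which.max(prof$R)]
  if (nrow(peaks) > 0) {
    peaks$rbns_pos <- classify_peaks_by_motif(
      peak_sequences(peaks, ann, upstream = 50L), top_kmer)
    write_tsv(peaks, file.path(out_dir, "peaks_annotated.tsv"))
  }
  note("RBNS: top 5-mer %s (R = %.2f), %d logo(s)", top_kmer, max(prof$R),
       length(logos))

  ## knockdown tables and the splicing map ---------------------------------
  kd <- simulate_kd_tables(ann, truth, n_events = config$n_events,
                           seed = derive_seed(seed, 5L))
  write_tsv(kd$events, file.path(out_dir, "kd_events.tsv"))
  write_tsv(kd$expression, file.path(out_dir, "kd_expression.tsv"))
  ev <- filter_events(kd$events, p_cut = config$event_p,
                      fdr_cut = config$event_fdr,
                      dpsi_cut = config$dpsi_cut,
                      native_band = config$native_band)
  ip_cov <- coverage_vector(dd$ip1, ann$chrom_len) +
    coverage_vector(dd$ip2, ann$chrom_len)
  in_cov <- coverage_vector(dd$input, ann$chrom_len)
  cls <- if (nrow(ev$included) >= nrow(ev$excluded)) "included" else "excluded"
  sig_ev <- ev[[cls]]
  map <- NULL
  if (nrow(sig_ev) >= config$min_events_se && nrow(ev$native) >= 10) {
    em <- event_density_matrix(ip_cov, in_cov, sig_ev,
                               nrow(dd$ip1) + nrow(dd$ip2), nrow(dd$input),
                               windows = config$windows)
    nm <- event_density_matrix(ip_cov, in_cov, ev$native,
                               nrow(dd$ip1) + nrow(dd$ip2), nrow(dd$input),
                               windows = config$windows)
    map <- splicing_map(em, nm, n_samplings = config$n_samplings,
                        seed = derive_seed(seed, 6L),
                        min_events = config$min_events_se)
    write_tsv(data.frame(position = seq_along(map$map), map = map$map,
                         band_lo = map$band_lo, band_hi = map$band_hi),
              file.path(out_dir, sprintf("splicing_map_%s.tsv", cls)))
    note("splicing map (%s): %d events, %.1f%% positions outside band",
         cls, map$n_events,
         100 * mean(map$map < map$band_lo | map$map > map$band_hi,
                    na.rm = TRUE))
  } else {
    note("splicing map skipped: %d %s events < %d", nrow(sig_ev), cls,
         config$min_events_se)
  }

  ## saturation -------------------------------------------------------------
  gene_sets <- list(
    peaks = unique(stats::na.omit(peaks$gene_id)),
    de = unique(kd$expression$gene_id[kd$expression$padj < 0.05]),
    bound = bound_genes)
  sat <- saturation_curve(gene_sets, n_shuffles = 100,
                          seed = derive_seed(seed, 7L))
  write_tsv(data.frame(n_sets = seq_along(gene_sets), mean = sat$mean,
                       min = sat$min, max = sat$max),
            file.path(out_dir, "saturation.tsv"))

  ## binding vs expression / chromatin --------------------------------------
  de_up <- kd$expression$gene_id[kd$expression$padj < 0.05 &
                                   kd$expression$log2fc > 0]
  de_dn <- kd$expression$gene_id[kd$expression$padj < 0.05 &
                                   kd$expression$log2fc < 0]
  fams <- list(up = de_up, down = de_dn)
  executed <- sum(vapply(fams, function(s)
    length(intersect(s, elig_genes)) > 10, logical(1)))
  ovl <- lapply(names(fams), function(dir) {
    r <- expression_overlap(bound_genes, fams[[dir]], elig_genes,
                            n_comparisons = max(1, executed))
    data.frame(direction = dir, p = r$p, p_bonferroni = r$p_bonferroni,
               skipped = r$skipped, stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, ovl), file.path(out_dir, "expression_overlap.tsv"))

  chip1 <- simulate_chip(ann, promoter_bias = config$promoter_bias,
                         seed = derive_seed(seed, 8L),
                         n_peaks = config$chip_peaks)
  chip2 <- simulate_chip(ann, promoter_bias = config$promoter_bias,
                         seed = derive_seed(seed, 9L),
                         n_peaks = config$chip_peaks)
  jac <- jaccard_matrix(list(rbp1 = chip1$peaks, rbp2 = chip2$peaks),
                        promoter_windows(ann), ann$chrom_len)
  gb <- gene_bodies(ann)
  pk_gb <- if (nrow(peaks)) {
    ov <- overlap_hits(peaks, data.frame(chrom = "chrS", start = gb$start,
                                         end = gb$end, strand = peaks$strand[1]))
    peaks[unique(ov$q), , drop = FALSE]
  } else peaks
  ce <- chip_at_eclip(chip1$track, pk_gb, ann$chrom_len)
  tss_bound <- chip_tss_genes(chip1$peaks, ann)
  de_chip <- kd$expression$gene_id[
    (kd$expression$log2fc > log2(1.5) | kd$expression$log2fc < log2(2 / 3)) &
      kd$expression$padj < 0.05]
  dep <- chip_kd_dependence(tss_bound, de_chip,
                            data.frame(gene_id = kd$expression$gene_id,
                                       tpm = kd$expression$tpm_a),
                            n_rounds = config$n_rounds,
                            seed = derive_seed(seed, 10L))
  write_tsv(data.frame(
    statistic = c("jaccard_promoter", "jaccard_non_promoter",
                  "chip_at_eclip_p", "chip_kd_dependent",
                  "chip_kd_rounds_significant"),
    value = c(jac$promoter[1, 2], jac$non_promoter[1, 2],
              if (is.null(ce$p)) NA else ce$p,
              as.numeric(isTRUE(dep$dependent)),
              if (is.na(dep$n_significant)) NA else dep$n_significant)),
    file.path(out_dir, "chip_summary.tsv"))

  ## manifest ----------------------------------------------------------------
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  digests <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(
    package = "rbpatlas",
    version = as.character(utils::packageVersion("rbpatlas")),
    seed = seed,
    config = unclass(config),
    files = as.list(stats::setNames(unname(digests), files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# Candidate peak windows: the planted elements plus deterministic null
# windows tiled over gene bodies.
candidate_windows <- function(ann, truth, seed, n_null = 300L,
                              width = 200L) {
  with_seed(seed, {
    g <- ann$genes
    gi <- sample_weighted(n_null, g$end - g$start)
    off <- floor(stats::runif(n_null) * pmax(1, g$end[gi] - g$start[gi] - width))
    null <- data.frame(chrom = "chrS", start = as.integer(g$start[gi] + off),
                       strand = g$strand[gi], stringsAsFactors = FALSE)
    null$end <- null$start + width
    el <- truth$elements
    planted <- data.frame(chrom = "chrS", start = el$start,
                          strand = el$strand, end = el$end,
                          stringsAsFactors = FALSE)
    out <- rbind(planted, null)[, c("chrom", "start", "end", "strand")]
    out[order(out$start), , drop = FALSE]
  })
}

# per-replicate peak scores from IP and input read counts in each window
score_windows <- function(cand, ip, input) {
  g_ip <- ip[ip$target == "genome", , drop = FALSE]
  g_in <- input[input$target == "genome", , drop = FALSE]
  cnt <- function(recs) {
    ov <- overlap_hits(cand, data.frame(chrom = "chrS", start = recs$start,
                                        end = recs$stop,
                                        strand = recs$strand))
    tabulate(ov$q, nbins = nrow(cand))
  }
  ipc <- cnt(g_ip); inc <- cnt(g_in)
  fold <- ((ipc + 1) / (nrow(g_ip) + 1)) / ((inc + 1) / (nrow(g_in) + 1))
  p <- fisher_exact_2x2(ipc, nrow(g_ip) - ipc, inc, nrow(g_in) - inc)
  data.frame(cand, log2fc = log2(fold),
             neglog10p = -log10(pmax(p, 1e-300)),
             stringsAsFactors = FALSE)
}

#' Gene bodies: gene spans minus 1-kb TSS and TTS windows
#'
#' @param annotation a `transcriptome`.
#' @param flank window half-width (nt).
#' @return data frame `gene_id`, `start`, `end` (genes consumed by their
#'   windows are dropped).
#' @export
gene_bodies <- function(annotation, flank = 1000L) {
  g <- annotation$genes
  lo <- pmin(g$tss, g$tts) + flank
  hi <- pmax(g$tss, g$tts) - flank
  keep <- hi > lo
  data.frame(gene_id = g$gene_id[keep], start = lo[keep], end = hi[keep],
             stringsAsFactors = FALSE)
}

# genes whose 1-kb TSS window overlaps a ChIP peak
chip_tss_genes <- function(chip_peaks, annotation) {
  prom <- promoter_windows(annotation)
  ov <- IRanges::findOverlaps(to_ir(prom$start, prom$end),
                              to_ir(chip_peaks$start, chip_peaks$end),
                              minoverlap = 1L)
  unique(prom$gene_id[S4Vectors::queryHits(ov)])
}
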