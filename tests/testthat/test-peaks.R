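test_that("replicate merging takes geometric means and applies the filters", {
  r1 <- mk_peaks(100, 200, log2fc = 4, neglog10p = 6)
  r2 <- mk_peaks(150, 250, log2fc = 2, neglog10p = 6)
  # geometric mean sqrt(4*2) = 2.83 fails the fold >= 8 (log2 >= 3) filter
  out <- reproducible_peaks(r1, r2)
  expect_identical(nrow(out), 0L)
  out2 <- reproducible_peaks(r1, r2, fold_cut = 4)
  expect_identical(nrow(out2), 1L)
  expect_equal(out2$log2fc, sqrt(8))
  expect_equal(out2$start, 100)  # interval union
  expect_equal(out2$end, 250)
})

test_that("identical replicates pass in full; empty or disjoint inputs do not", {
  r <- mk_peaks(c(100, 500, 900), c(200, 600, 1000), log2fc = 4,
                neglog10p = 5)
  out <- reproducible_peaks(r, r)
  expect_identical(nrow(out), 3L)
  expect_identical(nrow(reproducible_peaks(r[0, ], r)), 0L)
  expect_identical(nrow(reproducible_peaks(r, r[0, ])), 0L)
  r2 <- r; r2$chrom <- "chr_other"
  expect_error(reproducible_peaks(r, r2), "reference")
  # opposite strands never merge
  r3 <- r; r3$strand <- "-"
  expect_identical(nrow(reproducible_peaks(r, r3)), 0L)
})

test_that("blacklist removal uses 1-nt half-open overlap and is anti-monotone", {
  pk <- mk_peaks(100, 200)
  bl1 <- data.frame(chrom = "chrS", start = 199, end = 300)
  bl2 <- data.frame(chrom = "chrS", start = 200, end = 300)
  expect_identical(nrow(remove_blacklist(pk, bl1)), 0L)
  expect_identical(nrow(remove_blacklist(pk, bl2)), 1L)
  expect_identical(remove_blacklist(pk, bl2[0, ]), pk)
  set.seed(7)
  pks <- mk_peaks(seq(0, 9000, by = 100), seq(50, 9050, by = 100))
  bl <- data.frame(chrom = "chrS", start = sample(0:9000, 30), end = 0)
  bl$end <- bl$start + 80
  n_prev <- nrow(pks)
  for (k in c(5, 15, 30)) {
    n_k <- nrow(remove_blacklist(pks, bl[seq_len(k), ]))
    expect_lte(n_k, n_prev)
    n_prev <- n_k
  }
})

test_that("peak annotation resolves label conflicts by the stated priority", {
  trk <- function(gene, label, start = 100, end = 200, strand = "+") {
    data.frame(gene_id = gene, label = label, start = start, end = end,
               strand = strand, stringsAsFactors = FALSE)
  }
  pk <- data.frame(start = 120, end = 180, strand = "+")
  # within one gene: CDS beats 3'UTR (isoform conflict)
  expect_identical(annotate_peak(pk, rbind(trk("G1", "cds"),
                                           trk("G1", "three_utr"))), "cds")
  # across genes: miRNA beats CDS
  expect_identical(annotate_peak(pk, rbind(trk("G1", "cds"),
                                           trk("G2", "mirna"))), "mirna")
  # across genes the splice-site labels drop below noncoding_exon
  expect_identical(annotate_peak(pk, rbind(trk("G1", "five_ss"),
                                           trk("G2", "noncoding_exon"))),
                   "noncoding_exon")
  # but within one gene mirna_proximal outranks CDS
  expect_identical(annotate_peak(pk, rbind(trk("G1", "mirna_proximal"),
                                           trk("G1", "cds"))),
                   "mirna_proximal")
  # strand mismatch -> intergenic
  expect_identical(annotate_peak(pk, trk("G1", "cds", strand = "-")),
                   "intergenic")
})

test_that("a peak 400 nt into a long intron is proximal intron", {
  ann <- tiny_txome()
  f <- ann$features
  mir <- f[f$region == "mirna", , drop = FALSE]
  ins <- f[f$region == "intron" & (f$end - f$start) > 1500, ]
  # avoid introns hosting an embedded miRNA (its proximal flank outranks)
  keep <- !vapply(seq_len(nrow(ins)), function(i)
    any(mir$start < ins$end[i] & mir$end > ins$start[i]), logical(1))
  intron <- ins[keep, ][1, ]
  pk <- data.frame(start = intron$start + 400, end = intron$start + 420,
                   strand = intron$strand)
  expect_identical(annotate_peak(pk, region_tracks(ann)), "proximal_intron")
  pk2 <- data.frame(start = intron$start + 600,
                    end = intron$start + 620, strand = intron$strand)
  expect_identical(annotate_peak(pk2, region_tracks(ann)), "distal_intron")
  pk3 <- data.frame(start = intron$start + 20, end = intron$start + 40,
                    strand = intron$strand)
  expect_identical(annotate_peak(pk3, region_tracks(ann)),
                   if (intron$strand == "+") "five_ss" else "three_ss")
})

test_that("region fraction vectors count labels and sum to one", {
  expect_error(region_fraction_vector(character(0)), "empty")
  fr <- region_fraction_vector(rep("cds", 5))
  expect_equal(unname(fr["cds"]), 1)
  expect_equal(sum(fr), 1)
  fr2 <- region_fraction_vector(c(rep("cds", 3), "three_utr"))
  expect_equal(unname(fr2[c("cds", "three_utr")]), c(0.75, 0.25))
  fr3 <- region_fraction_vector(region_labels())
  expect_equal(unname(fr3[region_labels()]), rep(1 / 11, 11))
})

test_that("saturation curves are monotone with an exact union endpoint", {
  sets <- list(a = letters[1:3], b = letters[4:7], c = letters[8:12])
  sat <- saturation_curve(sets, n_shuffles = 50, seed = 2)
  expect_true(all(sat$curves[, 3] == 12))
  expect_true(all(apply(sat$curves, 1, function(x) all(diff(x) >= 0))))
  expect_identical(saturation_curve(sets, 50, seed = 2)$curves, sat$curves)
  one <- saturation_curve(list(letters[1:4]), n_shuffles = 5, seed = 1)
  expect_true(all(one$curves == 4))
  # nested sets: endpoint equals the largest set
  nest <- list(letters[1:2], letters[1:5], letters[1:10])
  sn <- saturation_curve(nest, 20, seed = 3)
  expect_true(all(sn$curves[, 3] == 10))
})

test_that("covered-base fractions use the representative isoform", {
  ann <- make_transcriptome(1, 1, seed = 3)
  g <- ann$genes[1, ]
  full <- data.frame(start = g$start, end = g$end, strand = g$strand)
  res <- base_coverage_by_region(list(full), ann,
                                 region_types = c("pre_mrna", "exon",
                                                  "intron"))
  expect_equal(unname(res$fractions[1, ]), c(1, 1, 1))
  none <- base_coverage_by_region(list(full[0, ]), ann, "pre_mrna")
  expect_equal(unname(none$fractions[1, 1]), 0)
  # two half-covering disjoint sets union to 1
  mid <- floor((g$start + g$end) / 2)
  h1 <- data.frame(start = g$start, end = mid, strand = g$strand)
  h2 <- data.frame(start = mid, end = g$end, strand = g$strand)
  res2 <- base_coverage_by_region(list(h1, h2), ann, "pre_mrna")
  expect_lt(res2$fractions[1, 1], 1)
  expect_equal(unname(res2$fractions[2, 1]), 1)
  expect_error(base_coverage_by_region(list(full), ann, "nonsense"),
               "unknown region type")
})

test_that("expression categories follow the stated boundaries", {
  expect_identical(as.character(classify_expression_category(10, 10)),
                   "unchanged")
  expect_identical(as.character(classify_expression_category(10, 0.05)),
                   "specific")
  expect_identical(as.character(classify_expression_category(1.2, 1)),
                   "unchanged")   # fold-difference exactly 1.2
  expect_identical(as.character(classify_expression_category(2, 1)), "weak")
  expect_identical(as.character(classify_expression_category(5, 1)),
                   "moderate")
  expect_identical(as.character(classify_expression_category(5.1, 1)),
                   "strong")
  expect_identical(as.character(classify_expression_category(0.5, 0.5)),
                   "other")
  expect_identical(as.character(classify_expression_category(NA, 3)),
                   "other")
})

test_that("cross-cell preservation is exact under identical coverage", {
  set.seed(11)
  cov <- list(ip = rpois(5000, 2), input = rpois(5000, 1),
              ip_total = 10000, input_total = 5000)
  peaks <- data.frame(start = seq(100, 4000, by = 400), end = 0,
                      gene_id = sprintf("G%02d", 1:10))
  peaks$end <- peaks$start + 150
  expr <- data.frame(gene_id = peaks$gene_id, tpm_a = 10,
                     tpm_b = c(rep(10, 5), rep(0.05, 5)))
  res <- cross_cell_preservation(peaks, cov, expr)
  expect_identical(as.character(unique(res$per_peak$category)),
                   c("unchanged", "specific"))
  # identical coverage: fold in B equals fold recomputed in A
  res2 <- cross_cell_preservation(peaks, cov, expr)
  expect_identical(res$per_peak$fold_b, res2$per_peak$fold_b)
})
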