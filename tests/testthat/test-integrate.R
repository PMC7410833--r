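test_that("DE and splicing strength classifications hit their boundaries", {
  expect_identical(as.character(de_classify(c(2, -2, 1.5, 1, 0.3))),
                   c("strong", "strong", "moderate", "weak", "weak"))
  expect_identical(as.character(splicing_classify(c(0.30, 0.20, 0.15,
                                                    0.06, -0.31))),
                   c("strong", "moderate", "moderate", "weak", "strong"))
  expect_true(is.na(splicing_classify(0.05)))
})

test_that("tandem-UTR filter requires both grouped orderings to pass", {
  cmp <- data.frame(kd_reads = c(100, 100, 80, 80),
                    cn_reads = c(90, 70, 90, 70),
                    bayes_factor = 10, p = 0.01)
  expect_true(miso_tandem_filter(cmp))
  # groupings are (kd=100 vs cn=70) and (kd=80 vs cn=90)
  weak_bf <- cmp; weak_bf$bayes_factor[weak_bf$kd_reads == 100 &
                                         weak_bf$cn_reads == 70] <- 4
  expect_false(miso_tandem_filter(weak_bf))
  # a BF = 4 on a non-required comparison does not matter
  side_bf <- cmp; side_bf$bayes_factor[side_bf$kd_reads == 100 &
                                         side_bf$cn_reads == 90] <- 4
  expect_true(miso_tandem_filter(side_bf))
  weak_p <- cmp; weak_p$p[weak_p$kd_reads == 80 & weak_p$cn_reads == 90] <- 0.2
  expect_false(miso_tandem_filter(weak_p))
  expect_error(miso_tandem_filter(cmp[1:3, ]), "four")
})

test_that("expression overlap matches the enumeration oracle and skip rule", {
  bg <- sprintf("g%03d", 1:80)
  bound <- bg[1:40]
  de <- bg[c(1:30, 51:60)]   # a = 30, b = 10, c = 10, d = 30
  r <- expression_overlap(bound, de, bg)
  expect_false(r$skipped)
  expect_identical(as.vector(r$table), c(30L, 10L, 10L, 30L))
  # all observed and expected cells exceed 5, so the Yates branch applies;
  # the Fisher branch itself matches the enumeration oracle exactly
  expect_equal(r$p, yates_chisq_2x2(30, 10, 10, 30)$p)
  expect_lt(abs(fisher_exact_2x2(30, 10, 10, 30) -
                  fisher_oracle(30, 10, 10, 30)), 1e-9)
  # balanced (independence) table: no signal
  de_bal <- bg[c(1:20, 41:60)]
  expect_gt(expression_overlap(bound, de_bal, bg)$p, 0.5)
  # a DE set of exactly 10 genes is skipped and reported
  r10 <- expression_overlap(bound, bg[1:10], bg)
  expect_true(r10$skipped)
  expect_match(r10$reason, "10 genes")
  expect_error(expression_overlap(bound, de, character(0)), "background")
})

test_that("KS comparisons detect shifts and skip degenerate categories", {
  set.seed(7)
  lfc <- c(rnorm(500), rnorm(500) + 0.5, rnorm(1))
  cat_ <- c(rep("not_enriched", 500), rep("enriched", 500), "tiny")
  res <- ks_by_enrichment(lfc, cat_)
  expect_lt(res$p[res$category == "enriched"], 1e-5)
  expect_true(is.na(res$p[res$category == "tiny"]))
  same <- ks_by_enrichment(c(1:5, 1:5),
                           rep(c("not_enriched", "enriched"), each = 5))
  expect_equal(same$p, 1)
})

test_that("Jaccard indexes follow interval arithmetic", {
  a <- data.frame(start = 0, end = 100)
  b <- data.frame(start = 50, end = 150)
  expect_equal(jaccard_index(a, b), 1 / 3)
  expect_equal(jaccard_index(a, a), 1)
  expect_equal(jaccard_index(a, data.frame(start = 500, end = 600)), 0)
  expect_equal(jaccard_index(a, a[0, ]), 0)
  set.seed(8)
  for (i in 1:20) {
    x <- data.frame(start = sample(0:500, 5), end = 0)
    x$end <- x$start + sample(10:50, 5)
    y <- data.frame(start = sample(0:500, 5), end = 0)
    y$end <- y$start + sample(10:50, 5)
    j <- jaccard_index(x, y)
    expect_identical(j, jaccard_index(y, x))
    expect_gte(j, 0); expect_lte(j, 1)
  }
})

test_that("promoter/non-promoter Jaccard matrices are computed per compartment", {
  prom <- data.frame(start = 0, end = 1000)
  sets <- list(a = data.frame(start = c(100, 2000), end = c(200, 2100)),
               b = data.frame(start = c(100, 3000), end = c(200, 3100)))
  jm <- jaccard_matrix(sets, prom, 5000)
  expect_equal(jm$promoter["a", "b"], 1)     # identical promoter intervals
  expect_equal(jm$non_promoter["a", "b"], 0) # disjoint gene-body intervals
  expect_equal(unname(diag(jm$promoter)), c(1, 1))
})

test_that("ChIP-at-eCLIP enrichment test behaves across signal regimes", {
  peaks <- data.frame(start = seq(1000, 20000, by = 1000)[1:15], end = 0)
  peaks$end <- peaks$start + 100
  flat <- data.frame(start = 0, end = 30000, value = 2)
  r0 <- chip_at_eclip(flat, peaks, 30000)
  expect_equal(r0$p, 0.5)
  zero <- data.frame(start = 0, end = 30000, value = 0)
  expect_true(is.na(chip_at_eclip(zero, peaks, 30000)$p))
  # doubled signal inside peaks: strongly significant at n = 200
  set.seed(9)
  pk2 <- data.frame(start = seq(500, 199500, by = 995)[1:200], end = 0)
  pk2$end <- pk2$start + 100
  bins <- data.frame(start = seq(0, 199900, by = 100), end = 0,
                     value = rexp(2000) + 1)
  bins$end <- bins$start + 100
  ov <- IRanges::countOverlaps(
    IRanges::IRanges(bins$start + 1, bins$end),
    IRanges::IRanges(pk2$start + 1, pk2$end))
  bins$value[ov > 0] <- bins$value[ov > 0] * 2
  r2 <- chip_at_eclip(bins, pk2, 200000)
  expect_lt(r2$p, 0.001)
  expect_true(r2$significant)
  # flanks extending past the chromosome end are truncated and flagged
  r3 <- chip_at_eclip(flat, data.frame(start = 10, end = 110), 30000)
  expect_true(r3$truncated[1])
})

test_that("resampled binding-DE dependence finds planted effects, not nulls", {
  set.seed(10)
  n <- 500
  expr <- data.frame(gene_id = sprintf("g%03d", 1:n), tpm = rlnorm(n))
  bound <- expr$gene_id[1:150]
  # planted OR = 3: P(DE | bound) from odds 3x the unbound odds of 0.15
  p0 <- 0.15; odds1 <- 3 * p0 / (1 - p0); p1 <- odds1 / (1 + odds1)
  de <- expr$gene_id[c(which(runif(150) < p1),
                       150 + which(runif(350) < p0))]
  r <- chip_kd_dependence(bound, de, expr, n_rounds = 100, seed = 2)
  expect_true(r$dependent)
  expect_gt(median(r$odds_ratios, na.rm = TRUE), 1.5)
  # independence: no verdict
  de0 <- sample(expr$gene_id, 80)
  r0 <- chip_kd_dependence(bound, de0, expr, n_rounds = 100, seed = 3)
  expect_false(r0$dependent)
  # degenerate: everything bound -> not applicable
  rna <- chip_kd_dependence(expr$gene_id, de0, expr, n_rounds = 10, seed = 1)
  expect_true(is.na(rna$dependent))
})

test_that("localization associations detect planted information shifts", {
  set.seed(11)
  info <- cbind(rRNA = c(rnorm(20, 2), rnorm(20, 0)),
                mRNA = rnorm(40))
  labels <- cbind(nucleolar = rep(c(TRUE, FALSE), each = 20),
                  lonely = c(TRUE, rep(FALSE, 39)))
  p <- localization_association(info, labels)
  expect_lt(p["rRNA", "nucleolar"], 0.01)
  expect_gt(p["mRNA", "nucleolar"], 0.01)
  expect_true(all(is.na(p[, "lonely"])))  # one-sided split empty
})

test_that("spliced/unspliced read classification follows the 10-nt rule", {
  introns <- data.frame(start = 1000, end = 1500)
  reads <- data.frame(
    start = c(988, 991, 980, 995, 1485),
    end = c(1515, 1512, 1020, 1004, 1520),
    gap_start = c(1000, 1000, NA, NA, NA),
    gap_end = c(1500, 1500, NA, NA, NA))
  r <- spliced_unspliced_counts(reads, introns)
  # 12/15-nt anchors: spliced; 9-nt anchor: neither
  expect_identical(r$classification[1], "spliced")
  expect_identical(r$classification[2], "neither")
  # contiguous read across the exon-intron boundary with 20/20: unspliced
  expect_identical(r$classification[3], "unspliced")
  # 5 nt into the intron only: neither; short read at 3' junction: neither
  expect_identical(r$classification[4], "neither")
  expect_identical(r$classification[5], "unspliced")
  expect_identical(r$spliced + r$unspliced + r$neither, nrow(reads))
  # localization classification from the nuclear:cytoplasmic ratio
  expect_identical(classify_localization(c(2, 0.5, 1)),
                   c("nuclear", "cytoplasmic", "neither"))
})
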