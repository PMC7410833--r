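test_that("R values satisfy the weighted-mean and standardization identities", {
  rb <- simulate_rbns("UGCAUG", 4, 4000, 20, seed = 21)
  prof <- kmer_r_values(rb$pulldown, rb$input, 5)
  expect_lt(abs(sum(prof$input_freq * prof$R) - 1), 1e-12)
  expect_lt(abs(mean(prof$Z)), 1e-9)
  expect_lt(abs(stats::sd(prof$Z) - 1), 1e-9)
  # identical libraries give R = 1 everywhere
  same <- kmer_r_values(rb$input, rb$input, 5)
  expect_true(all(same$R == 1))
})

test_that("planted motif dominates the R ranking at modest depth", {
  rb <- simulate_rbns("UGCAUG", 10, 2e4, 20, seed = 31)
  prof <- kmer_r_values(rb$pulldown, rb$input, 5)
  expect_true(prof$kmer[which.max(prof$R)] %in% c("UGCAU", "GCAUG"))
})

test_that("the expected-R oracle reduces to exact base cases", {
  expect_equal(rbns_expected_r("UGCAUG", 1, "GCAUG", 20), 1)
  # a k-mer unrelated to the motif is (slightly) depleted, never enriched
  expect_lt(rbns_expected_r("UGCAUG", 10, "AAAAA", 20), 1)
  # both constituent 5-mers of the 6-mer motif share one expected R
  expect_equal(rbns_expected_r("UGCAUG", 10, "UGCAU", 20),
               rbns_expected_r("UGCAUG", 10, "GCAUG", 20))
  # enrichment grows with the selection factor
  expect_gt(rbns_expected_r("UGCAUG", 20, "GCAUG", 20),
            rbns_expected_r("UGCAUG", 5, "GCAUG", 20))
})

test_that("concentration selection picks the library with the top R value", {
  weak <- simulate_rbns("UGCAUG", 2, 5000, 20, seed = 41)
  strong <- simulate_rbns("UGCAUG", 12, 5000, 20, seed = 42)
  sel <- select_concentration(list(c5nM = weak$pulldown,
                                   c320nM = strong$pulldown),
                              strong$input, k = 5)
  expect_identical(sel$selected, "c320nM")
  expect_gt(sel$top_r["c320nM"], sel$top_r["c5nM"])
})

test_that("masking strictly reduces unmasked k-mer mass and kills shadows", {
  reads <- c("AAUGCAUGAA", "GGUGCAUGGG", "CCCCCCCCCC")
  before <- sum(kmer_count_vector(reads, 5))
  masked <- mask_kmer(reads, "UGCAU")
  after <- sum(kmer_count_vector(masked, 5))
  expect_lt(after, before)
  # the shadow GCAUG overlapping the masked occurrence is gone too
  expect_equal(unname(kmer_count_vector(masked, 5)["GCAUG"]), 0)
})

test_that("logo building recovers a single planted motif and rejects null", {
  rb <- simulate_rbns("UGCAUG", 10, 3e4, 20, seed = 51)
  logos <- build_rbns_logos(rb$pulldown, rb$input, k = 5, z_threshold = 3)
  expect_identical(length(logos), 1L)
  expect_true(grepl(logo_consensus(logos[[1]]), "UGCAUG", fixed = TRUE))
  expect_true(all(abs(colSums(logos[[1]]$pwm) - 1) < 1e-12))
  expect_true(all(logos[[1]]$kmers$weight > 0))
  null <- simulate_rbns("UGCAUG", 1, 2e4, 20, seed = 52)
  expect_identical(length(build_rbns_logos(null$pulldown, null$input)), 0L)
})

test_that("two dissimilar planted motifs yield two separate logos", {
  set.seed(61)
  n <- 24000
  input <- rbpatlas:::random_sequences(n, 20)
  plant <- function(reads, motif, frac) {
    idx <- seq_len(floor(frac * length(reads)))
    pos <- sample.int(20 - nchar(motif) + 1, length(idx), TRUE)
    substr(reads[idx], pos, pos + nchar(motif) - 1) <- motif
    reads
  }
  pd <- rbpatlas:::random_sequences(n, 20)
  pd[seq(1, n, 2)] <- plant(pd[seq(1, n, 2)], "AAAAA", 0.5)
  pd[seq(2, n, 2)] <- plant(pd[seq(2, n, 2)], "CCCCC", 0.5)
  pd <- sample(pd)
  logos <- build_rbns_logos(pd, input, k = 5, z_threshold = 3)
  expect_gte(length(logos), 2L)
  cons <- vapply(logos, logo_consensus, "")
  expect_true(any(grepl("AAA", cons)) && any(grepl("CCC", cons)))
})

test_that("every 5-mer in a final logo is corroborated by both halves", {
  rb <- simulate_rbns("UGCAUG", 8, 2e4, 20, seed = 71)
  n <- length(rb$pulldown)
  h <- seq_len(n %/% 2)
  acc1 <- iterative_top_kmers(rb$pulldown[h], rb$input[h], 5, 3)
  acc2 <- iterative_top_kmers(rb$pulldown[-h], rb$input[-h], 5, 3)
  logos <- build_rbns_logos(rb$pulldown, rb$input, 5, 3)
  expect_gte(length(logos), 1L)
  for (lg in logos) for (km in lg$kmers$kmer) {
    expect_true(rbpatlas:::kmer_matches_any(km, acc1$kmer, 1))
    expect_true(rbpatlas:::kmer_matches_any(km, acc2$kmer, 1))
  }
  # logo recovery does not depend on which motif variant each half picks
  for (s in c(2, 3, 4)) {
    rb2 <- simulate_rbns("UGCAUG", 10, 3e4, 20, seed = s)
    lg2 <- build_rbns_logos(rb2$pulldown, rb2$input, 5, 3)
    expect_identical(length(lg2), 1L)
    expect_true(grepl(logo_consensus(lg2[[1]]), "UGCAUG", fixed = TRUE))
  }
})

test_that("eCLIP k-mer Z-scores flag planted enrichment and degenerate input", {
  set.seed(81)
  bg <- rbpatlas:::random_sequences(4000, 60)
  fg <- bg
  pos <- sample.int(56, 2000, TRUE)
  substr(fg[1:2000], pos, pos + 4) <- "GCAUG"
  z <- eclip_kmer_zscores(fg, bg, 5)
  expect_identical(z$kmer[which.max(z$Z)], "GCAUG")
  z0 <- eclip_kmer_zscores(fg, fg, 5)
  expect_true(all(abs(z0$Z) < 1e-9))
  expect_error(eclip_kmer_zscores(fg[1], bg, 5), "at least 2")
})

test_that("motif overlap test matches the closed-form hypergeometric", {
  a <- all_kmers(5)[1:10]
  r <- motif_overlap_test(a, a)
  expect_equal(r$p, exp(-lchoose(1024, 10)))
  expect_true(r$significant)
  disj <- motif_overlap_test(a, all_kmers(5)[11:20])
  expect_gt(disj$p, 0.5)
  expect_equal(motif_overlap_test(all_kmers(5), a)$p, 1)
  expect_equal(motif_overlap_test(character(0), a)$p, 1)
})

test_that("peak sequences honour strand and the 50-nt upstream extension", {
  genome <- Biostrings::DNAStringSet(paste(rep("A", 200), collapse = ""))
  s <- as.character(genome[[1]])
  substr(s, 91, 95) <- "GCATG"   # just upstream of a + peak at [100, 120)
  ann <- list(genome = Biostrings::DNAStringSet(s))
  pk <- data.frame(start = 100, end = 120, strand = "+")
  expect_true(classify_peaks_by_motif(peak_sequences(pk, ann, 50), "GCAUG"))
  expect_false(classify_peaks_by_motif(peak_sequences(pk, ann, 0), "GCAUG"))
  # minus-strand peak: upstream is to the right, sequence reverse-complemented
  s2 <- paste(rep("A", 200), collapse = "")
  substr(s2, 130, 134) <- "CATGC"  # revcomp GCAUG, right of [100, 120)
  ann2 <- list(genome = Biostrings::DNAStringSet(s2))
  pk2 <- data.frame(start = 100, end = 120, strand = "-")
  expect_true(classify_peaks_by_motif(peak_sequences(pk2, ann2, 50), "GCAUG"))
})

test_that("matched controls reproduce the joint decile histogram", {
  set.seed(91)
  cases <- data.frame(expr = rlnorm(100), psi = runif(100, 0.05, 0.95))
  cands <- data.frame(expr = rlnorm(3000), psi = runif(3000, 0.05, 0.95))
  m <- matched_controls(cases, cands, seed = 5)
  expect_identical(nrow(m) + length(attr(m, "dropped")), 100L)
  # single candidate per cell is matched deterministically
  one_case <- data.frame(expr = 1, psi = 0.5)
  one_cand <- data.frame(expr = 1, psi = 0.5)
  m1 <- matched_controls(one_case, one_cand, seed = 1)
  m2 <- matched_controls(one_case, one_cand, seed = 99)
  expect_identical(nrow(m1), 1L)
  expect_identical(m1$expr, m2$expr)
  expect_warning(matched_controls(one_case, one_cand[0, ], seed = 1),
                 "no candidate")
})

test_that("splicing-effect comparison matches the permutation oracle", {
  # identical groups: one-sided p near 1/2 by exchangeability
  x <- c(0.1, 0.2, 0.3, 0.15, 0.25)
  r <- splicing_effect_compare(x, x)
  expect_gt(r$p, 0.3); expect_lt(r$p, 0.8)
  # {4,5,6} vs {1,2,3}: exhaustive enumeration over choose(6,3) splits
  r2 <- splicing_effect_compare(c(4, 5, 6), c(1, 2, 3))
  perms <- combn(6, 3)
  vals <- c(1, 2, 3, 4, 5, 6)
  stat <- function(g) sum(rank(vals)[g])
  obs <- stat(4:6)
  p_oracle <- mean(apply(perms, 2, stat) >= obs)
  expect_equal(r2$p, p_oracle)
  # undefined for tiny groups
  expect_true(is.na(splicing_effect_compare(1, c(1, 2))$p))
  # power at a planted shift
  set.seed(101)
  pk <- rnorm(200, 0.25, 0.1); npk <- rnorm(200, 0.15, 0.1)
  expect_lt(splicing_effect_compare(pk, npk)$p, 0.05)
  # significant comparisons split by motif presence and re-test
  res <- splicing_effect_compare(pk, npk,
                                 peak_has_motif = rep(c(TRUE, FALSE), 100))
  expect_true(!is.null(res$motif_p))
})
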