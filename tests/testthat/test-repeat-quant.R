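test_that("family assignment follows priority and discards multi-family ties", {
  db <- demo_repeat_db()
  m <- data.frame(target = c("RNA18SP7", "RNA18S"), mismatches = c(0L, 0L),
                  strand = "+", stringsAsFactors = FALSE)
  r <- assign_family(m, db)
  expect_identical(r$status, "assigned")
  expect_identical(r$transcript, "RNA18S")  # priority 1 beats pseudogene
  # equal best score across two families -> discarded
  m2 <- data.frame(target = c("AluY", "L1HS"), mismatches = c(1L, 1L),
                   strand = "+", stringsAsFactors = FALSE)
  expect_identical(assign_family(m2, db)$status, "discarded")
  # a worse-scoring second family does not trigger the discard
  m3 <- data.frame(target = c("AluY", "L1HS"), mismatches = c(0L, 2L),
                   strand = "+", stringsAsFactors = FALSE)
  expect_identical(assign_family(m3, db)$family, "Alu")
  # single mapping -> its family; empty -> unmapped, not an error
  m4 <- data.frame(target = "L1HS", mismatches = 3L, strand = "+")
  expect_identical(assign_family(m4, db)$family, "L1")
  expect_identical(assign_family(m4[0, ], db)$status, "unmapped")
})

test_that("antisense mappings go to the antisense family; simple repeats do not", {
  db <- demo_repeat_db()
  m <- data.frame(target = "AluY", mismatches = 0L, strand = "-")
  expect_identical(assign_family(m, db)$family, "antisense_Alu")
  # sense and antisense are distinct families: tie across them -> discarded
  m2 <- data.frame(target = c("AluY", "AluSx"), mismatches = 0L,
                   strand = c("+", "-"), stringsAsFactors = FALSE)
  expect_identical(assign_family(m2, db)$status, "discarded")
  ms <- data.frame(target = "simple1", mismatches = 0L, strand = "-")
  expect_identical(assign_family(ms, db)$family, "simple_repeat")
})

test_that("family assignment is order-invariant", {
  db <- demo_repeat_db()
  set.seed(42)
  for (i in 1:25) {
    n <- sample(2:5, 1)
    m <- data.frame(target = sample(db$transcript_id, n, TRUE),
                    mismatches = sample(0:2, n, TRUE),
                    strand = sample(c("+", "-"), n, TRUE),
                    stringsAsFactors = FALSE)
    r1 <- assign_family(m, db)
    r2 <- assign_family(m[sample.int(n), , drop = FALSE], db)
    expect_identical(r1, r2)
  }
})

test_that("genomic-vs-repeat reconciliation uses a strict 24-score margin", {
  rec <- function(score, id = "r1") data.frame(read_id = id,
                                               alignment_score = score)
  expect_identical(reconcile_unique_vs_repeat(rec(100), rec(75)), "genomic")
  expect_identical(reconcile_unique_vs_repeat(rec(99), rec(75)), "repeat")
  expect_identical(reconcile_unique_vs_repeat(rec(65), rec(75)), "repeat")
  expect_error(reconcile_unique_vs_repeat(rec(100, "a"), rec(75, "b")),
               "different read pairs")
})

test_that("PCR deduplication keeps one record per key, stably", {
  r <- data.frame(read_id = c("b", "a"), umi = "ACGTACGTAC", target = "genome",
                  start = 100L, stop = 150L, strand = "+",
                  stringsAsFactors = FALSE)
  out <- dedup_pcr(r)
  expect_identical(nrow(out), 1L)
  expect_identical(out$read_id, "a")  # lexicographically smallest survives
  distinct <- data.frame(read_id = c("a", "b"), umi = c("AAAA", "CCCC"),
                         start = 1L, stop = 2L, stringsAsFactors = FALSE)
  expect_identical(nrow(dedup_pcr(distinct)), 2L)
  bad <- r; bad$umi <- NA
  expect_error(dedup_pcr(bad), "UMI")
})

test_that("dedup is idempotent and permutation-stable", {
  r <- random_records(1000, seed = 5)
  d1 <- dedup_pcr(r)
  expect_identical(dedup_pcr(d1), d1)
  perm <- r[sample.int(nrow(r)), ]
  d2 <- dedup_pcr(perm)
  expect_setequal(d1$read_id, d2$read_id)
})

test_that("relative information matches direct evaluation and sign rule", {
  expect_identical(relative_information(0.5, 0.5), 0)
  expect_equal(relative_information(0.5, 0.25), 0.5)
  expect_equal(relative_information(0.25, 0.5), -0.25)
  expect_error(relative_information(0.5, 0), "pseudocount")
  expect_error(relative_information(1.5, 0.2), "fractions")
  set.seed(1)
  p <- runif(100); q <- runif(100)
  ri <- relative_information(p, q)
  expect_true(all(sign(ri[p > 0]) == sign(p - q)[p > 0]))
})

test_that("family_quant applies the half-reciprocal-depth pseudocount", {
  ip <- c(A = 50L, B = 0L, C = 10L)
  inp <- c(A = 25L, B = 10L, C = 0L)
  fq <- family_quant(ip, inp, ip_total = 1000, input_total = 2000)
  expect_equal(fq$p[fq$element == "B"], 0.5 / 1000)
  expect_equal(fq$q[fq$element == "C"], 0.5 / 2000)
  expect_equal(fq$information_bits[1],
               relative_information(50 / 1000, 25 / 2000))
  expect_lte(sum(fq$p), 1)
  # merged-replicate variant averages the two IP fractions
  fq2 <- family_quant(ip, inp, 1000, 2000, ip_counts2 = c(A = 100L, B = 0L,
                                                          C = 20L),
                      ip_total2 = 4000)
  expect_equal(fq2$p[1], (50 / 1000 + 100 / 4000) / 2)
})

test_that("region quantification applies eligibility, fold and p rules", {
  r <- quantify_region(5, 5, 1e6, 1e6)
  expect_false(r$eligible)
  r2 <- quantify_region(100, 100, 1e6, 1e6)
  expect_true(r2$eligible)
  expect_equal(r2$fold, 1)
  expect_false(r2$significant)
  # depth normalization: doubling every count leaves fold unchanged
  a <- quantify_region(80, 10, 1e5, 1e5)
  b <- quantify_region(160, 20, 2e5, 2e5)
  expect_equal(a$fold, b$fold)
  # zero totals: ineligible, not an exception
  z <- quantify_region(0, 0, 0, 0)
  expect_false(z$eligible)
  # asymmetric eligibility: 10 reads in IP but < 10 expected in input
  r3 <- quantify_region(12, 0, 1e6, 1e5)
  expect_false(r3$eligible)
  r4 <- quantify_region(12, 0, 1e5, 1e6)
  expect_true(r4$eligible)
})

test_that("Fisher p matches the enumeration oracle and fisher.test", {
  expect_lt(abs(fisher_exact_2x2(40, 10, 10, 40) -
                  fisher_oracle(40, 10, 10, 40)), 1e-9)
  set.seed(3)
  for (i in 1:200) {
    t <- as.vector(stats::rmultinom(1, sample(20:200, 1), runif(4) + 0.05))
    p_pkg <- fisher_exact_2x2(t[1], t[2], t[3], t[4])
    p_ref <- stats::fisher.test(matrix(t, 2))$p.value
    expect_lt(abs(p_pkg - p_ref), 1e-7)
  }
})

test_that("Yates statistic matches chisq.test and the closed form", {
  set.seed(4)
  for (i in 1:50) {
    t <- sample(6:80, 4, TRUE)
    y <- yates_chisq_2x2(t[1], t[2], t[3], t[4])
    ref <- suppressWarnings(stats::chisq.test(matrix(t, 2, byrow = TRUE),
                                              correct = TRUE))
    expect_equal(y$statistic, unname(ref$statistic))
    expect_equal(y$p, ref$p.value)
    expect_equal(y$statistic, yates_oracle(t[1], t[2], t[3], t[4]))
  }
})
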