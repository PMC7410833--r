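test_that("event filtering applies the stated thresholds and direction", {
  ev <- data.frame(event_id = sprintf("e%d", 1:4),
                   p = c(0.01, 0.01, 0.5, 0.01),
                   fdr = c(0.05, 0.05, 0.9, 0.05),
                   dpsi = c(0.2, 0.03, 0.0, -0.2),
                   psi_control = c(0.5, 0.5, 0.5, 0.99))
  f <- filter_events(ev)
  expect_identical(f$included$event_id, "e1")
  expect_identical(f$excluded$event_id, "e4")  # psi band applies to natives
  expect_identical(f$native$event_id, c("e2", "e3"))
  expect_error(filter_events(ev[, setdiff(names(ev), "fdr")]), "fdr")
})

test_that("meta-region positions mask short features and mirror on minus", {
  ev <- data.frame(strand = "+", exon_start = 1000, exon_end = 1100,
                   upstream_start = 820, upstream_end = 850,
                   downstream_start = 1250, downstream_end = 1500)
  pos <- meta_positions(ev)
  expect_identical(length(pos), 1400L)
  # upstream exon is 30 nt: the first 20 exonic positions are masked
  expect_true(all(is.na(pos[1:20])))
  expect_false(anyNA(pos[21:50]))
  # upstream intron is 150 nt: block-A intron positions past it are masked
  expect_true(all(is.na(pos[51 + 150:299])))
  ev$strand <- "-"
  expect_identical(meta_positions(ev), rev(pos))
})

test_that("event densities are strand-correct and null under IP == input", {
  L <- 3000
  ip <- rep(2, L); input <- rep(2, L)
  ev <- data.frame(strand = "+", exon_start = 1000, exon_end = 1100,
                   upstream_start = 500, upstream_end = 650,
                   downstream_start = 1500, downstream_end = 1700)
  d0 <- event_density(ip, input, ev)
  expect_true(all(d0[!is.na(d0)] == 0))
  # bump in the downstream proximal intron appears exactly there on + ...
  ip2 <- ip; ip2[1101:1300] <- 10
  d <- event_density(ip2, input, ev)
  bumped <- which(!is.na(d) & d > 0)
  # downstream proximal intron shows up in the SE 5'ss block and again in
  # the downstream-exon block (same bases, two anchors)
  expect_setequal(bumped, c(751:950, 1051:1150))
  # ... and, after mirroring the genome, at the same meta positions on -
  mir <- function(v) rev(v)
  ev_m <- data.frame(strand = "-",
                     exon_start = L - ev$exon_end, exon_end = L - ev$exon_start,
                     upstream_start = L - ev$upstream_end,
                     upstream_end = L - ev$upstream_start,
                     downstream_start = L - ev$downstream_end,
                     downstream_end = L - ev$downstream_start)
  # swap flank roles: genomic left of the mirrored event is the downstream exon
  ev_m2 <- data.frame(strand = "-",
                      exon_start = ev_m$exon_start, exon_end = ev_m$exon_end,
                      upstream_start = ev_m$downstream_start,
                      upstream_end = ev_m$downstream_end,
                      downstream_start = ev_m$upstream_start,
                      downstream_end = ev_m$upstream_end)
  d_m <- event_density(mir(ip2), mir(input), ev_m2)
  expect_equal(d_m, d)
})

test_that("splicing maps refuse tiny event sets and are seed-deterministic", {
  set.seed(5)
  nat <- matrix(rnorm(200 * 140), 200)
  evm <- matrix(rnorm(30 * 140), 30)
  expect_error(splicing_map(evm[1:5, ], nat, min_events = 30), "5 < 30")
  m1 <- splicing_map(evm, nat, n_samplings = 50, seed = 9, min_events = 30)
  m2 <- splicing_map(evm, nat, n_samplings = 50, seed = 9, min_events = 30)
  expect_identical(m1$band_lo, m2$band_lo)
  expect_identical(m1$map, m2$map)
  single <- splicing_map(evm, nat, n_samplings = 1, seed = 3, min_events = 30)
  expect_identical(single$band_lo, single$band_hi)
})

test_that("planted enrichment escapes the band exactly where planted", {
  set.seed(6)
  nat <- matrix(rnorm(500 * 140), 500)
  evm <- matrix(rnorm(120 * 140), 120)
  planted <- 101:120
  evm[, planted] <- evm[, planted] + 2
  m <- splicing_map(evm, nat, n_samplings = 500, seed = 4, min_events = 100)
  expect_true(all(m$map[planted] > m$band_hi[planted]))
  expect_lt(mean((m$map > m$band_hi | m$map < m$band_lo)[-planted]), 0.1)
})

test_that("map correlation concatenates classes and handles absences", {
  mk <- function(v) structure(list(map = v), class = "splicing_map")
  a <- list(included = mk(c(1, 2, 3, 4)), excluded = mk(c(0, 1, 0, 1)))
  expect_equal(map_correlation(a, a), 1)
  b <- list(included = mk(-c(1, 2, 3, 4)), excluded = mk(-c(0, 1, 0, 1)))
  expect_equal(map_correlation(a, b), -1)
  # one class missing on one side: the other class is used alone
  a2 <- list(included = mk(c(1, 2, 3, 4)), excluded = NULL)
  b2 <- list(included = mk(c(2, 4, 6, 8)), excluded = mk(c(9, 9, 9, 9)))
  expect_equal(map_correlation(a2, b2), 1)
  expect_true(is.na(map_correlation(list(included = NULL, excluded = NULL),
                                    b2)))
  # random maps of realistic length are near-uncorrelated
  set.seed(12)
  r <- replicate(40, map_correlation(list(included = mk(rnorm(1400))),
                                     list(included = mk(rnorm(1400)))))
  expect_gt(mean(abs(r) < 0.1), 0.9)
})

test_that("class envelopes and cross-RBP maps average member maps", {
  mk <- function(v) structure(list(map = v), class = "splicing_map")
  env <- class_map_envelope(list(mk(c(1, 1)), mk(c(3, 3)), mk(c(2, 2))))
  expect_equal(env$mean, c(2, 2))
  expect_identical(env$n_members, 3L)
  expect_true(all(env$lo <= env$mean & env$mean <= env$hi))
})

test_that("per-exon RBP profiles are additive and hit covered windows", {
  exons <- data.frame(start = c(1000, 3000), end = c(1100, 3120),
                      strand = "+")
  # one RBP whose peaks blanket both upstream 3'ss windows completely
  pk <- data.frame(start = c(700, 2700), end = c(1000, 3000), strand = "+")
  prof1 <- rbp_per_exon_profile(list(rbp1 = pk), exons)
  expect_equal(prof1[1:300], rep(1, 300))     # intronic 3'ss window
  expect_equal(prof1[301:350], rep(0, 50))    # exonic part uncovered
  prof2 <- rbp_per_exon_profile(list(rbp1 = pk, rbp2 = pk), exons)
  expect_equal(prof2, 2 * prof1)
  expect_equal(rbp_per_exon_profile(list(rbp1 = pk, rbp2 = pk), exons,
                                    exclude = "rbp2"), prof1)
  expect_error(rbp_per_exon_profile(list(rbp1 = pk), exons[0, ]), "empty")
})
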