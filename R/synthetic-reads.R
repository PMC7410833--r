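# Simulators for eCLIP read-pair records and RBNS sequence pools.

#' Simulate eCLIP read records for two IPs and a paired input
#'
#' Input reads are sampled proportionally to expression times region weight
#' (exonic bases weighted 1, intronic 0.1, plus a small intergenic floor);
#' IP reads are additionally weighted by the planted fold enrichment
#' `lambda` over enriched elements and by the per-family selection weights
#' over repeat transcripts. PCR duplicates are created by copying whole
#' records (identical mapping start/stop and UMI, fresh read id), matching
#' the start/stop/UMI key used for deduplication.
#'
#' @param annotation a `transcriptome`.
#' @param truth a `binding_truth`.
#' @param depth number of (pre-duplication) read pairs per library.
#' @param dup_rate probability that a record receives one PCR copy
#'   (0 <= dup_rate < 1).
#' @param seed integer seed.
#' @param read_len read-pair footprint length (nt).
#' @param repeat_fraction fraction of the library drawn from repeat
#'   transcripts rather than unique genomic positions.
#' @param umi_len UMI length (nt), fixed per run.
#' @return list of class `eclip_sim` with data frames `ip1`, `ip2`, `input`,
#'   each with columns `read_id`, `umi`, `target` ("genome" or a repeat
#'   transcript id), `start`, `stop` (0-based half-open), `strand`,
#'   `alignment_score`, `mismatches`.
#' @export
simulate_eclip <- function(annotation, truth, depth = 1e5, dup_rate = 0.05,
                           seed = 1, read_len = 40L, repeat_fraction = 0.25,
                           umi_len = 10L) {
  stopifnot(inherits(annotation, "transcriptome"),
            inherits(truth, "binding_truth"))
  if (depth < 0) stop_invalid("depth must be >= 0")
  if (dup_rate < 0 || dup_rate >= 1) stop_invalid("dup_rate must be in [0, 1)")
  depth <- as.integer(depth)
  empty <- data.frame(read_id = character(0), umi = character(0),
                      target = character(0), start = integer(0),
                      stop = integer(0), strand = character(0),
                      alignment_score = integer(0), mismatches = integer(0),
                      stringsAsFactors = FALSE)
  if (depth == 0L) {
    out <- list(ip1 = empty, ip2 = empty, input = empty)
    class(out) <- "eclip_sim"
    return(out)
  }

  L <- annotation$chrom_len
  w_in <- rep(0.01, L)
  strands <- rep("+", L)
  tx_tpm <- annotation$transcripts$tpm_a
  names(tx_tpm) <- annotation$transcripts$tx_id
  f <- annotation$features
  for (i in seq_len(nrow(f))) {
    wgt <- tx_tpm[[f$tx_id[i]]] * if (f$region[i] == "intron") 0.1 else 1
    idx <- (f$start[i] + 1L):f$end[i]
    w_in[idx] <- w_in[idx] + wgt
  }
  g <- annotation$genes
  for (i in seq_len(nrow(g))) strands[(g$start[i] + 1L):g$end[i]] <- g$strand[i]

  w_ip <- w_in
  el <- truth$elements
  for (i in seq_len(nrow(el)))
    w_ip[(el$start[i] + 1L):el$end[i]] <-
      w_ip[(el$start[i] + 1L):el$end[i]] * el$lambda[i]

  db <- annotation$repeat_db
  fam_w <- truth$family_weights[db$family_id]
  fam_w[is.na(fam_w)] <- 1
  rep_w_in <- db$length
  rep_w_ip <- db$length * fam_w

  n_rep <- as.integer(round(depth * repeat_fraction))
  n_gen <- depth - n_rep

  make_lib <- function(prefix, w_pos, w_rep, lib_seed) {
    with_seed(lib_seed, {
      # genomic read pairs
      pos_max <- L - read_len
      starts <- sample_weighted(n_gen, w_pos[seq_len(pos_max)]) - 1L
      gen <- data.frame(
        read_id = sprintf("%s_g%07d", prefix, seq_len(n_gen)),
        umi = random_umis(n_gen, umi_len),
        target = "genome",
        start = starts, stop = starts + read_len,
        strand = strands[starts + 1L],
        stringsAsFactors = FALSE)
      # repeat-transcript read pairs
      ti <- sample_weighted(n_rep, w_rep)
      tlen <- db$length[ti]
      rstart <- as.integer(floor(stats::runif(n_rep) * pmax(1L, tlen - read_len)))
      rep_df <- data.frame(
        read_id = sprintf("%s_r%07d", prefix, seq_len(n_rep)),
        umi = random_umis(n_rep, umi_len),
        target = db$transcript_id[ti],
        start = rstart, stop = pmin(rstart + read_len, tlen),
        strand = ifelse(stats::runif(n_rep) < 0.15, "-", "+"),
        stringsAsFactors = FALSE)
      recs <- rbind(gen, rep_df)
      recs$mismatches <- stats::rbinom(nrow(recs), 2, 0.08)
      recs$alignment_score <- 2L * read_len - 6L * recs$mismatches
      # PCR duplicates: full-record copies with a fresh read id
      if (dup_rate > 0) {
        di <- which(stats::runif(nrow(recs)) < dup_rate)
        if (length(di)) {
          dups <- recs[di, , drop = FALSE]
          dups$read_id <- paste0(dups$read_id, "_dup")
          recs <- rbind(recs, dups)
        }
      }
      rownames(recs) <- NULL
      recs
    })
  }

  out <- list(
    ip1 = make_lib("ip1", w_ip, rep_w_ip, derive_seed(seed, 11L)),
    ip2 = make_lib("ip2", w_ip, rep_w_ip, derive_seed(seed, 22L)),
    input = make_lib("in", w_in, rep_w_in, derive_seed(seed, 33L)))
  class(out) <- "eclip_sim"
  out
}

#' Per-base coverage of genomic read records
#'
#' @param records a read-record data frame (genomic records only are used).
#' @param chrom_len chromosome length.
#' @param strand optional strand filter ("+", "-" or `NULL` for both).
#' @return integer vector of per-base read coverage (1-based indexing over
#'   the chromosome; position i covers 0-based base i-1).
#' @export
coverage_vector <- function(records, chrom_len, strand = NULL) {
  r <- records[records$target == "genome", , drop = FALSE]
  if (!is.null(strand)) r <- r[r$strand == strand, , drop = FALSE]
  cov <- integer(chrom_len)
  if (nrow(r) == 0) return(cov)
  ir <- to_ir(r$start, pmin(r$stop, chrom_len))
  as.integer(IRanges::coverage(ir, width = chrom_len))
}

#' Simulate an RNA Bind-N-Seq experiment
#'
#' Input reads are uniform random oligos over ACGU. Pulldown reads are
#' selected from a larger candidate pool with relative odds `s` per motif
#' occurrence (weighted resampling with weights `s^m`, where `m` counts
#' overlapping occurrences of the consensus in the candidate). This
#' acceptance model has a closed-form expected enrichment for any k-mer,
#' computable with [rbns_expected_r()].
#'
#' @param motif planted consensus (RNA alphabet, e.g. "UGCAUG").
#' @param s per-occurrence selection factor (>= 1); `s = 1` is the null pool.
#' @param n_reads reads per library.
#' @param read_len oligo length (the assay uses 20 or 40 nt).
#' @param seed integer seed.
#' @param pool_factor size of the candidate pool relative to `n_reads`.
#' @return list of class `rbns_sim` with character vectors `pulldown` and
#'   `input` plus the generation parameters.
#' @export
simulate_rbns <- function(motif, s, n_reads, read_len = 20L, seed = 1,
                          pool_factor = 5) {
  if (nchar(motif) > read_len)
    stop_invalid("motif (%d nt) longer than read length (%d nt)",
                 nchar(motif), read_len)
  if (s < 1) stop_invalid("selection factor s must be >= 1")
  n_reads <- as.integer(n_reads)
  with_seed(seed, {
    input <- random_sequences(n_reads, read_len)
    if (s == 1) {
      pulldown <- random_sequences(n_reads, read_len)
    } else {
      pool <- random_sequences(as.integer(n_reads * pool_factor), read_len)
      m <- Biostrings::vcountPattern(chartr("U", "T", motif), as_dna(pool))
      pulldown <- pool[sample_weighted(n_reads, s^m)]
    }
    out <- list(pulldown = pulldown, input = input, motif = motif, s = s,
                read_len = read_len)
    class(out) <- "rbns_sim"
    out
  })
}

#' Closed-form expected RBNS R value under the selection model
#'
#' Computes the exact expected enrichment R of a query k-mer in pulldown
#' versus input when pulldown reads of length `read_len` are selected with
#' odds `s^m` (m = overlapping occurrences of `motif`):
#' \deqn{R = E[c_k s^m] / (E[s^m] \, E[c_k])}
#' where \eqn{c_k} is the occurrence count of the query k-mer in a uniform
#' random read. The expectations are evaluated exactly by dynamic
#' programming over a suffix automaton (4^(M-1) states, M = max motif/k-mer
#' length), so the value serves as an analytic oracle for the simulator and
#' the enrichment estimator.
#'
#' @param motif planted consensus (RNA or DNA alphabet).
#' @param s selection factor (>= 1).
#' @param kmer query k-mer.
#' @param read_len read length.
#' @return expected R (a single number; 1 when `s = 1`).
#' @export
rbns_expected_r <- function(motif, s, kmer, read_len) {
  lm <- nchar(motif); lk <- nchar(kmer)
  M <- max(lm, lk)
  if (M > read_len) stop_invalid("pattern longer than read")
  if (M > 8) stop_invalid("patterns longer than 8 nt are not supported")
  enc <- function(x) {
    v <- match(strsplit(chartr("U", "T", toupper(x)), "")[[1]],
               c("A", "C", "G", "T")) - 1L
    if (anyNA(v)) stop_invalid("pattern must be over ACGU/ACGT")
    sum(v * 4^(rev(seq_along(v)) - 1))
  }
  mot_code <- enc(motif); km_code <- enc(kmer)
  Sn <- 4^(M - 1)
  idx <- 0:(Sn - 1)

  # occurrences completing inside the length-(M-1) prefix
  cnt_in_prefix <- function(code, l) {
    cnt <- integer(Sn)
    for (j in seq_len(M - 1)) {
      if (j >= l) cnt <- cnt + (((idx %/% 4^(M - 1 - j)) %% 4^l) == code)
    }
    cnt
  }
  m_p <- cnt_in_prefix(mot_code, lm)
  c_p <- cnt_in_prefix(km_code, lk)

  # stacked transition tables over (state, next char)
  f <- rep(idx * 4L, 4L) + rep(0:3, each = Sn)
  NS <- f %% Sn
  MOT <- (f %% 4^lm) == mot_code
  INCK <- as.numeric((f %% 4^lk) == km_code)
  IDXR <- rep(seq_len(Sn), 4L)

  run <- function(sel) {
    MULT <- ifelse(MOT, sel, 1)
    W <- (1 / 4)^(M - 1) * sel^m_p
    A <- W * c_p
    for (t in seq_len(read_len - (M - 1))) {
      cw <- W[IDXR] * MULT / 4
      ca <- (A[IDXR] + W[IDXR] * INCK) * MULT / 4
      W <- as.vector(rowsum(cw, NS))
      A <- as.vector(rowsum(ca, NS))
    }
    c(w = sum(W), a = sum(A))
  }
  tilted <- run(s)
  base <- run(1)
  unname((tilted["a"] / tilted["w"]) / base["a"])
}
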