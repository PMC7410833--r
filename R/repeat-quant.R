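# Family-aware assignment of multi-mapping read pairs, reconciliation with
# unique genomic mappings, PCR deduplication and relative information.

#' Assign a read pair's mappings to a repeat family
#'
#' Applies the family-aware assignment rules: keep only the mappings with
#' the lowest mismatch score; among equal-scoring mappings within one family
#' the highest-priority (lowest priority number) transcript is the primary
#' match; read pairs whose best score spans two or more families are
#' discarded. Mapping to the reverse strand of a transcript belongs to the
#' family's antisense counterpart (`antisense_<family>`), except for the
#' combined simple-repeat family.
#'
#' @param mappings data frame of candidate mappings for ONE read pair, with
#'   columns `target` (transcript id in `db`), `mismatches` and `strand`.
#' @param db repeat-family database (`transcript_id`, `family_id`,
#'   `priority`, `length`, `sense`).
#' @return list with `status` ("assigned", "discarded" or "unmapped"),
#'   `family` and `transcript` (NA unless assigned).
#' @examples
#' db <- data.frame(transcript_id = c("RNA18S", "RNA18SP7"),
#'                  family_id = "rRNA18S", priority = c(1, 7),
#'                  length = c(1869, 1800), sense = "+")
#' m <- data.frame(target = c("RNA18SP7", "RNA18S"), mismatches = 0,
#'                 strand = "+")
#' assign_family(m, db)$transcript  # highest priority wins
#' @export
assign_family <- function(mappings, db) {
  if (is.null(mappings) || nrow(mappings) == 0)
    return(list(status = "unmapped", family = NA_character_,
                transcript = NA_character_))
  i <- match(mappings$target, db$transcript_id)
  if (anyNA(i)) stop_invalid("mapping target not present in repeat database")
  fam <- db$family_id[i]
  anti <- mappings$strand == "-" & db$sense[i] != "both"
  fam[anti] <- paste0("antisense_", fam[anti])
  best <- mappings$mismatches == min(mappings$mismatches)
  fams <- unique(fam[best])
  if (length(fams) > 1)
    return(list(status = "discarded", family = NA_character_,
                transcript = NA_character_))
  cand <- which(best)
  primary <- cand[which.min(db$priority[i[cand]])]
  list(status = "assigned", family = fams,
       transcript = mappings$target[primary])
}

#' Assign many read pairs at once
#'
#' @param mappings data frame with a `read_id` column plus the columns of
#'   [assign_family()]; rows are grouped by read pair.
#' @param db repeat-family database.
#' @return data frame `read_id`, `status`, `family`, `transcript`, one row
#'   per read pair, in order of first appearance.
#' @export
assign_families <- function(mappings, db) {
  ids <- unique(mappings$read_id)
  res <- lapply(ids, function(id) {
    r <- assign_family(mappings[mappings$read_id == id, , drop = FALSE], db)
    data.frame(read_id = id, status = r$status, family = r$family,
               transcript = r$transcript, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Reconcile a unique genomic mapping with a repeat mapping
#'
#' The unique genomic mapping is kept only when its pair-summed alignment
#' score exceeds the repeat-element score by strictly more than `margin`
#' (default 24, i.e. more than two mismatches per read better); otherwise
#' the repeat mapping wins and the genomic one is discarded. The boundary
#' (margin exactly 24) goes to the repeat mapping.
#'
#' @param genomic,repeat_ read records (one row each) for the same read
#'   pair, each with `read_id` and `alignment_score`.
#' @param margin score margin required to keep the genomic mapping.
#' @return "genomic" or "repeat".
#' @export
reconcile_unique_vs_repeat <- function(genomic, repeat_, margin = 24) {
  if (!identical(as.character(genomic$read_id),
                 as.character(repeat_$read_id)))
    stop_invalid("records refer to different read pairs (%s vs %s)",
                 genomic$read_id, repeat_$read_id)
  if (genomic$alignment_score - repeat_$alignment_score > margin)
    "genomic" else "repeat"
}

#' Remove PCR duplicates by (start, stop, UMI)
#'
#' Exactly one record survives per distinct (target, start, stop, UMI)
#' combination. The survivor is the record with the lexicographically
#' smallest `read_id` (a stable, order-independent choice; counts do not
#' depend on which duplicate survives).
#'
#' @param records read-record data frame with columns `read_id`, `umi`,
#'   `start`, `stop` and optionally `target` (included in the key when
#'   present, so records on different repeat transcripts never collide).
#' @return the deduplicated records (a subset of the input rows).
#' @export
dedup_pcr <- function(records) {
  if (nrow(records) == 0) return(records)
  if (is.null(records$umi) || anyNA(records$umi) || any(records$umi == ""))
    stop_invalid("records carry missing UMIs; cannot deduplicate")
  tgt <- if (!is.null(records$target)) records$target else ""
  key <- paste(tgt, records$start, records$stop, records$umi, sep = "\r")
  ord <- order(key, records$read_id, method = "radix")
  r <- records[ord, , drop = FALSE]
  out <- r[!duplicated(key[ord]), , drop = FALSE]
  out <- out[order(match(out$read_id, records$read_id)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relative information content of elements (bits)
#'
#' Computes p_i * log2(p_i / q_i) element-wise, where p_i and q_i are the
#' fractions of total reads mapping to element i in IP and input. Values
#' may be negative (input-depleted elements). Elements with p_i = 0
#' contribute 0 bits.
#'
#' @param p,q fraction vectors in \[0, 1\] (apply the pseudocount policy of
#'   [family_quant()] first; q_i = 0 with p_i > 0 is an error).
#' @return numeric vector of relative information, in bits.
#' @examples
#' relative_information(0.5, 0.25)   #  0.5 bits
#' relative_information(0.25, 0.5)   # -0.25 bits
#' @export
relative_information <- function(p, q) {
  stopifnot(length(p) == length(q))
  if (any(p < 0 | p > 1 | q < 0 | q > 1, na.rm = TRUE))
    stop_invalid("fractions must lie in [0, 1]")
  if (any(p > 0 & q == 0, na.rm = TRUE))
    stop_invalid("q_i = 0 with p_i > 0: apply the pseudocount policy first")
  out <- numeric(length(p))
  pos <- !is.na(p) & p > 0
  out[pos] <- p[pos] * log2(p[pos] / q[pos])
  out[is.na(p) | is.na(q)] <- NA_real_
  out
}

#' Per-element IP/input fractions and relative information
#'
#' Builds the element-level summary: read fractions p_i (IP) and q_i
#' (input) against the library depth normalizers, and the relative
#' information in bits. Elements with zero reads in exactly one of IP or
#' input receive a pseudo-fraction equal to half the reciprocal of that
#' library's depth (a documented policy; the quantity is undefined at true
#' zeros).
#'
#' @param ip_counts,input_counts named integer vectors of deduplicated
#'   read-pair counts per element (names must match).
#' @param ip_total,input_total total usable read pairs per library
#'   (including unique genomic mappings; discarded multi-family pairs are
#'   not counted).
#' @param ip_counts2 optional second-replicate IP counts; when supplied the
#'   merged variant is computed with p_i = the average fraction of total
#'   reads across the two IPs (`ip_total2` must then be given).
#' @param ip_total2 depth normalizer for the second IP replicate.
#' @return data frame `element`, `ip_count`, `input_count`, `p`, `q`,
#'   `information_bits`.
#' @export
family_quant <- function(ip_counts, input_counts, ip_total, input_total,
                         ip_counts2 = NULL, ip_total2 = NULL) {
  plain <- function(x) if (is.null(x)) x else
    stats::setNames(as.vector(x), names(x))   # tables -> named vectors
  ip_counts <- plain(ip_counts)
  input_counts <- plain(input_counts)
  ip_counts2 <- plain(ip_counts2)
  stopifnot(identical(names(ip_counts), names(input_counts)))
  if (ip_total <= 0 || input_total <= 0)
    stop_invalid("library depth normalizers must be positive")
  p <- ip_counts / ip_total
  if (!is.null(ip_counts2)) {
    if (is.null(ip_total2)) stop_invalid("ip_total2 required with ip_counts2")
    p <- (p + ip_counts2 / ip_total2) / 2
  }
  q <- input_counts / input_total
  # pseudo-fraction for elements seen in exactly one library
  p[p == 0 & q > 0] <- 0.5 / ip_total
  q[q == 0 & p > 0] <- 0.5 / input_total
  data.frame(element = names(ip_counts),
             ip_count = as.integer(ip_counts),
             input_count = as.integer(input_counts),
             p = p, q = q,
             information_bits = relative_information(p, q),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Count deduplicated read pairs per repeat family
#'
#' @param records read-record data frame (already deduplicated) whose
#'   `target` column names repeat transcripts or "genome".
#' @param db repeat-family database.
#' @return named integer vector over all families (sense and antisense),
#'   including a `genome` element for unique genomic pairs.
#' @export
count_families <- function(records, db) {
  fams <- unique(db$family_id)
  anti <- paste0("antisense_", fams[db$sense[match(fams, db$family_id)] != "both"])
  levels <- c(fams, anti, "genome")
  i <- match(records$target, db$transcript_id)
  fam <- ifelse(is.na(i), "genome", db$family_id[i])
  flip <- !is.na(i) & records$strand == "-" & db$sense[i] != "both"
  fam[flip] <- paste0("antisense_", fam[flip])
  table(factor(fam, levels = levels))
}

#' Region-level eCLIP enrichment test
#'
#' For a region's read counts in IP and paired input, computes fold
#' enrichment ((ip/ip_total) / (input/input_total)), a two-sided p-value
#' (Fisher's exact test, replaced by the Yates-corrected chi-square when
#' every observed and expected cell of the 2x2 table exceeds 5), the
#' eligibility flag (at least `min_reads` reads in one library AND at least
#' `min_reads` expected in the other given the depth ratio) and the final
#' significance call (eligible, fold >= `fold_cut`, p <= `p_cut`).
#' Vectorized over regions.
#'
#' @param ip_count,input_count region read counts (vectors).
#' @param ip_total,input_total library totals.
#' @param min_reads eligibility threshold (default 10 reads).
#' @param fold_cut,p_cut significance thresholds (defaults: fold >= 4,
#'   p <= 1e-5).
#' @return data frame `fold`, `p`, `eligible`, `significant`.
#' @export
quantify_region <- function(ip_count, input_count, ip_total, input_total,
                            min_reads = 10, fold_cut = 4, p_cut = 1e-5) {
  n <- max(length(ip_count), length(input_count))
  ip <- rep_len(as.numeric(ip_count), n)
  inp <- rep_len(as.numeric(input_count), n)
  if (any(ip > ip_total) || any(inp > input_total))
    stop_invalid("counts exceed library totals")
  if (ip_total <= 0 || input_total <= 0) {
    return(data.frame(fold = rep(NA_real_, n), p = NA_real_,
                      eligible = FALSE, significant = FALSE))
  }
  fold <- (ip / ip_total) / (inp / input_total)
  eligible <- (ip >= min_reads & ip * input_total / ip_total >= min_reads) |
              (inp >= min_reads & inp * ip_total / input_total >= min_reads)
  p <- fisher_or_yates(ip, ip_total - ip, inp, input_total - inp)
  significant <- eligible & !is.na(p) & fold >= fold_cut & p <= p_cut
  data.frame(fold = fold, p = p, eligible = eligible,
             significant = significant)
}

#' Two-sided Fisher's exact p for 2x2 tables
#'
#' Exact conditional test on the table rbind(c(a, b), c(c, d)): the p-value
#' is the sum of hypergeometric probabilities of all tables with the same
#' margins that are no more probable than the observed one (with the
#' conventional relative tolerance of 1e-7 for ties). Vectorized over
#' tables; cross-checked against stats::fisher.test in the test suite.
#'
#' @param a,b,c_,d_ cell counts (vectors).
#' @return two-sided p-values.
#' @export
fisher_exact_2x2 <- function(a, b, c_, d_) {
  n <- max(length(a), length(b), length(c_), length(d_))
  a <- rep_len(a, n); b <- rep_len(b, n)
  c_ <- rep_len(c_, n); d_ <- rep_len(d_, n)
  vapply(seq_len(n), function(i) {
    m <- a[i] + b[i]; nn <- c_[i] + d_[i]; k <- a[i] + c_[i]
    if (m + nn == 0) return(NA_real_)
    lo <- max(0, k - nn); hi <- min(k, m)
    probs <- stats::dhyper(lo:hi, m, nn, k)
    pobs <- stats::dhyper(a[i], m, nn, k)
    min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Yates-corrected chi-square statistic and p for 2x2 tables
#'
#' Closed form: X^2 = N (|ad - bc| - N/2)^2 / (r1 r2 c1 c2), with the
#' continuity correction clamped at zero, referred to chi-square with 1 df.
#'
#' @inheritParams fisher_exact_2x2
#' @return data frame `statistic`, `p`.
#' @export
yates_chisq_2x2 <- function(a, b, c_, d_) {
  N <- a + b + c_ + d_
  r1 <- a + b; r2 <- c_ + d_; k1 <- a + c_; k2 <- b + d_
  num <- pmax(0, abs(a * d_ - b * c_) - N / 2)^2 * N
  stat <- ifelse(r1 * r2 * k1 * k2 > 0, num / (r1 * r2 * k1 * k2), NA_real_)
  data.frame(statistic = stat,
             p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# Fisher's exact test, or Yates chi-square when all observed and expected
# cells exceed 5 (vectorized chooser used by the region and overlap tests).
fisher_or_yates <- function(a, b, c_, d_) {
  N <- a + b + c_ + d_
  e11 <- (a + b) * (a + c_) / N
  e12 <- (a + b) * (b + d_) / N
  e21 <- (c_ + d_) * (a + c_) / N
  e22 <- (c_ + d_) * (b + d_) / N
  use_yates <- !is.na(N) & N > 0 &
    pmin(a, b, c_, d_) > 5 & pmin(e11, e12, e21, e22) > 5
  p <- rep(NA_real_, length(N))
  if (any(use_yates))
    p[use_yates] <- yates_chisq_2x2(a[use_yates], b[use_yates],
                                    c_[use_yates], d_[use_yates])$p
  if (any(!use_yates)) {
    i <- which(!use_yates & N > 0)
    p[i] <- fisher_exact_2x2(a[i], b[i], c_[i], d_[i])
  }
  p
}
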