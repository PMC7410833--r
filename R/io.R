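# Readers and writers. All genomic coordinates are 0-based half-open (BED
# convention) in files and in memory, so round trips are bit-exact.

#' Read a BED file
#'
#' Strict reader for BED3/BED6 plus optional documented extra numeric
#' columns. Malformed records are rejected with the offending line number.
#'
#' @param path file path.
#' @param extra_names names for columns beyond the sixth (e.g. the peak
#'   score columns of [write_peaks_bed()]).
#' @return data frame `chrom`, `start`, `end` and, when present, `name`,
#'   `score`, `strand`, plus any extra columns.
#' @export
read_bed <- function(path, extra_names = character(0)) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3))
    stop_invalid("line %d: fewer than 3 BED fields", which(nf < 3)[1])
  ncol <- min(nf)
  m <- do.call(rbind, lapply(parts, `[`, seq_len(ncol)))
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop_invalid("line %d: non-integer start/end", bad[1])
  bad <- which(start >= end)
  if (length(bad))
    stop_invalid("line %d: start >= end (%d >= %d)", bad[1], start[bad[1]],
                 end[bad[1]])
  out <- data.frame(chrom = m[, 1], start = start, end = end,
                    stringsAsFactors = FALSE)
  if (ncol >= 4) out$name <- m[, 4]
  if (ncol >= 5) out$score <- suppressWarnings(as.numeric(m[, 5]))
  if (ncol >= 6) out$strand <- m[, 6]
  if (ncol > 6) {
    extra <- m[, 7:ncol, drop = FALSE]
    nms <- if (length(extra_names) >= ncol - 6) extra_names[seq_len(ncol - 6)]
           else sprintf("extra%d", seq_len(ncol - 6))
    for (j in seq_len(ncol - 6))
      out[[nms[j]]] <- suppressWarnings(as.numeric(extra[, j]))
  }
  out
}

#' Write intervals as BED
#'
#' @param x data frame with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand` plus extra numeric columns (written in order).
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  extra <- setdiff(names(x), cols)
  df <- x[, c(cols, extra), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# BED6+4 peak layout: columns 7-10 are log2FC rep1, -log10 p rep1,
# log2FC rep2, -log10 p rep2.
PEAK_EXTRA_COLS <- c("log2fc_rep1", "neglog10p_rep1", "log2fc_rep2",
                     "neglog10p_rep2")

#' Read/write replicate-scored peaks (BED6+4)
#'
#' @param path file path.
#' @return data frame with BED6 columns plus the four per-replicate score
#'   columns.
#' @export
read_peaks_bed <- function(path) read_bed(path, extra_names = PEAK_EXTRA_COLS)

#' @rdname read_peaks_bed
#' @param peaks peak data frame carrying the per-replicate score columns.
#' @export
write_peaks_bed <- function(peaks, path) {
  df <- peaks
  if (is.null(df$name)) df$name <- sprintf("peak%05d", seq_len(nrow(df)))
  if (is.null(df$score)) df$score <- rep(0, nrow(df))
  write_bed(df[, c("chrom", "start", "end", "name", "score", "strand",
                   intersect(PEAK_EXTRA_COLS, names(df)))], path)
}

#' Read sequences from FASTA
#'
#' @param path file path.
#' @return named character vector (RNA alphabet preserved as written).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences to FASTA
#'
#' @param seqs character vector (names become headers; unnamed sequences
#'   get sequential ids).
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- sprintf("read%07d", seq_along(seqs))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read a TSV with a declared schema
#'
#' @param path file path.
#' @param schema named character vector mapping required column names to
#'   modes ("character", "integer", "numeric", "logical"); extra columns
#'   are kept as-is.
#' @return data frame with at least the schema columns, coerced to the
#'   declared modes.
#' @export
read_tsv_schema <- function(path, schema) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(names(schema), names(df))
  if (length(miss)) stop_invalid("missing column '%s' in %s", miss[1], path)
  for (nm in names(schema)) {
    df[[nm]] <- switch(schema[[nm]],
                       character = as.character(df[[nm]]),
                       integer = as.integer(df[[nm]]),
                       numeric = as.numeric(df[[nm]]),
                       logical = as.logical(df[[nm]]),
                       df[[nm]])
  }
  df
}

#' Write a data frame as TSV (deterministic layout)
#'
#' @param df data frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# documented tabular layout for read records
READ_RECORD_SCHEMA <- c(read_id = "character", umi = "character",
                        target = "character", start = "integer",
                        stop = "integer", strand = "character",
                        alignment_score = "integer", mismatches = "integer")

#' Read/write read-record tables
#'
#' Column order: read_id, umi, target, start, stop, strand,
#' alignment_score, mismatches (0-based half-open coordinates).
#'
#' @param path file path.
#' @return read-record data frame.
#' @export
read_read_records <- function(path) read_tsv_schema(path, READ_RECORD_SCHEMA)

#' @rdname read_read_records
#' @param records read-record data frame.
#' @export
write_read_records <- function(records, path) {
  write_tsv(records[, names(READ_RECORD_SCHEMA)], path)
}

#' Minimal SAM ingestion for interoperability
#'
#' Parses an uncompressed SAM text file into the package's read-record
#' layout: the UMI is taken from the final underscore-delimited token of
#' the query name (the common read-name encoding), the footprint from the
#' POS field plus the sum of M/D/N/=/X cigar lengths, and the strand from
#' flag bit 0x10. Header lines are skipped. This is deliberately a small
#' subset of SAM, sufficient for the tabular fixtures used here.
#'
#' @param path SAM file path.
#' @return read-record data frame.
#' @export
read_sam_records <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(read_id = character(0), umi = character(0),
                      target = character(0), start = integer(0),
                      stop = integer(0), strand = character(0),
                      alignment_score = integer(0),
                      mismatches = integer(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 11)
  if (length(bad)) stop_invalid("SAM line %d: fewer than 11 fields", bad[1])
  qname <- vapply(parts, `[`, "", 1L)
  flag <- as.integer(vapply(parts, `[`, "", 2L))
  rname <- vapply(parts, `[`, "", 3L)
  pos <- as.integer(vapply(parts, `[`, "", 4L))
  cigar <- vapply(parts, `[`, "", 6L)
  ref_len <- vapply(cigar, function(cg) {
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
    if (ops[1] == -1) return(0L)
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    sum(as.integer(sub("[A-Z=]$", "", toks))[
      grepl("[MDN=X]$", toks)])
  }, integer(1), USE.NAMES = FALSE)
  umi <- sub(".*_", "", qname)
  data.frame(read_id = qname, umi = umi, target = rname,
             start = pos - 1L, stop = pos - 1L + ref_len,
             strand = ifelse(bitwAnd(flag, 16L) > 0, "-", "+"),
             alignment_score = NA_integer_, mismatches = NA_integer_,
             stringsAsFactors = FALSE)
}
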