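#' Compile and validate a degenerate DNA motif
#'
#' The alphabet is A/C/G/T plus N (matches any one of A/C/G/T); input is
#' uppercased. Other IUPAC ambiguity codes are rejected loudly rather than
#' silently mis-handled.
#'
#' @param pattern motif string, e.g. "TNTC" (the DarT target motif).
#' @return a `motif` with fields `pattern` and `length`.
#' @export
compile_motif <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  p <- toupper(pattern)
  if (nchar(p) < 1) stop("motif must be non-empty", call. = FALSE)
  chars <- strsplit(p, "")[[1]]
  bad <- setdiff(unique(chars), c("A", "C", "G", "T", "N"))
  if (length(bad) > 0)
    stop("unsupported motif character(s): ",
         paste(bad, collapse = ", "),
         " (only A, C, G, T and N are allowed)", call. = FALSE)
  structure(list(pattern = p, length = nchar(p)), class = "motif")
}

as_motif <- function(motif) {
  if (inherits(motif, "motif")) motif else compile_motif(motif)
}

#' Count non-overlapping motif occurrences
#'
#' Greedy left-to-right scan: at each position, if the motif matches,
#' count it and advance by the motif length, otherwise advance by one.
#' For fixed-length motifs this equals the maximum number of mutually
#' non-overlapping occurrences. Sequence N (or any non-ACGT character)
#' matches nothing; case is folded.
#'
#' @param sequence DNA string.
#' @param motif a `motif` or pattern string.
#' @return integer count.
#' @export
count_nonoverlapping <- function(sequence, motif) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  motif <- as_motif(motif)
  cpp_count_nonoverlap(sequence, motif$pattern)
}

#' Motif occurrence density
#'
#' @param count non-overlapping occurrence count.
#' @param sequence_length denominator length in bases (>= 1).
#' @return percent: `100 * count / sequence_length`.
#' @export
motif_density <- function(count, sequence_length) {
  stop_if_not_number(count, "count", lower = 0)
  if (!is.numeric(sequence_length) || length(sequence_length) != 1L ||
      is.na(sequence_length) || sequence_length < 1)
    stop("sequence_length must be at least 1", call. = FALSE)
  100 * count / sequence_length
}

#' Scan a FASTA file for non-overlapping motif occurrences
#'
#' Per-record greedy non-overlapping counts and densities, with an
#' aggregate over the selected records. When `revcomp` is set, the reverse
#' complement of each record is scanned separately and reported as
#' additional rows; reverse-strand counts are never merged into the
#' forward aggregate.
#'
#' @param path FASTA file (plain or gzipped).
#' @param motif a `motif` or pattern string.
#' @param record_filter optional regular expression; only records whose
#'   names match are scanned.
#' @param revcomp also scan the reverse complement of each record.
#' @param use_effective_length use the non-N (effective) length as the
#'   density denominator instead of the full sequence length.
#' @return a `genome_scan_report`: list with `records` (data.frame:
#'   sequence_id, strand, length, effective_length, count,
#'   density_percent), `aggregate` (forward-strand count, length,
#'   density_percent), `motif` and `revcomp`.
#' @export
scan_fasta <- function(path, motif, record_filter = NULL, revcomp = FALSE,
                       use_effective_length = FALSE) {
  motif <- as_motif(motif)
  if (!file.exists(path)) stop("unreadable FASTA: ", path, call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop("no records in FASTA", call. = FALSE)
  ids <- sub("\\s.*$", "", names(seqs))
  if (!is.null(record_filter)) {
    keep <- grepl(record_filter, ids)
    if (!any(keep))
      stop("no records pass the filter: ", record_filter, call. = FALSE)
    seqs <- seqs[keep]
    ids <- ids[keep]
  }
  scan_one <- function(s, id, strand) {
    cs <- as.character(s)
    cnt <- cpp_count_nonoverlap(cs, motif$pattern)
    len <- nchar(cs)
    eff <- cpp_effective_length(cs)
    denom <- if (use_effective_length) eff else len
    data.frame(sequence_id = id, strand = strand, length = len,
               effective_length = eff, count = cnt,
               density_percent = if (denom >= 1) 100 * cnt / denom else NA_real_)
  }
  rows <- lapply(seq_along(seqs), function(i)
    scan_one(seqs[[i]], ids[i], "+"))
  if (revcomp) {
    rc <- Biostrings::reverseComplement(seqs)
    rows <- c(rows, lapply(seq_along(rc), function(i)
      scan_one(rc[[i]], paste0(ids[i], "_revcomp"), "-")))
  }
  records <- do.call(rbind, rows)
  fwd <- records[records$strand == "+", , drop = FALSE]
  agg_len <- sum(if (use_effective_length) fwd$effective_length
                 else fwd$length)
  aggregate <- list(count = sum(fwd$count), length = agg_len,
                    density_percent = 100 * sum(fwd$count) / agg_len)
  structure(list(records = records, aggregate = aggregate,
                 motif = motif, revcomp = revcomp,
                 use_effective_length = use_effective_length),
            class = "genome_scan_report")
}

#' @export
print.genome_scan_report <- function(x, ...) {
  cat(sprintf("<genome_scan_report> motif %s, %d record(s)\n",
              x$motif$pattern, nrow(x$records)))
  cat(sprintf("  aggregate (+ strand): %d occurrences / %s bases = %.4f%%\n",
              x$aggregate$count, format(x$aggregate$length, big.mark = ","),
              x$aggregate$density_percent))
  invisible(x)
}

#' Write a genome scan report (TSV records + JSON aggregate)
#'
#' @param report a `genome_scan_report`.
#' @param tsv_path per-record TSV output path.
#' @param json_path aggregate JSON output path (optional).
#' @return invisibly, the paths written.
#' @export
write_scan_report <- function(report, tsv_path, json_path = NULL) {
  stopifnot(inherits(report, "genome_scan_report"))
  utils::write.table(report$records, tsv_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(c(report$aggregate,
                           list(motif = report$motif$pattern)),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv = tsv_path, json = json_path))
}
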