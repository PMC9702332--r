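#' Quality-control parameters for read preprocessing
#'
#' @param quality_threshold minimum Phred score required (default 30).
#' @param prefix_length number of leading bases checked (default 25).
#' @param min_length minimum read length after adapter removal (default 18 nt).
#' @param adapter 3' adapter sequence (DNA alphabet).
#' @param min_overlap minimum adapter prefix length used for detection.
#' @param require_adapter reject reads with no detectable adapter (default
#'   TRUE; untrimmed reads would carry adapter bases into alignment).
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(quality_threshold = 30L, prefix_length = 25L,
                      min_length = 18L, adapter = "TGGAATTCTCGGGTGCCAAGG",
                      min_overlap = 6L, require_adapter = TRUE) {
  stopifnot(quality_threshold > 0, quality_threshold <= 41,
            prefix_length > 0, min_length > 0, nzchar(adapter),
            min_overlap > 0)
  structure(list(quality_threshold = as.integer(quality_threshold),
                 prefix_length = as.integer(prefix_length),
                 min_length = as.integer(min_length),
                 adapter = toupper(adapter),
                 min_overlap = as.integer(min_overlap),
                 require_adapter = isTRUE(require_adapter)),
            class = "qc_params")
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path FASTQ file, optionally gzip-compressed.
#' @return data.frame with columns `sequence` (DNA alphabet) and `quality`
#'   (Phred+33 string).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readQualityScaledDNAStringSet(path)
  data.frame(sequence = as.character(x),
             quality = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter reads on leading-base quality
#'
#' A read passes iff every base among its first
#' `min(prefix_length, read length)` bases has Phred quality at or above
#' `quality_threshold`.
#'
#' @param reads data.frame with `sequence` and `quality` (Phred+33) columns.
#' @param params a [qc_params()] object.
#' @return The passing subset, with attribute `n_failed`.
#' @export
quality_filter <- function(reads, params = qc_params()) {
  if (!all(c("sequence", "quality") %in% names(reads)))
    stopf("reads must have 'sequence' and 'quality' columns")
  if (any(nchar(reads$sequence) != nchar(reads$quality)))
    stopf("quality string length differs from sequence length")
  pass <- vapply(reads$quality, function(q) {
    v <- utf8ToInt(substr(q, 1L, params$prefix_length)) - 33L
    all(v >= params$quality_threshold)
  }, logical(1), USE.NAMES = FALSE)
  out <- reads[pass, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_failed") <- sum(!pass)
  out
}

#' Remove 3' adapters and apply the minimum-length filter
#'
#' Locates the leftmost exact occurrence of the adapter's first
#' `min_overlap` bases (the full adapter if shorter) in each read and
#' truncates from there. Reads with no detectable adapter are rejected when
#' `require_adapter` is set; trimmed reads shorter than `min_length` are
#' rejected.
#'
#' @param sequences character vector of read sequences (DNA alphabet).
#' @param params a [qc_params()] object.
#' @return character vector of kept trimmed sequences, with attributes
#'   `n_no_adapter` and `n_too_short`.
#' @export
trim_adapter <- function(sequences, params = qc_params()) {
  probe <- substr(params$adapter, 1L, params$min_overlap)
  hit <- regexpr(probe, sequences, fixed = TRUE)
  pos <- as.integer(hit)
  trimmed <- ifelse(pos > 0L, substr(sequences, 1L, pos - 1L), sequences)
  keep_adapter <- pos > 0L | !params$require_adapter
  keep_len <- nchar(trimmed) >= params$min_length
  out <- trimmed[keep_adapter & keep_len]
  attr(out, "n_no_adapter") <- sum(!keep_adapter)
  attr(out, "n_too_short") <- sum(keep_adapter & !keep_len)
  out
}

#' Collapse identical reads
#'
#' @param sequences character vector of trimmed read sequences.
#' @return data.frame of class `collapsed_reads` with columns `sequence`
#'   (RNA alphabet, T normalized to U) and `count`, in lexicographic
#'   sequence order.
#' @export
collapse_reads <- function(sequences) {
  sequences <- rna_norm(sequences)
  if (!length(sequences)) {
    out <- data.frame(sequence = character(), count = integer(),
                      stringsAsFactors = FALSE)
  } else {
    tb <- table(sequences)
    out <- data.frame(sequence = names(tb), count = as.integer(tb),
                      stringsAsFactors = FALSE)
    out <- out[order(out$sequence), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("collapsed_reads", "data.frame")
  out
}

#' Run the full read-preprocessing chain
#'
#' Quality screening, 3' adapter removal, minimum-length filtering and
#' collapsing, in that order.
#'
#' @param reads FASTQ path or a data.frame with `sequence`/`quality`.
#' @param params a [qc_params()] object.
#' @return `collapsed_reads` with a `qc_log` attribute (named integer
#'   vector of category counts).
#' @export
preprocess_reads <- function(reads, params = qc_params()) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  n_raw <- nrow(reads)
  qf <- quality_filter(reads, params)
  tr <- trim_adapter(qf$sequence, params)
  out <- collapse_reads(tr)
  attr(out, "qc_log") <- c(
    n_raw = n_raw,
    n_fail_quality = attr(qf, "n_failed"),
    n_no_adapter = attr(tr, "n_no_adapter"),
    n_too_short = attr(tr, "n_too_short"),
    n_kept = length(tr))
  out
}

#' Write collapsed reads as FASTA
#'
#' Headers follow the `seq<i>_x<count>` convention used for collapsed
#' small-RNA libraries.
#' @param collapsed a `collapsed_reads` data.frame.
#' @param path output FASTA path.
#' @export
write_collapsed_fasta <- function(collapsed, path) {
  s <- Biostrings::BStringSet(to_dna(collapsed$sequence))
  names(s) <- sprintf("seq%d_x%d", seq_len(nrow(collapsed)), collapsed$count)
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}
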