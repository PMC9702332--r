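#' Align collapsed reads to pre-miRNA hairpins
#'
#' Ungapped alignment of each read against every precursor, tolerating up to
#' `max_mismatch` internal mismatches and a short non-templated 3' tail. The
#' tail is determined by the maximal-templated-suffix rule: it is the
#' shortest read suffix such that the remaining body carries at most
#' `max_mismatch` mismatches against the template (the body never extends
#' past the precursor 3' terminus; read bases overhanging it are always
#' tail). A placement is kept when the body is at least `min_body` nt, has
#' at most `max_mismatch` internal mismatches, and the tail is at most
#' `max_tail` nt. All qualifying placements are reported.
#'
#' Variants are emitted for internal mismatches and for mismatching tail
#' bases that still lie at precursor positions; tail bases beyond the
#' precursor 3' terminus have no template coordinate and are dropped from
#' the variant list.
#'
#' @param reads a `collapsed_reads` data.frame ([collapse_reads()]).
#' @param premirnas a `premirna_set` ([load_premirnas()]).
#' @param max_mismatch maximum internal mismatches in the body (default 1).
#' @param max_tail maximum 3' tail length in nt (default 5).
#' @param min_body minimum body length in nt (default 16, so an 18-nt read
#'   may carry a 2-nt tail).
#' @return A list of class `premir_alignments`: `placements` (data.table
#'   with `aln_id`, `read_id`, `pre_id`, `offset`, `body_len`, `tail_len`,
#'   `n_mm`, `weight`, `orphan`, `count`), `variants` (data.table with
#'   `aln_id`, `target_pos`, `ref`, `alt`, `in_tail`, `read_pos`) and the
#'   `reads` table.
#' @export
align_to_precursors <- function(reads, premirnas, max_mismatch = 1L,
                                max_tail = 5L, min_body = 16L) {
  stopifnot(inherits(premirnas, "premirna_set"))
  seqs <- reads$sequence
  lens <- nchar(seqs)
  ints <- lapply(seqs, nt_ints)
  tri <- upper.tri(matrix(0, 64, 64), diag = TRUE)  # cumsum operator, trimmed per L

  plc <- list(); vars <- list(); k <- 0L
  for (pre in premirnas) {
    P <- nchar(pre$sequence)
    pre_int <- nt_ints(pre$sequence)
    padded <- c(pre_int, rep(-1L, max_tail))
    pre_chars <- strsplit(pre$sequence, "", fixed = TRUE)[[1]]
    for (L in sort(unique(lens))) {
      if (L < min_body) next
      n_off <- min(P - min_body + 1L, length(padded) - L + 1L)
      if (n_off < 1L) next
      W <- stats::embed(padded, L)[seq_len(n_off), L:1, drop = FALSE]
      templ <- pmin(L, P - seq_len(n_off) + 1L)
      U <- tri[seq_len(L), seq_len(L)]
      jmat <- matrix(seq_len(L), n_off, L, byrow = TRUE)
      ok_j <- jmat <= templ  # body cannot cross the precursor 3' terminus
      for (ri in which(lens == L)) {
        M <- W != matrix(ints[[ri]], n_off, L, byrow = TRUE)
        C <- M %*% U                       # cumulative mismatches from read 5'
        score <- jmat * ((C <= max_mismatch) & ok_j)
        mc <- max.col(score, ties.method = "last")
        body <- score[cbind(seq_len(n_off), mc)]
        tail_len <- L - body
        keep <- which(body >= min_body & tail_len <= max_tail)
        for (o in keep) {
          k <- k + 1L
          b <- body[o]
          plc[[k]] <- list(aln_id = k, read_id = ri, pre_id = pre$id,
                           offset = o, body_len = b, tail_len = L - b,
                           n_mm = as.integer(C[o, b]))
          mmj <- which(M[o, ] & (o + seq_len(L) - 1L <= P))
          if (length(mmj)) {
            tp <- o + mmj - 1L
            vars[[length(vars) + 1L]] <- data.table::data.table(
              aln_id = k, target_pos = tp, ref = pre_chars[tp],
              alt = substring(seqs[ri], mmj, mmj), in_tail = mmj > b,
              read_pos = mmj)
          }
        }
      }
    }
  }
  placements <- if (k) data.table::rbindlist(plc) else data.table::data.table(
    aln_id = integer(), read_id = integer(), pre_id = character(),
    offset = integer(), body_len = integer(), tail_len = integer(),
    n_mm = integer())
  placements[, `:=`(count = reads$count[read_id], weight = 1, orphan = FALSE)]
  variants <- if (length(vars)) data.table::rbindlist(vars) else
    data.table::data.table(aln_id = integer(), target_pos = integer(),
                           ref = character(), alt = character(),
                           in_tail = logical(), read_pos = integer())
  structure(list(placements = placements, variants = variants, reads = reads),
            class = "premir_alignments")
}

#' Align collapsed reads to the genome (all best loci)
#'
#' Reports every ungapped genomic placement on either strand with at most
#' `max_mismatch` mismatches, keeping only placements achieving the
#' minimum mismatch count observed for that read ("best" semantics).
#'
#' @param reads a `collapsed_reads` data.frame.
#' @param genome a named `DNAStringSet` or named character vector of
#'   chromosome sequences.
#' @param max_mismatch maximum mismatches (default 1).
#' @return A data.table of class `genome_alignments` with columns
#'   `read_id`, `chrom`, `start`, `end`, `strand`, `n_mm`, `count` and a
#'   `weight` column initialized to `NA` (set by [correct_crossmapping()]).
#' @export
align_to_genome <- function(reads, genome, max_mismatch = 1L) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  stopifnot(!is.null(names(genome)))
  hits <- list()
  for (ri in seq_len(nrow(reads))) {
    pat <- Biostrings::DNAString(to_dna(reads$sequence[ri]))
    rcp <- Biostrings::reverseComplement(pat)
    for (ch in names(genome)) {
      subj <- genome[[ch]]
      for (strand in c("+", "-")) {
        p <- if (strand == "+") pat else rcp
        mt <- Biostrings::matchPattern(p, subj, max.mismatch = max_mismatch)
        if (!length(mt)) next
        st <- Biostrings::start(mt)
        nm <- Biostrings::neditStartingAt(p, subj, starting.at = st,
                                          with.indels = FALSE)
        hits[[length(hits) + 1L]] <- data.table::data.table(
          read_id = ri, chrom = ch, start = st, end = st + length(p) - 1L,
          strand = strand, n_mm = as.integer(nm))
      }
    }
  }
  out <- if (length(hits)) data.table::rbindlist(hits) else
    data.table::data.table(read_id = integer(), chrom = character(),
                           start = integer(), end = integer(),
                           strand = character(), n_mm = integer())
  if (nrow(out)) {
    out[, best := min(n_mm), by = read_id]
    out <- out[n_mm == best][, best := NULL]
  }
  out[, `:=`(count = reads$count[read_id], weight = NA_real_)]
  data.table::setorder(out, read_id, chrom, start, strand)
  out[, pid := .I]
  class(out) <- c("genome_alignments", class(out))
  attr(out, "reads") <- reads
  out
}

utils::globalVariables(c("best", "pid", "body_len", "tail_len", "in_tail",
                         "read_pos"))
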