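#' Load pre-miRNA hairpins with their mature annotations
#'
#' Reads hairpin sequences from a FASTA file and precursor/mature genomic
#' intervals from a miRBase-style GFF3 file, returning precursor objects with
#' mature annotations converted to precursor-relative 1-based coordinates.
#'
#' GFF3 records of type `miRNA_primary_transcript` define precursor loci
#' (attribute `ID=`, matched to FASTA identifiers via `Name=` or `ID=`);
#' records of type `miRNA` define mature miRNAs and must carry
#' `Derives_from=` naming their precursor. Sequences are normalized to the
#' RNA alphabet (T becomes U). Precursors without any mature annotation are
#' dropped with a warning; a precursor annotated at several genomic loci
#' keeps the first locus (warning).
#'
#' @param fasta_path path to the precursor FASTA file.
#' @param gff3_path path to the miRBase-style GFF3 annotation.
#' @return An object of class `premirna_set`: a named list of `PreMiRNA`
#'   records, each a list with elements `id`, `sequence` (RNA alphabet),
#'   `chrom`, `start`, `end`, `strand` (1-based inclusive genomic locus) and
#'   `matures`, a data.frame with columns `name`, `start`, `end`
#'   (precursor-relative, 1-based inclusive) and `arm` ("5p" or "3p").
#' @export
load_premirnas <- function(fasta_path, gff3_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqc <- rna_norm(as.character(seqs))
  bad <- grepl("[^ACGUN]", seqc)
  if (any(bad))
    stopf("precursor sequence(s) with invalid characters: %s",
          paste(names(seqs)[bad], collapse = ", "))

  validate_gff3_lines(gff3_path)
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)

  is_pre <- type == "miRNA_primary_transcript"
  is_mat <- type == "miRNA"
  if (!any(is_pre)) stopf("no miRNA_primary_transcript records in %s", gff3_path)

  pre_key <- function(i) {
    nm <- meta$Name[i] %||% NA_character_
    id <- meta$ID[i] %||% NA_character_
    ifelse(!is.na(nm) & nzchar(nm), nm, id)
  }
  pre_idx <- which(is_pre)
  keys <- pre_key(pre_idx)
  if (anyDuplicated(keys)) {
    dup <- unique(keys[duplicated(keys)])
    warnf("precursor(s) annotated at multiple loci; keeping first: %s",
          paste(dup, collapse = ", "))
    pre_idx <- pre_idx[!duplicated(keys)]
    keys <- keys[!duplicated(keys)]
  }

  # mature records grouped by Derives_from (precursor GFF3 ID)
  mat_idx <- which(is_mat)
  mat_parent <- as.character(unlist(lapply(meta$Derives_from[mat_idx], `[`, 1)))
  if (length(mat_idx) && (length(mat_parent) != length(mat_idx) || anyNA(mat_parent)))
    stopf("miRNA record(s) without Derives_from= attribute in %s", gff3_path)

  out <- list()
  for (j in seq_along(pre_idx)) {
    i <- pre_idx[j]
    id <- keys[j]
    if (!id %in% names(seqc)) {
      warnf("precursor %s has no FASTA sequence; dropped", id)
      next
    }
    p_start <- GenomicRanges::start(gr)[i]
    p_end <- GenomicRanges::end(gr)[i]
    p_strand <- as.character(GenomicRanges::strand(gr))[i]
    if (!p_strand %in% c("+", "-"))
      stopf("precursor %s has no strand", id)
    sq <- seqc[[id]]
    if (nchar(sq) != p_end - p_start + 1)
      stopf("precursor %s: sequence length %d != locus span %d",
            id, nchar(sq), p_end - p_start + 1)

    gid <- meta$ID[i]
    mi <- mat_idx[mat_parent == gid]
    if (!length(mi)) {
      warnf("precursor %s has no mature annotations; dropped", id)
      next
    }
    m_g_start <- GenomicRanges::start(gr)[mi]
    m_g_end <- GenomicRanges::end(gr)[mi]
    if (p_strand == "+") {
      m_start <- m_g_start - p_start + 1L
      m_end <- m_g_end - p_start + 1L
    } else {
      m_start <- p_end - m_g_end + 1L
      m_end <- p_end - m_g_start + 1L
    }
    if (any(m_start < 1L) || any(m_end > nchar(sq)) || any(m_start > m_end))
      stopf("precursor %s: mature interval outside precursor", id)
    m_name <- as.character(meta$Name[mi] %||% meta$ID[mi])
    arm <- ifelse(grepl("-5p$", m_name), "5p",
           ifelse(grepl("-3p$", m_name), "3p",
                  ifelse((m_start + m_end) / 2 <= nchar(sq) / 2, "5p", "3p")))
    matures <- data.frame(name = m_name, start = as.integer(m_start),
                          end = as.integer(m_end), arm = arm,
                          stringsAsFactors = FALSE)
    matures <- matures[order(matures$start), , drop = FALSE]
    rownames(matures) <- NULL
    # sites inside mature regions must be callable
    for (k in seq_len(nrow(matures))) {
      reg <- substr(sq, matures$start[k], matures$end[k])
      if (grepl("N", reg, fixed = TRUE))
        stopf("precursor %s: N base inside mature region %s", id, matures$name[k])
    }
    out[[id]] <- structure(
      list(id = id, sequence = sq, chrom = as.character(GenomicRanges::seqnames(gr))[i],
           start = as.integer(p_start), end = as.integer(p_end),
           strand = p_strand, matures = matures),
      class = "PreMiRNA")
  }
  if (!length(out)) stopf("no usable precursors loaded")
  structure(out, class = "premirna_set")
}

# cheap structural validation so malformed lines are reported by number
validate_gff3_lines <- function(path) {
  ln <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", ln) & nzchar(trimws(ln)))
  nf <- lengths(strsplit(ln[body], "\t", fixed = TRUE))
  bad <- body[nf != 9L]
  if (length(bad))
    stopf("malformed GFF3 line %d in %s (expected 9 tab-separated fields)",
          bad[1], path)
  invisible(TRUE)
}

#' Convert a precursor-relative position to a genomic coordinate
#'
#' @param pre a `PreMiRNA` record.
#' @param pos 1-based position(s) within the precursor sequence.
#' @return 1-based genomic coordinate(s) on the precursor's chromosome.
#' @export
premir_to_genomic <- function(pre, pos) {
  n <- nchar(pre$sequence)
  if (any(pos < 1L | pos > n))
    stopf("position out of range 1..%d for %s", n, pre$id)
  if (pre$strand == "+") pre$start + pos - 1L else pre$end - pos + 1L
}

#' Convert a genomic coordinate to a precursor-relative position
#'
#' Inverse of [premir_to_genomic()].
#' @param pre a `PreMiRNA` record.
#' @param gpos 1-based genomic coordinate(s) within the precursor locus.
#' @export
genomic_to_premir <- function(pre, gpos) {
  if (any(gpos < pre$start | gpos > pre$end))
    stopf("genomic position outside locus %s:%d-%d", pre$chrom, pre$start, pre$end)
  if (pre$strand == "+") gpos - pre$start + 1L else pre$end - gpos + 1L
}

#' Load a SNP or known-editing-site catalog from TSV
#'
#' Reads a tab-delimited catalog with header columns `chromosome`,
#' `position`, `ref`, `alt` (and `source` for `kind = "known_editing"`).
#' Rows sharing a (chromosome, position) key are merged with the union of
#' their alt alleles. Alleles are stored in DNA space (genome strand).
#'
#' @param tsv_path path to the catalog file.
#' @param kind `"snp"` or `"known_editing"`.
#' @return A data.frame of class `site_catalog` with one row per
#'   (chromosome, position): columns `chromosome`, `position`, `ref`,
#'   `alts` (list column of character vectors), `id`.
#' @export
load_catalog <- function(tsv_path, kind = c("snp", "known_editing")) {
  kind <- match.arg(kind)
  # everything as character first: a lone "T" allele would otherwise be
  # type-converted to logical TRUE
  df <- utils::read.delim(tsv_path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  need <- c("chromosome", "position", "ref", "alt")
  if (kind == "known_editing") need <- c(need, "source")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("catalog %s missing required column(s): %s", tsv_path,
          paste(miss, collapse = ", "))
  if (!nrow(df)) {
    out <- data.frame(chromosome = character(), position = integer(),
                      ref = character(), id = character(),
                      stringsAsFactors = FALSE)
    out$alts <- list()
    class(out) <- c("site_catalog", "data.frame")
    attr(out, "kind") <- kind
    return(out)
  }
  df$ref <- toupper(df$ref); df$alt <- toupper(df$alt)
  if (any(df$ref == df$alt))
    stopf("catalog %s: row(s) with ref == alt", tsv_path)
  idcol <- if ("id" %in% names(df)) df$id else if (kind == "known_editing") df$source
           else rep(NA_character_, nrow(df))
  key <- paste(df$chromosome, df$position, sep = ":")
  sp <- split(seq_len(nrow(df)), key)
  rows <- lapply(sp, function(ix) {
    refs <- unique(df$ref[ix])
    if (length(refs) > 1)
      stopf("catalog %s: conflicting ref alleles at %s", tsv_path, key[ix[1]])
    list(chromosome = df$chromosome[ix[1]],
         position = as.integer(df$position[ix[1]]),
         ref = refs,
         alts = sort(unique(df$alt[ix])),
         id = paste(unique(stats::na.omit(idcol[ix])), collapse = ","))
  })
  out <- data.frame(
    chromosome = vapply(rows, `[[`, "", "chromosome"),
    position = vapply(rows, `[[`, 0L, "position"),
    ref = vapply(rows, `[[`, "", "ref"),
    id = vapply(rows, `[[`, "", "id"),
    stringsAsFactors = FALSE)
  out$alts <- lapply(rows, `[[`, "alts")
  out <- out[order(out$chromosome, out$position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("site_catalog", "data.frame")
  attr(out, "kind") <- kind
  out
}

#' @export
print.premirna_set <- function(x, ...) {
  cat(sprintf("<premirna_set> %d precursors\n", length(x)))
  for (p in x[seq_len(min(5, length(x)))])
    cat(sprintf("  %s %s:%d-%d(%s) len=%d matures=%d\n", p$id, p$chrom,
                p$start, p$end, p$strand, nchar(p$sequence), nrow(p$matures)))
  if (length(x) > 5) cat(sprintf("  ... and %d more\n", length(x) - 5))
  invisible(x)
}
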