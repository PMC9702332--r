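# Internal helpers shared across modules.

RNA_ALPHABET <- c("A", "C", "G", "U")

#' @importFrom data.table data.table := setorder setorderv rbindlist setDT as.data.table
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", ".I", "aln_id", "alt", "count", "edited_count", "edited_weight",
  "n_mm", "obs", "offset", "orphan", "orphan_count", "position", "pre_id",
  "read_id", "ref", "seq_", "target_pos", "total_count", "total_weight",
  "weight", "chrom", "start_", "end_", "strand", "precursor", "J"
))

# T->U, uppercase; accepts character vector
rna_norm <- function(x) chartr("Tt", "UU", toupper(x))

# U->T for DNA-space operations (genome matching, FASTQ output)
to_dna <- function(x) chartr("U", "T", toupper(x))

# complement in RNA space (N -> N)
rna_complement <- function(x) chartr("ACGUN", "UGCAN", toupper(x))

# complement of DNA-space allele characters (used for minus-strand SNP matching)
dna_complement <- function(x) chartr("ACGTN", "TGCAN", toupper(x))

# integer encoding of a nucleotide string (A=1,C=2,G=3,U/T=4, other=0)
nt_ints <- function(x) {
  v <- utf8ToInt(chartr("acgut", "ACGUU", chartr("T", "U", x)))
  out <- integer(length(v))
  out[v == 65L] <- 1L; out[v == 67L] <- 2L
  out[v == 71L] <- 3L; out[v == 85L] <- 4L
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
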