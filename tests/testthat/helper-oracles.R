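# Independent oracles, deliberately naive: these re-derive expected values
# by enumeration / direct summation and must stay free of package internals.

# offset-by-offset ungapped genome scan, both strands, best-mismatch-count
# semantics; returns data.frame(chrom, start, end, strand, n_mm)
oracle_align_genome <- function(read_rna, genome, max_mismatch = 1L) {
  if (!is.character(genome)) genome <- as.character(genome)
  enc <- function(x) utf8ToInt(chartr("U", "T", toupper(x)))
  revcomp <- function(x) paste(rev(strsplit(chartr("ACGTU", "TGCAA",
    toupper(x)), "")[[1]]), collapse = "")
  hits <- NULL
  for (ch in names(genome)) {
    g <- enc(genome[[ch]])
    for (strand in c("+", "-")) {
      r <- enc(if (strand == "+") read_rna else revcomp(read_rna))
      L <- length(r)
      if (L > length(g)) next
      # every window of the chromosome compared position by position
      W <- stats::embed(g, L)[, L:1, drop = FALSE]
      mm <- rowSums(W != matrix(r, nrow(W), L, byrow = TRUE))
      keep <- which(mm <= max_mismatch)
      if (length(keep))
        hits <- rbind(hits, data.frame(chrom = ch, start = keep,
                                       end = keep + L - 1L, strand = strand,
                                       n_mm = as.integer(mm[keep]),
                                       stringsAsFactors = FALSE))
    }
  }
  if (is.null(hits)) return(data.frame(chrom = character(),
    start = integer(), end = integer(), strand = character(),
    n_mm = integer(), stringsAsFactors = FALSE))
  hits[hits$n_mm == min(hits$n_mm), , drop = FALSE]
}

# binomial upper tail by direct summation of the mass function
oracle_binom_tail <- function(k, n, e) {
  if (k <= 0) return(1)
  sum(stats::dbinom(k:n, n, e))
}

# exact two-sided Mann-Whitney p by full enumeration of rank assignments
oracle_mw_exact <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  idx <- utils::combn(na + nb, na)
  pool <- seq_len(na + nb)  # no ties assumed: ranks are 1..n
  us <- apply(idx, 2, function(s) sum(pool[s]) - na * (na + 1) / 2)
  mu <- na * nb / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# minimal site_calls object for cohort-level tests; sites needs precursor,
# position, ref, alt, editing_level, significant; coverage needs pre_id,
# position, total_count
make_calls <- function(sites, coverage) {
  n <- nrow(sites)
  if (is.null(sites$anchor)) sites$anchor <- sites$position
  if (is.null(sites$category)) sites$category <- rep("A-to-I", n)
  if (is.null(sites$name))
    sites$name <- name_site(sites$precursor, sites$position, sites$ref,
                            sites$alt)
  if (is.null(coverage$ref)) coverage$ref <- rep("A", nrow(coverage))
  if (is.null(coverage$total_weight))
    coverage$total_weight <- as.numeric(coverage$total_count)
  structure(list(sites = sites, coverage = coverage, total_mapped = 0L),
            class = "site_calls")
}

# aggregate built directly from a levels matrix (diffstats tests)
make_aggregate <- function(levels, categories = NULL) {
  n <- nrow(levels)
  sites <- data.frame(
    name = if (is.null(rownames(levels)))
      sprintf("site-%d_%d_A_g", seq_len(n), seq_len(n)) else rownames(levels),
    precursor = sprintf("site-%d", seq_len(n)),
    position = seq_len(n), anchor = seq_len(n),
    ref = "A", alt = "G",
    category = categories %||% rep("A-to-I", n),
    n_significant = rep(0L, n),
    max_level = apply(levels, 1, max, na.rm = TRUE),
    stringsAsFactors = FALSE)
  structure(list(sites = sites, levels = levels,
                 significant = !is.na(levels), n_samples = ncol(levels)),
            class = "site_aggregate")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built single-precursor reference for aligner/site-calling tests
make_preset <- function(seed = 11, len = 60L, m5 = c(6L, 27L),
                        m3 = c(34L, 55L), chrom = "chrT", start = 1001L,
                        strand = "+") {
  set.seed(seed)
  len <- as.integer(len); start <- as.integer(start)
  sq <- paste(sample(c("A", "C", "G", "U"), len, TRUE), collapse = "")
  p <- structure(list(
    id = "pre-1", sequence = sq, chrom = chrom, start = start,
    end = start + len - 1L, strand = strand,
    matures = data.frame(name = c("pre-1-5p", "pre-1-3p"),
                         start = c(m5[1], m3[1]), end = c(m5[2], m3[2]),
                         arm = c("5p", "3p"), stringsAsFactors = FALSE)),
    class = "PreMiRNA")
  structure(list(`pre-1` = p), class = "premirna_set")
}

reads_df <- function(sequences, counts = 1L) {
  data.frame(sequence = chartr("T", "U", toupper(sequences)),
             count = as.integer(rep(counts, length.out = length(sequences))),
             stringsAsFactors = FALSE)
}

subchr <- function(x, i, j) substr(x, i, j)
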