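#' Cross-mapping correction of multi-mapped reads
#'
#' Distributes each read's count across its genomic placements as weights
#' proportional to locus support, iterated to a fixed point. Locus support
#' ("expression") is the count-weighted sum of the weights of all placements
#' whose genomic intervals intersect the locus, with the read's own
#' contribution removed before its weights are updated (leave-self-out).
#' Weights start uniform over each read's loci and are renormalized every
#' sweep, so they always sum to one per read. A read whose loci all have
#' zero external support keeps its current (uniform) weights.
#'
#' @param galn a `genome_alignments` table ([align_to_genome()]).
#' @param tol convergence tolerance on the largest absolute weight change
#'   per sweep (default 1e-6).
#' @param max_iter maximum number of sweeps (default 100).
#' @return `galn` with its `weight` column filled in; attribute
#'   `crossmap_diagnostics` holds `iterations`, the `max_delta` trace and
#'   the per-sweep worst deviation of per-read weight sums from one.
#' @export
correct_crossmapping <- function(galn, tol = 1e-6, max_iter = 100L) {
  n <- nrow(galn)
  if (!n) {
    attr(galn, "crossmap_diagnostics") <-
      list(iterations = 0L, max_delta = numeric(), sum_dev = numeric())
    return(galn)
  }
  gr <- GenomicRanges::GRanges(galn$chrom,
                               IRanges::IRanges(galn$start, galn$end))
  ov <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
  H <- data.table::data.table(q = S4Vectors::queryHits(ov),
                              s = S4Vectors::subjectHits(ov))
  read_of <- galn$read_id
  cnt <- as.numeric(galn$count)
  H[, same_read := read_of[q] == read_of[s]]
  loci_of_read <- split(seq_len(n), read_of)
  n_loci <- lengths(loci_of_read)[as.character(read_of)]

  w <- 1 / as.numeric(n_loci)
  deltas <- numeric(); sumdev <- numeric(); it <- 0L
  repeat {
    it <- it + 1L
    contrib <- w * cnt
    expr_all <- H[, .(v = sum(contrib[s])), by = q]
    own <- H[same_read == TRUE, .(v = sum(contrib[s])), by = q]
    e <- numeric(n)
    e[expr_all$q] <- expr_all$v
    e[own$q] <- e[own$q] - own$v
    e[e < 0] <- 0  # numerical guard
    w_new <- w
    for (loci in loci_of_read) {
      if (length(loci) < 2L) { w_new[loci] <- 1; next }
      tot <- sum(e[loci])
      if (tot > 0) w_new[loci] <- e[loci] / tot
    }
    deltas[it] <- max(abs(w_new - w))
    sums <- vapply(loci_of_read, function(l) sum(w_new[l]), numeric(1))
    sumdev[it] <- max(abs(sums - 1))
    w <- w_new
    if (deltas[it] < tol || it >= max_iter) break
  }
  galn$weight <- w
  attr(galn, "crossmap_diagnostics") <-
    list(iterations = it, max_delta = deltas, sum_dev = sumdev)
  galn
}

#' Transfer genomic cross-mapping weights onto precursor alignments
#'
#' Each precursor placement of a read receives the total weight of that
#' read's genomic placements falling inside the precursor locus. A read
#' that maps to the genome but never inside the precursor locus gets weight
#' 0 and is flagged `orphan` (its apparent editing is best explained by
#' another locus; feeds the Pseudo category). A read with no genomic
#' placement at all keeps weight 1: typically a tailed read whose
#' non-templated bases exceed the genomic mismatch budget, which cannot
#' cross-map.
#'
#' @param paln a `premir_alignments` object.
#' @param galn a weighted `genome_alignments` table.
#' @param premirnas the `premirna_set` providing precursor loci.
#' @return `paln` with `weight` and `orphan` columns updated.
#' @export
transfer_weights_to_precursor <- function(paln, galn, premirnas) {
  plc <- paln$placements
  if (!nrow(plc)) return(paln)
  pre_ids <- unique(plc$pre_id)
  loci <- GenomicRanges::GRanges(
    vapply(premirnas[pre_ids], `[[`, "", "chrom"),
    IRanges::IRanges(vapply(premirnas[pre_ids], function(p)
                       as.numeric(p$start), numeric(1)),
                     vapply(premirnas[pre_ids], function(p)
                       as.numeric(p$end), numeric(1))))
  names(loci) <- pre_ids
  mapped_reads <- unique(galn$read_id)
  if (nrow(galn)) {
    gg <- GenomicRanges::GRanges(galn$chrom,
                                 IRanges::IRanges(galn$start, galn$end))
    ov <- GenomicRanges::findOverlaps(gg, loci, ignore.strand = TRUE)
    wtab <- data.table::data.table(
      read_id = galn$read_id[S4Vectors::queryHits(ov)],
      pre_id = pre_ids[S4Vectors::subjectHits(ov)],
      w = galn$weight[S4Vectors::queryHits(ov)])
    wtab <- wtab[, .(w = sum(w)), by = .(read_id, pre_id)]
  } else {
    wtab <- data.table::data.table(read_id = integer(), pre_id = character(),
                                   w = numeric())
  }
  plc[, `:=`(weight = NA_real_, orphan = FALSE)]
  plc[wtab, weight := i.w, on = c("read_id", "pre_id")]
  plc[is.na(weight) & read_id %in% mapped_reads,
      `:=`(weight = 0, orphan = TRUE)]
  plc[is.na(weight), weight := 1]  # no genomic placement anywhere
  paln$placements <- plc
  paln
}

utils::globalVariables(c("same_read", "q", "s", "i.w", "w"))
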