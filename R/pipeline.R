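#' Run the full per-sample identification pipeline
#'
#' Preprocesses reads (quality screening, adapter removal, collapsing),
#' aligns collapsed reads to the precursors, aligns the precursor-mapped
#' reads to the genome, applies cross-mapping correction, transfers locus
#' weights onto the precursor alignments and calls sites.
#'
#' @param reads FASTQ path or data.frame with `sequence`/`quality`.
#' @param ref a reference list with elements `premirnas` (a
#'   `premirna_set`) and `genome` (named `DNAStringSet`), e.g. a
#'   `sim_reference`.
#' @param qc a [qc_params()] object.
#' @param cp a [call_params()] object.
#' @param max_mismatch,min_body aligner settings (see
#'   [align_to_precursors()]); the tail allowance is taken from `cp`.
#' @param ... passed to [call_sample()] (e.g. `apply_level_filter`).
#' @return A `site_calls` object.
#' @export
run_sample <- function(reads, ref, qc = qc_params(), cp = call_params(),
                       max_mismatch = 1L, min_body = 16L, ...) {
  collapsed <- preprocess_reads(reads, qc)
  paln <- align_to_precursors(collapsed, ref$premirnas,
                              max_mismatch = max_mismatch,
                              max_tail = cp$max_tail, min_body = min_body)
  mapped <- sort(unique(paln$placements$read_id))
  if (length(mapped)) {
    sub <- collapsed[mapped, , drop = FALSE]
    rownames(sub) <- NULL
    galn <- align_to_genome(sub, ref$genome, max_mismatch = max_mismatch)
    galn$read_id <- mapped[galn$read_id]
    galn <- correct_crossmapping(galn)
    paln <- transfer_weights_to_precursor(paln, galn, ref$premirnas)
  }
  call_sample(paln, ref$premirnas, cp, ...)
}

#' Run the cohort-level pipeline
#'
#' Per-sample identification for every sample, cohort aggregation,
#' sample-fraction retention and SNP reclassification.
#'
#' @param sample_reads named list of per-sample read sets (each a FASTQ
#'   path or a `sequence`/`quality` data.frame; `sim_sample` objects are
#'   accepted directly).
#' @param ref reference list (`premirnas`, `genome`, optional
#'   `snp_catalog`).
#' @param qc,cp parameter objects.
#' @param fraction retention fraction (default 0.2).
#' @param ... passed to [run_sample()].
#' @return A list with `calls` (per-sample `site_calls`), `aggregate`
#'   (all candidate sites), `retained` (after [retention_filter()] and,
#'   when a SNP catalog is present, [snp_reclassify()]).
#' @export
run_cohort <- function(sample_reads, ref, qc = qc_params(),
                       cp = call_params(), fraction = 0.2, ...) {
  stopifnot(!is.null(names(sample_reads)))
  calls <- lapply(sample_reads, function(x) {
    if (inherits(x, "sim_sample")) x <- x$reads
    run_sample(x, ref, qc = qc, cp = cp, ...)
  })
  aggregate <- merge_samples(calls)
  retained <- retention_filter(aggregate, fraction = fraction)
  if (!is.null(ref$snp_catalog) && nrow(ref$snp_catalog))
    retained <- snp_reclassify(retained, ref$snp_catalog, ref$premirnas)
  list(calls = calls, aggregate = aggregate, retained = retained)
}

#' Write a per-sample site table as TSV
#'
#' @param calls a `site_calls` object.
#' @param path output path.
#' @export
write_site_table <- function(calls, path) {
  utils::write.table(calls$sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write cohort matrices as TSV
#'
#' Writes `<stem>_levels.tsv` (sites x samples editing levels) and
#' `<stem>_sites.tsv` (site metadata).
#'
#' @param aggregate a `site_aggregate`.
#' @param stem output path stem.
#' @export
write_cohort_tables <- function(aggregate, stem) {
  lv <- data.frame(name = aggregate$sites$name, aggregate$levels,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(lv, paste0(stem, "_levels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(aggregate$sites, paste0(stem, "_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(stem)
}
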