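#' Site-calling parameters
#'
#' @param min_level minimum relative editing level (default 0.05).
#' @param min_reads minimum raw read support for the edited allele
#'   (default 10).
#' @param quality_threshold Phred score defining the per-base error rate
#'   used in the binomial test, `e = 10^(-Q/10)` (default 30, so e = 0.001).
#' @param alpha significance level on BH-corrected p-values (default 0.05).
#' @param pseudo_threshold fraction of alt-supporting reads whose best
#'   genomic placements lie outside the precursor locus above which a site
#'   is classified Pseudo (default 0.5).
#' @param max_tail tail allowance used when attributing a site to a mature
#'   miRNA's extended region (default 5, matching the aligner).
#' @return A list of class `call_params`.
#' @export
call_params <- function(min_level = 0.05, min_reads = 10L,
                        quality_threshold = 30L, alpha = 0.05,
                        pseudo_threshold = 0.5, max_tail = 5L) {
  stopifnot(min_level > 0, min_level < 1, min_reads >= 1,
            alpha > 0, alpha < 1)
  structure(list(min_level = min_level, min_reads = as.integer(min_reads),
                 quality_threshold = as.integer(quality_threshold),
                 error_rate = 10^(-quality_threshold / 10),
                 alpha = alpha, pseudo_threshold = pseudo_threshold,
                 max_tail = as.integer(max_tail)),
            class = "call_params")
}

#' Pile up weighted precursor alignments
#'
#' Tallies, for every covered precursor position, the weighted and raw read
#' support per observed nucleotide. A placement covers its body positions
#' and any tail positions that lie at precursor coordinates; tail bases
#' overhanging the precursor 3' terminus are not counted.
#'
#' @param paln a weighted `premir_alignments` object.
#' @param premirnas the `premirna_set`.
#' @return A list with `alleles` (data.table: `pre_id`, `position`, `ref`,
#'   `obs`, `weight`, `count`, `orphan_count`) and `coverage` (data.table:
#'   `pre_id`, `position`, `ref`, `total_weight`, `total_count`).
#' @export
pileup <- function(paln, premirnas) {
  plc <- paln$placements
  empty <- list(
    alleles = data.table::data.table(
      pre_id = character(), position = integer(), ref = character(),
      obs = character(), weight = numeric(), count = integer(),
      orphan_count = integer()),
    coverage = data.table::data.table(
      pre_id = character(), position = integer(), ref = character(),
      total_weight = numeric(), total_count = integer()))
  if (!nrow(plc)) return(empty)
  pre_len <- vapply(premirnas, function(p) nchar(p$sequence), 0L)
  reads <- paln$reads
  L <- nchar(reads$sequence)[plc$read_id]
  n_pos <- pmin(L, pre_len[plc$pre_id] - plc$offset + 1L)
  idx <- rep(seq_len(nrow(plc)), n_pos)
  i <- sequence(n_pos)
  long <- data.table::data.table(
    pre_id = plc$pre_id[idx],
    position = plc$offset[idx] + i - 1L,
    obs = substring(reads$sequence[plc$read_id[idx]], i, i),
    weight = plc$weight[idx] * plc$count[idx],
    count = plc$count[idx],
    orphan = plc$orphan[idx])
  alleles <- long[, .(weight = sum(weight), count = sum(count),
                      orphan_count = sum(count[orphan])),
                  by = .(pre_id, position, obs)]
  coverage <- alleles[, .(total_weight = sum(weight),
                          total_count = sum(count)),
                      by = .(pre_id, position)]
  refs <- vapply(seq_len(nrow(coverage)), function(r)
    substr(premirnas[[coverage$pre_id[r]]]$sequence,
           coverage$position[r], coverage$position[r]), "")
  coverage[, ref := refs]
  alleles[coverage, ref := i.ref, on = c("pre_id", "position")]
  data.table::setcolorder(alleles, c("pre_id", "position", "ref", "obs"))
  data.table::setorder(alleles, pre_id, position, obs)
  data.table::setorder(coverage, pre_id, position)
  list(alleles = alleles,
       coverage = coverage[, .(pre_id, position, ref, total_weight, total_count)])
}

#' One-sided binomial p-value for a candidate site
#'
#' Upper-tail probability `P(X >= k)` with `X ~ Binomial(n, e)`, testing
#' whether `k` edited reads among `n` covering reads exceed what the
#' sequencing-error rate `e` alone would produce.
#'
#' @param k edited read count(s) (raw integers).
#' @param n total read count(s).
#' @param error_rate per-base error probability (default `10^-3`, the
#'   Phred-30 implied rate).
#' @return p-value(s); `NA` where `n == 0`.
#' @export
site_pvalue <- function(k, n, error_rate = 1e-3) {
  stopifnot(all(k >= 0), all(k <= n | n == 0), error_rate > 0, error_rate < 1)
  p <- stats::pbinom(k - 1, n, error_rate, lower.tail = FALSE)
  p[n == 0] <- NA_real_
  p
}

#' Benjamini-Hochberg step-up correction
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"`, kept as the
#' package's single named entry point for multiple-testing correction.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @export
bh_correct <- function(p) {
  if (!length(p)) return(numeric())
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Name a mutation/editing site and parse such names
#'
#' A site is named `<precursor>_<position>_<REF>_<alt>` with the original
#' nucleotide in upper case and the edited/mutated nucleotide in lower
#' case, e.g. `hsa-mir-376a-1_9_A_g`. The corresponding edited-miRNA name
#' is `<precursor>_<position><alt>`, e.g. `hsa-mir-376a-1_9g`.
#'
#' @param precursor_id precursor name.
#' @param position 1-based position within the precursor.
#' @param ref original nucleotide.
#' @param alt edited/mutated nucleotide.
#' @return `name_site`: the site name. `edited_mirna_name`: the edited
#'   miRNA name. `parse_site_name`: a data.frame with components
#'   `precursor`, `position`, `ref`, `alt`.
#' @export
name_site <- function(precursor_id, position, ref, alt) {
  sprintf("%s_%d_%s_%s", precursor_id, as.integer(position),
          toupper(ref), tolower(alt))
}

#' @rdname name_site
#' @export
edited_mirna_name <- function(precursor_id, position, alt) {
  sprintf("%s_%d%s", precursor_id, as.integer(position), tolower(alt))
}

#' @rdname name_site
#' @param name site name(s) to parse.
#' @export
parse_site_name <- function(name) {
  m <- regmatches(name, regexec("^(.+)_(\\d+)_([ACGUN])_([acgun])$", name))
  bad <- lengths(m) != 5L
  if (any(bad))
    stopf("malformed site name: %s", paste(name[bad], collapse = ", "))
  data.frame(precursor = vapply(m, `[`, "", 2L),
             position = as.integer(vapply(m, `[`, "", 3L)),
             ref = vapply(m, `[`, "", 4L),
             alt = toupper(vapply(m, `[`, "", 5L)),
             stringsAsFactors = FALSE)
}

#' Classify a mutation/editing site
#'
#' Assigns one of the categories A-to-I, C-to-U, 3'-A, 3'-U, 3'-Other,
#' 5'-editing, Other or Pseudo, based on the site's position relative to
#' its mature miRNA and the identity of the change. SNP status is decided
#' later, at the cohort stage ([snp_reclassify()]). A site whose
#' alt-supporting reads mostly have their best genomic placements outside
#' the precursor locus (`orphan_fraction > pseudo_threshold`) is Pseudo.
#' The governing mature is the one whose extended region
#' (`start - max_tail` .. `end + max_tail`) contains the position; when two
#' qualify (or none), the mature with the nearer terminus wins, ties going
#' to the 5p arm.
#'
#' @param position precursor-relative site position.
#' @param ref,alt original and observed nucleotide (upper case).
#' @param matures the precursor's mature annotation data.frame.
#' @param orphan_fraction fraction of alt-supporting raw reads flagged as
#'   cross-mapping orphans.
#' @param params a [call_params()] object.
#' @return The category string.
#' @export
classify_site <- function(position, ref, alt, matures,
                          orphan_fraction = 0, params = call_params()) {
  if (orphan_fraction > params$pseudo_threshold) return("Pseudo")
  m <- matures[attribute_mature(position, matures, params$max_tail), ]
  alt <- toupper(alt); ref <- toupper(ref)
  if (position > m$end) {
    switch(alt, A = "3'-A", U = "3'-U", "3'-Other")
  } else if (position < m$start) {
    "5'-editing"
  } else if (ref == "A" && alt == "G") {
    "A-to-I"
  } else if (ref == "C" && alt == "U") {
    "C-to-U"
  } else "Other"
}

# pick the mature miRNA governing a site: the one whose extended region
# (start - max_tail .. end + max_tail) contains the position; ties and the
# no-candidate case resolve to the nearer terminus, then to the 5p arm
attribute_mature <- function(position, matures, max_tail) {
  d <- vapply(seq_len(nrow(matures)), function(i) {
    m <- matures[i, ]
    as.numeric(if (position < m$start) m$start - position
               else if (position > m$end) position - m$end
               else 0)
  }, numeric(1))
  inside_ext <- d <= max_tail
  cand <- if (any(inside_ext)) which(inside_ext) else seq_len(nrow(matures))
  if (length(cand) > 1L) {
    best <- cand[d[cand] == min(d[cand])]
    if (length(best) > 1L)
      best <- best[order(match(matures$arm[best], c("5p", "3p")))][1L]
    cand <- best[1L]
  }
  cand
}

# anchor position whose coverage is the editing-level denominator: the site
# position for central sites, the governing mature's terminus for 5'/3' sites
anchor_position <- function(position, matures, max_tail) {
  m <- matures[attribute_mature(position, matures, max_tail), ]
  min(max(position, m$start), m$end)
}

#' Call mutation/editing sites for one sample
#'
#' Runs the pileup, computes one-sided binomial p-values on raw counts
#' against the Phred-implied error rate, applies Benjamini-Hochberg
#' correction across all candidate sites of the sample, flags significance
#' (editing level >= `min_level`, raw edited reads >= `min_reads`, BH p <
#' `alpha`), and classifies every candidate. Editing levels are computed
#' from cross-mapping-corrected weights: edited weight over the total
#' weighted coverage at the site's anchor position (the site position for
#' central sites; the governing mature's terminus for 5'/3' addition
#' sites, whose own position is only reached by edited reads). The
#' binomial test uses raw integer counts at the same anchor.
#'
#' @param paln a weighted `premir_alignments` object.
#' @param premirnas the `premirna_set`.
#' @param params a [call_params()] object.
#' @param apply_level_filter,apply_reads_filter set FALSE to disable the
#'   level / read-support criteria (used in error-control studies).
#' @return A list of class `site_calls`: `sites` (data.frame, one row per
#'   candidate site), `coverage` (per-position totals) and `total_mapped`
#'   (raw count of reads with at least one precursor placement).
#' @export
call_sample <- function(paln, premirnas, params = call_params(),
                        apply_level_filter = TRUE, apply_reads_filter = TRUE) {
  pu <- pileup(paln, premirnas)
  al <- pu$alleles[obs != ref & obs != "N"]
  cov <- pu$coverage
  if (nrow(al)) {
    # editing-level denominator: coverage at the site's anchor position
    # (the governing mature's terminus for 5'/3' sites)
    al[, anchor := vapply(seq_len(.N), function(i)
      anchor_position(position[i], premirnas[[pre_id[i]]]$matures,
                      params$max_tail), 0L)]
    al <- merge(al, cov[, .(pre_id, anchor = position, total_weight,
                            total_count)],
                by = c("pre_id", "anchor"), sort = FALSE)
    al[, editing_level := ifelse(total_weight > 0,
                                 pmin(1, weight / total_weight), NA_real_)]
    al[, p_raw := site_pvalue(pmin(count, total_count), total_count,
                              params$error_rate)]
    al[, p_bh := bh_correct(p_raw)]
    al[, orphan_fraction := ifelse(count > 0, orphan_count / count, 0)]
    sig <- !is.na(al$p_bh) & al$p_bh < params$alpha
    if (apply_level_filter)
      sig <- sig & !is.na(al$editing_level) & al$editing_level >= params$min_level
    if (apply_reads_filter) sig <- sig & al$count >= params$min_reads
    al[, significant := sig]
    al[, category := vapply(seq_len(.N), function(i)
      classify_site(position[i], ref[i], obs[i],
                    premirnas[[pre_id[i]]]$matures,
                    orphan_fraction[i], params), "")]
    al[, name := name_site(pre_id, position, ref, obs)]
  }
  sites <- data.frame(
    name = if (nrow(al)) al$name else character(),
    precursor = if (nrow(al)) al$pre_id else character(),
    position = if (nrow(al)) al$position else integer(),
    anchor = if (nrow(al)) al$anchor else integer(),
    ref = if (nrow(al)) al$ref else character(),
    alt = if (nrow(al)) al$obs else character(),
    category = if (nrow(al)) al$category else character(),
    edited_count = if (nrow(al)) al$count else integer(),
    total_count = if (nrow(al)) al$total_count else integer(),
    edited_weight = if (nrow(al)) al$weight else numeric(),
    total_weight = if (nrow(al)) al$total_weight else numeric(),
    editing_level = if (nrow(al)) al$editing_level else numeric(),
    p_raw = if (nrow(al)) al$p_raw else numeric(),
    p_bh = if (nrow(al)) al$p_bh else numeric(),
    orphan_fraction = if (nrow(al)) al$orphan_fraction else numeric(),
    significant = if (nrow(al)) al$significant else logical(),
    stringsAsFactors = FALSE)
  total_mapped <- if (nrow(paln$placements))
    sum(paln$reads$count[unique(paln$placements$read_id)]) else 0L
  structure(list(sites = sites, coverage = as.data.frame(cov),
                 total_mapped = total_mapped),
            class = "site_calls")
}

#' Tags-per-ten-million normalization
#'
#' @param count raw read count(s).
#' @param total_mapped total mapped reads in the sample (> 0).
#' @return `count / total_mapped * 1e7`.
#' @export
tptm <- function(count, total_mapped) {
  if (any(total_mapped <= 0)) stopf("total_mapped must be positive")
  count / total_mapped * 1e7
}

utils::globalVariables(c("editing_level", "p_raw", "p_bh", "orphan_fraction",
                         "significant", "category", "name", "i.ref", "anchor"))
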