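#' Minimum number of samples for site retention
#'
#' Nearest integer to `fraction * n_samples`, ties rounded up, with a floor
#' of one sample.
#'
#' @param fraction required fraction of samples (default 0.2).
#' @param n_samples cohort size (cases plus controls).
#' @export
min_sample_threshold <- function(fraction, n_samples) {
  stopifnot(fraction > 0, fraction <= 1, n_samples >= 1)
  max(1L, as.integer(floor(fraction * n_samples + 0.5)))
}

#' Merge per-sample site calls into a cohort aggregate
#'
#' Takes the union of site identities (precursor, position, ref, alt)
#' across samples and builds site-by-sample matrices of editing levels and
#' significance flags. A cell is missing (`NA`) when the sample had no
#' coverage at the position, and zero when the position was covered but the
#' alternative allele was not observed.
#'
#' @param sample_calls named list of `site_calls` objects ([call_sample()]),
#'   names are sample identifiers.
#' @return A list of class `site_aggregate`: `sites` (data.frame with
#'   `name`, `precursor`, `position`, `ref`, `alt`, `category`,
#'   `n_significant`, `max_level`), `levels` and `significant` (matrices,
#'   sites x samples), `n_samples`.
#' @export
merge_samples <- function(sample_calls) {
  stopifnot(length(sample_calls) >= 1, !is.null(names(sample_calls)))
  snames <- names(sample_calls)
  allsites <- data.table::rbindlist(lapply(sample_calls, function(x)
    data.table::as.data.table(x$sites[, c("precursor", "position", "anchor",
                                          "ref", "alt", "category")])))
  if (!nrow(allsites)) {
    sites <- data.frame(name = character(), precursor = character(),
                        position = integer(), ref = character(),
                        alt = character(), category = character(),
                        n_significant = integer(), max_level = numeric(),
                        stringsAsFactors = FALSE)
    lev <- matrix(numeric(), 0, length(snames), dimnames = list(NULL, snames))
    return(structure(list(sites = sites, levels = lev,
                          significant = lev > 0, n_samples = length(snames)),
                     class = "site_aggregate"))
  }
  conflict <- allsites[, .(nref = data.table::uniqueN(ref)),
                       by = .(precursor, position)][nref > 1L]
  if (nrow(conflict))
    stopf("conflicting reference nucleotides across samples at %s:%d; samples were not produced against identical references",
          conflict$precursor[1], conflict$position[1])
  ident <- unique(allsites[, .(precursor, position, anchor, ref, alt)])
  data.table::setorder(ident, precursor, position, alt)
  key <- paste(ident$precursor, ident$position, ident$alt, sep = "|")
  ns <- length(snames)
  lev <- matrix(NA_real_, nrow(ident), ns, dimnames = list(key, snames))
  sig <- matrix(FALSE, nrow(ident), ns, dimnames = list(key, snames))
  cat_first <- rep(NA_character_, nrow(ident))
  for (j in seq_len(ns)) {
    sc <- sample_calls[[j]]
    st <- sc$sites
    if (nrow(st)) {
      k <- paste(st$precursor, st$position, st$alt, sep = "|")
      m <- match(k, key)
      lev[m, j] <- st$editing_level
      sig[m, j] <- st$significant
      cat_first[m[is.na(cat_first[m])]] <- st$category[is.na(cat_first[m])]
    }
    # covered-but-unedited sites: level 0 (coverage judged at the anchor)
    cv <- sc$coverage
    if (nrow(cv)) {
      ck <- paste(cv$pre_id, cv$position, sep = "|")
      pk <- paste(ident$precursor, ident$anchor, sep = "|")
      covered <- !is.na(match(pk, ck[cv$total_count > 0]))
      fill <- covered & is.na(lev[, j])
      lev[fill, j] <- 0
    }
  }
  sites <- data.frame(
    name = name_site(ident$precursor, ident$position, ident$ref, ident$alt),
    precursor = ident$precursor, position = ident$position,
    anchor = ident$anchor, ref = ident$ref, alt = ident$alt,
    category = cat_first,
    n_significant = as.integer(rowSums(sig)),
    max_level = apply(lev, 1, function(x) if (all(is.na(x))) NA_real_
                      else max(x, na.rm = TRUE)),
    stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  structure(list(sites = sites, levels = lev, significant = sig,
                 n_samples = ns),
            class = "site_aggregate")
}

#' Retain sites with significant editing in enough samples
#'
#' A site is retained iff it is significant in at least
#' `min_sample_threshold(fraction, n_samples)` samples, thresholds computed
#' on the combined cohort (cases plus controls).
#'
#' @param aggregate a `site_aggregate`.
#' @param fraction required fraction of samples (default 0.2).
#' @return The aggregate restricted to retained sites; the threshold used
#'   is recorded in attribute `threshold`.
#' @export
retention_filter <- function(aggregate, fraction = 0.2) {
  thr <- min_sample_threshold(fraction, aggregate$n_samples)
  keep <- aggregate$sites$n_significant >= thr
  out <- subset_aggregate(aggregate, keep)
  attr(out, "threshold") <- thr
  out
}

subset_aggregate <- function(aggregate, keep) {
  out <- aggregate
  out$sites <- aggregate$sites[keep, , drop = FALSE]
  rownames(out$sites) <- NULL
  out$levels <- aggregate$levels[keep, , drop = FALSE]
  out$significant <- aggregate$significant[keep, , drop = FALSE]
  out
}

#' Reclassify sites matching catalogued SNPs
#'
#' A site's category is overridden to `SNP` iff (i) its genomic position
#' equals a catalogued SNP position, (ii) both its original and changed
#' nucleotides match the SNP's reference and alternative alleles (alleles
#' compared on the genome strand: for precursors on the minus strand the
#' site's nucleotides are complemented first), and (iii) its editing level
#' reaches 100% in at least one sample.
#'
#' @param aggregate a `site_aggregate`.
#' @param snp_catalog a `site_catalog` ([load_catalog()]).
#' @param premirnas the `premirna_set` (for coordinate conversion).
#' @param level_tol numerical tolerance on the 100% level criterion.
#' @return The aggregate with updated `category` and a `snp_match` column
#'   naming the catalog entry (`NA` where no match).
#' @export
snp_reclassify <- function(aggregate, snp_catalog, premirnas,
                           level_tol = 1e-9) {
  st <- aggregate$sites
  st$snp_match <- NA_character_
  if (nrow(st) && nrow(snp_catalog)) {
    gpos <- vapply(seq_len(nrow(st)), function(i)
      premir_to_genomic(premirnas[[st$precursor[i]]], st$position[i]), numeric(1))
    chrom <- vapply(st$precursor, function(p) premirnas[[p]]$chrom, "")
    strand <- vapply(st$precursor, function(p) premirnas[[p]]$strand, "")
    ref_g <- to_dna(st$ref); alt_g <- to_dna(st$alt)
    neg <- strand == "-"
    ref_g[neg] <- dna_complement(ref_g[neg])
    alt_g[neg] <- dna_complement(alt_g[neg])
    m <- match(paste(chrom, gpos), paste(snp_catalog$chromosome,
                                         snp_catalog$position))
    for (i in which(!is.na(m))) {
      rec <- snp_catalog[m[i], ]
      allele_ok <- ref_g[i] == rec$ref && alt_g[i] %in% rec$alts[[1]]
      level_ok <- !is.na(st$max_level[i]) && st$max_level[i] >= 1 - level_tol
      if (allele_ok && level_ok) {
        st$category[i] <- "SNP"
        st$snp_match[i] <- if (nzchar(rec$id)) rec$id else
          sprintf("%s:%d", rec$chromosome, rec$position)
      }
    }
  }
  aggregate$sites <- st
  aggregate
}

#' Annotate sites found in a known-editing-site catalog
#'
#' Position- and allele-matched lookup against a catalogue of previously
#' reported editing sites; no category change, annotation only.
#'
#' @param aggregate a `site_aggregate`.
#' @param known_catalog a `site_catalog` of kind `known_editing`.
#' @param premirnas the `premirna_set`.
#' @return The aggregate with a `known_source` column added to `sites`.
#' @export
annotate_known_sites <- function(aggregate, known_catalog, premirnas) {
  st <- aggregate$sites
  st$known_source <- NA_character_
  if (nrow(st) && nrow(known_catalog)) {
    gpos <- vapply(seq_len(nrow(st)), function(i)
      premir_to_genomic(premirnas[[st$precursor[i]]], st$position[i]), numeric(1))
    chrom <- vapply(st$precursor, function(p) premirnas[[p]]$chrom, "")
    strand <- vapply(st$precursor, function(p) premirnas[[p]]$strand, "")
    alt_g <- to_dna(st$alt)
    alt_g[strand == "-"] <- dna_complement(alt_g[strand == "-"])
    m <- match(paste(chrom, gpos), paste(known_catalog$chromosome,
                                         known_catalog$position))
    for (i in which(!is.na(m))) {
      rec <- known_catalog[m[i], ]
      if (alt_g[i] %in% rec$alts[[1]]) st$known_source[i] <- rec$id
    }
  }
  aggregate$sites <- st
  aggregate
}

#' Intersect site sets across cohorts
#'
#' Venn-style membership of retained site identities across two or more
#' cohorts, and for sites present in every cohort, the per-cohort
#' direction of mean editing-level change (cases versus controls).
#'
#' @param aggregates named list of `site_aggregate` objects (one per
#'   cohort, typically after [retention_filter()]).
#' @param group_labels optional named list of factors/character vectors
#'   (two levels, case first) aligned with each aggregate's sample columns;
#'   required for the direction table.
#' @return A list with `membership` (data.frame: site name plus one
#'   logical column per cohort), `common_sites` (names in every cohort) and
#'   `directions` (data.frame of per-cohort `"up"`/`"down"`/`"none"` for
#'   common sites; `NULL` without `group_labels`).
#' @export
intersect_cohorts <- function(aggregates, group_labels = NULL) {
  stopifnot(length(aggregates) >= 2, !is.null(names(aggregates)))
  ids <- lapply(aggregates, function(a) a$sites$name)
  univ <- sort(unique(unlist(ids)))
  membership <- data.frame(name = univ, stringsAsFactors = FALSE)
  for (nm in names(aggregates)) membership[[nm]] <- univ %in% ids[[nm]]
  common <- univ[rowSums(as.matrix(membership[-1])) == length(aggregates)]
  directions <- NULL
  if (!is.null(group_labels) && length(common)) {
    directions <- data.frame(name = common, stringsAsFactors = FALSE)
    for (nm in names(aggregates)) {
      a <- aggregates[[nm]]
      lab <- group_labels[[nm]]
      lv <- unique(as.character(lab))
      stopifnot(length(lv) == 2)
      i <- match(common, a$sites$name)
      mcase <- rowMeans(a$levels[i, lab == lv[1], drop = FALSE], na.rm = TRUE)
      mctrl <- rowMeans(a$levels[i, lab == lv[2], drop = FALSE], na.rm = TRUE)
      d <- mcase - mctrl
      directions[[nm]] <- ifelse(is.na(d) | d == 0, "none",
                                 ifelse(d > 0, "up", "down"))
    }
  }
  list(membership = membership, common_sites = common,
       directions = directions)
}

utils::globalVariables(c("nref", "max_level"))
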