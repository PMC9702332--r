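#' Configuration for the small-RNA read simulator
#'
#' Defines the synthetic study conditions: reference geometry, injected
#' mutation/editing events with per-group editing levels, non-templated
#' addition models, sequencing-error model, adapters and cohort layout.
#'
#' Events are specified abstractly and materialized onto concrete precursor
#' positions by [generate_reference()]. The `events` data.frame columns:
#' `precursor` (index), `type` (`"central"`, `"three_prime"`,
#' `"five_prime"`), `arm` (`"5p"`/`"3p"`), `offset` (central: position
#' within the mature, e.g. 9 for the ninth nucleotide; three_prime: bases
#' past the mature 3' end; five_prime: bases before the mature 5' start),
#' `ref` (desired original nucleotide or `NA` to keep/resample), `alt`
#' (added or substituted nucleotide), `germline` (logical; editing level 1
#' in every group and a SNP-catalog entry), and either a single `theta`
#' column or one `theta_<group>` column per group.
#'
#' @param n_precursors number of hairpin precursors (default 6).
#' @param precursor_length length range, nt (default 70-100).
#' @param mature_length mature arm length range, nt (default 20-23).
#' @param depth reads per precursor per sample (default 300).
#' @param arm_bias fraction of a precursor's reads from the 5p arm.
#' @param error_rate per-base sequencing-error probability (default 0.001,
#'   the Phred-30 implied rate).
#' @param adapter 3' adapter appended to every read.
#' @param base_quality constant Phred score written to FASTQ (default 38).
#' @param events event table as described above (`NULL` for none).
#' @param templated_extension_rate probability a read (not carrying a 3'
#'   addition) extends 1-2 templated nucleotides past its mature 3' end,
#'   emulating 3' isomiRs (default 0).
#' @param tail_rate probability a read receives a background non-templated
#'   3' tail (default 0).
#' @param tail_geom_p geometric parameter for tail length (default 0.5,
#'   truncated at `tail_max`).
#' @param tail_max maximum background tail length (default 3).
#' @param tail_composition base composition of background tails (A/U
#'   dominated by default, mirroring the prevalence of 3'-A and 3'-U).
#' @param five_prime_rate probability of a background single-base 5'
#'   addition (default 0).
#' @param five_prime_composition base composition of 5' additions
#'   (C-biased by default).
#' @param paralogs optional data.frame with `source` (precursor index),
#'   `mode` (`"exact"`: an exact extra genomic copy of the locus;
#'   `"arm_shared"`: an annotated second precursor sharing the 5p mature
#'   sequence with a divergent 3p arm) and `depth_ratio` (arm_shared only).
#' @param groups named integer vector of cohort sizes,
#'   e.g. `c(case = 10, control = 2)`.
#' @param allow_minus_strand place some precursors on the minus strand.
#' @param flank background genome sequence between loci, nt.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_precursors = 6L,
                       precursor_length = c(70L, 100L),
                       mature_length = c(20L, 23L),
                       depth = 300L,
                       arm_bias = 0.7,
                       error_rate = 0.001,
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       base_quality = 38L,
                       events = NULL,
                       templated_extension_rate = 0,
                       tail_rate = 0,
                       tail_geom_p = 0.5,
                       tail_max = 3L,
                       tail_composition = c(A = 0.6, U = 0.3, G = 0.05, C = 0.05),
                       five_prime_rate = 0,
                       five_prime_composition = c(C = 0.7, A = 0.1, G = 0.1, U = 0.1),
                       paralogs = NULL,
                       groups = c(case = 10L, control = 10L),
                       allow_minus_strand = TRUE,
                       flank = 150L) {
  stopifnot(n_precursors >= 1, depth >= 1, error_rate >= 0, error_rate < 1,
            arm_bias > 0, arm_bias < 1, base_quality > 30, base_quality <= 41,
            !is.null(names(groups)), all(groups >= 1),
            abs(sum(tail_composition) - 1) < 1e-6,
            abs(sum(five_prime_composition) - 1) < 1e-6)
  if (!is.null(events)) {
    stopifnot(all(c("precursor", "type", "alt") %in% names(events)))
    if (!"arm" %in% names(events)) events$arm <- "5p"
    if (!"germline" %in% names(events)) events$germline <- FALSE
    if (!"ref" %in% names(events)) events$ref <- NA_character_
    tc <- paste0("theta_", names(groups))
    if (!all(tc %in% names(events))) {
      if (!"theta" %in% names(events))
        stopf("events need a 'theta' column or one theta_<group> per group")
      for (g in tc) events[[g]] <- events$theta
    }
    events[tc][events$germline, ] <- 1
  }
  structure(list(
    n_precursors = as.integer(n_precursors),
    precursor_length = as.integer(precursor_length),
    mature_length = as.integer(mature_length),
    depth = as.integer(depth), arm_bias = arm_bias,
    error_rate = error_rate, adapter = toupper(adapter),
    base_quality = as.integer(base_quality), events = events,
    templated_extension_rate = templated_extension_rate,
    tail_rate = tail_rate, tail_geom_p = tail_geom_p,
    tail_max = as.integer(tail_max), tail_composition = tail_composition,
    five_prime_rate = five_prime_rate,
    five_prime_composition = five_prime_composition,
    paralogs = paralogs, groups = groups,
    allow_minus_strand = isTRUE(allow_minus_strand),
    flank = as.integer(flank)), class = "sim_config")
}

rand_rna <- function(n) paste(sample(RNA_ALPHABET, n, replace = TRUE),
                              collapse = "")

#' Generate the synthetic reference set
#'
#' Builds precursors with annotated mature arms, materializes the
#' configured events onto concrete positions (adjusting precursor bases so
#' each event's original nucleotide differs from its alternative), embeds
#' the precursors in a random background genome (with paralogous copies
#' where configured) and derives the SNP catalog from germline events.
#' With `dir` set, writes `precursors.fa`, `genome.fa`, `annotation.gff3`
#' and `snps.tsv`; identical config and seed give byte-identical files.
#'
#' @param config a [sim_config()] object.
#' @param seed integer RNG seed.
#' @param dir optional output directory for reference files.
#' @return A list of class `sim_reference`: `premirnas` (a `premirna_set`),
#'   `genome` (named `DNAStringSet`), `events` (materialized event table),
#'   `snp_catalog` (a `site_catalog`), `depth_by_pre`, `paralog_loci`,
#'   `config`, and `files` when written.
#' @export
generate_reference <- function(config, seed = 1L, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed %% 2147483647L)
  np <- config$n_precursors
  lens <- sample(seq(config$precursor_length[1], config$precursor_length[2]),
                 np, replace = TRUE)
  pres <- list()
  for (i in seq_len(np)) {
    id <- sprintf("sim-mir-%d", i)
    L <- lens[i]
    m5l <- sample(seq(config$mature_length[1], config$mature_length[2]), 1)
    m3l <- sample(seq(config$mature_length[1], config$mature_length[2]), 1)
    s5 <- sample(4:6, 1)
    e3 <- L - sample(4:6, 1)
    matures <- data.frame(
      name = paste0(id, c("-5p", "-3p")),
      start = c(s5, e3 - m3l + 1L), end = c(s5 + m5l - 1L, e3),
      arm = c("5p", "3p"), stringsAsFactors = FALSE)
    if (matures$start[2] - matures$end[1] < 4L)
      stopf("precursor %s too short for both arms; increase precursor_length", id)
    pres[[id]] <- list(id = id, sequence = rand_rna(L), matures = matures)
  }

  # materialize events
  ev <- config$events
  mat_events <- NULL
  if (!is.null(ev) && nrow(ev)) {
    rows <- list()
    for (r in seq_len(nrow(ev))) {
      pi <- ev$precursor[r]
      stopifnot(pi >= 1, pi <= np)
      p <- pres[[pi]]
      m <- p$matures[p$matures$arm == ev$arm[r], ]
      off <- if ("offset" %in% names(ev)) ev$offset[r] else NA
      pos <- switch(ev$type[r],
        central = m$start + (ifelse(is.na(off), 9L, off)) - 1L,
        three_prime = m$end + ifelse(is.na(off), 1L, off),
        five_prime = m$start - ifelse(is.na(off), 1L, off),
        stopf("unknown event type '%s'", ev$type[r]))
      if (pos < 1L || pos > nchar(p$sequence))
        stopf("event %d falls outside precursor %s", r, p$id)
      if (ev$type[r] == "central" && (pos < m$start || pos > m$end))
        stopf("central event %d outside mature region", r)
      alt <- toupper(ev$alt[r])
      ref <- if (!is.na(ev$ref[r])) toupper(ev$ref[r]) else
        substr(p$sequence, pos, pos)
      if (ref == alt)
        ref <- sample(setdiff(RNA_ALPHABET, alt), 1)
      substr(pres[[pi]]$sequence, pos, pos) <- ref
      rows[[r]] <- data.frame(
        precursor = p$id, position = pos, ref = ref, alt = alt,
        type = ev$type[r], arm = ev$arm[r], germline = ev$germline[r],
        stringsAsFactors = FALSE)
      for (g in names(config$groups))
        rows[[r]][[paste0("theta_", g)]] <- ev[[paste0("theta_", g)]][r]
    }
    mat_events <- do.call(rbind, rows)
    if (anyDuplicated(mat_events[c("precursor", "position")]))
      stopf("two events materialize to the same precursor position")
    expected <- function(type, ref, alt) {
      if (type == "central") {
        if (ref == "A" && alt == "G") "A-to-I"
        else if (ref == "C" && alt == "U") "C-to-U"
        else "Other"
      } else if (type == "three_prime") {
        switch(alt, A = "3'-A", U = "3'-U", "3'-Other")
      } else "5'-editing"
    }
    mat_events$expected_category <- vapply(seq_len(nrow(mat_events)),
      function(r) expected(mat_events$type[r], mat_events$ref[r],
                           mat_events$alt[r]), "")
  }

  # annotated arm-shared paralogs become extra precursors
  depth_by_pre <- stats::setNames(rep(config$depth, np), names(pres))
  if (!is.null(config$paralogs) && nrow(config$paralogs)) {
    for (r in seq_len(nrow(config$paralogs))) {
      if (config$paralogs$mode[r] != "arm_shared") next
      src <- pres[[config$paralogs$source[r]]]
      id <- paste0(src$id, "-P")
      L <- nchar(src$sequence)
      sq <- rand_rna(L)
      m5 <- src$matures[src$matures$arm == "5p", ]
      substr(sq, m5$start, m5$end) <- substr(src$sequence, m5$start, m5$end)
      # guarantee divergence immediately past the shared arm so templated
      # 3' isomiRs are locus-specific
      for (dpos in (m5$end + 1L):min(m5$end + 2L, L)) {
        srcnt <- substr(src$sequence, dpos, dpos)
        substr(sq, dpos, dpos) <- sample(setdiff(RNA_ALPHABET, srcnt), 1)
      }
      pres[[id]] <- list(id = id, sequence = sq, matures = src$matures)
      depth_by_pre[id] <- max(1L, round(config$depth *
                                        config$paralogs$depth_ratio[r]))
    }
  }

  # genome assembly: one chromosome, loci separated by random background
  chrom <- "chrSim"
  segs <- character(); cursor <- 0L
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  add_seg <- function(s) { segs[[length(segs) + 1L]] <<- s
                           cursor <<- cursor + nchar(s); invisible(NULL) }
  premirnas <- list()
  for (id in names(pres)) {
    p <- pres[[id]]
    strand <- if (config$allow_minus_strand)
      sample(c("+", "-"), 1) else "+"
    add_seg(bg(config$flank))
    gstart <- cursor + 1L
    gseq <- to_dna(p$sequence)
    if (strand == "-")
      gseq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(gseq)))
    add_seg(gseq)
    premirnas[[id]] <- structure(
      list(id = id, sequence = p$sequence, chrom = chrom,
           start = gstart, end = cursor, strand = strand,
           matures = p$matures), class = "PreMiRNA")
  }
  paralog_loci <- NULL
  if (!is.null(config$paralogs) && nrow(config$paralogs)) {
    for (r in seq_len(nrow(config$paralogs))) {
      if (config$paralogs$mode[r] != "exact") next
      src <- premirnas[[config$paralogs$source[r]]]
      add_seg(bg(config$flank))
      gstart <- cursor + 1L
      gseq <- to_dna(src$sequence)
      if (src$strand == "-")
        gseq <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(gseq)))
      add_seg(gseq)
      paralog_loci <- rbind(paralog_loci, data.frame(
        source = src$id, chrom = chrom, start = gstart, end = cursor,
        strand = src$strand, stringsAsFactors = FALSE))
    }
  }
  add_seg(bg(config$flank))
  genome <- Biostrings::DNAStringSet(stats::setNames(
    paste(segs, collapse = ""), chrom))
  premirnas <- structure(premirnas, class = "premirna_set")

  # SNP catalog rows from germline events (genome-strand alleles)
  snp_rows <- NULL
  if (!is.null(mat_events)) {
    mat_events$chrom <- chrom
    mat_events$genomic_pos <- as.integer(vapply(
      seq_len(nrow(mat_events)), function(r)
        premir_to_genomic(premirnas[[mat_events$precursor[r]]],
                          mat_events$position[r]), numeric(1)))
    gl <- mat_events[mat_events$germline, , drop = FALSE]
    if (nrow(gl)) {
      strands <- vapply(gl$precursor, function(p) premirnas[[p]]$strand, "")
      refs <- to_dna(gl$ref); alts <- to_dna(gl$alt)
      refs[strands == "-"] <- dna_complement(refs[strands == "-"])
      alts[strands == "-"] <- dna_complement(alts[strands == "-"])
      snp_rows <- data.frame(
        chromosome = chrom, position = gl$genomic_pos, ref = refs,
        alt = alts, id = sprintf("simSNP%d", seq_len(nrow(gl))),
        stringsAsFactors = FALSE)
    }
  }
  snp_catalog <- catalog_from_rows(snp_rows)

  out <- structure(list(premirnas = premirnas, genome = genome,
                        events = mat_events, snp_catalog = snp_catalog,
                        depth_by_pre = depth_by_pre,
                        paralog_loci = paralog_loci, config = config),
                   class = "sim_reference")
  if (!is.null(dir)) out$files <- write_reference(out, dir)
  out
}

catalog_from_rows <- function(rows) {
  if (is.null(rows) || !nrow(rows)) {
    out <- data.frame(chromosome = character(), position = integer(),
                      ref = character(), id = character(),
                      stringsAsFactors = FALSE)
    out$alts <- list()
  } else {
    out <- data.frame(chromosome = rows$chromosome,
                      position = as.integer(rows$position),
                      ref = rows$ref, id = rows$id, stringsAsFactors = FALSE)
    out$alts <- as.list(rows$alt)
  }
  class(out) <- c("site_catalog", "data.frame")
  attr(out, "kind") <- "snp"
  out
}

write_reference <- function(ref, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, "precursors.fa")
  gfa <- file.path(dir, "genome.fa")
  gff <- file.path(dir, "annotation.gff3")
  tsv <- file.path(dir, "snps.tsv")
  ps <- Biostrings::BStringSet(vapply(ref$premirnas, `[[`, "", "sequence"))
  names(ps) <- names(ref$premirnas)
  Biostrings::writeXStringSet(ps, fa)
  Biostrings::writeXStringSet(ref$genome, gfa)

  lines <- c("##gff-version 3")
  for (p in ref$premirnas) {
    lines <- c(lines, sprintf(
      "%s\t.\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
      p$chrom, p$start, p$end, p$strand, p$id, p$id))
    for (k in seq_len(nrow(p$matures))) {
      g1 <- premir_to_genomic(p, p$matures$start[k])
      g2 <- premir_to_genomic(p, p$matures$end[k])
      lines <- c(lines, sprintf(
        "%s\t.\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;Derives_from=%s",
        p$chrom, min(g1, g2), max(g1, g2), p$strand,
        p$matures$name[k], p$matures$name[k], p$id))
    }
  }
  writeLines(lines, gff)

  sc <- ref$snp_catalog
  snp_df <- if (nrow(sc)) data.frame(
    chromosome = rep(sc$chromosome, lengths(sc$alts)),
    position = rep(sc$position, lengths(sc$alts)),
    ref = rep(sc$ref, lengths(sc$alts)),
    alt = unlist(sc$alts),
    id = rep(sc$id, lengths(sc$alts)), stringsAsFactors = FALSE)
  else data.frame(chromosome = character(), position = integer(),
                  ref = character(), alt = character(), id = character())
  utils::write.table(snp_df, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(precursor_fasta = fa, genome_fasta = gfa, gff3 = gff, snp_tsv = tsv)
}

#' Simulate one small-RNA sequencing sample
#'
#' Draws reads from the mature arms of every precursor at the configured
#' depth, applies the injected events at their group-specific editing
#' levels, the background 5' addition and 3' tail models, per-base
#' sequencing errors, appends the adapter and constant-quality Phred
#' strings, and records ground truth. Each sample uses its own RNG stream
#' derived from `(master_seed, sample_index)`.
#'
#' @param ref a `sim_reference` ([generate_reference()]).
#' @param group group name (must match `config$groups`).
#' @param sample_index integer sample index (unique within the cohort).
#' @param master_seed master RNG seed.
#' @param fastq optional path; when set the sample is also written as FASTQ.
#' @return A list of class `sim_sample`: `reads` (data.frame `sequence`
#'   (DNA, adapter included) and `quality`), `truth` (per-event realized
#'   counts: `precursor`, `position`, `ref`, `alt`, `type`,
#'   `expected_category`, `germline`, `theta`, `n_reads`, `n_edited`),
#'   `additions` (realized composition of background/model additions),
#'   `group`, `sample_index`.
#' @export
simulate_sample <- function(ref, group, sample_index, master_seed = 1L,
                            fastq = NULL) {
  stopifnot(inherits(ref, "sim_reference"),
            group %in% names(ref$config$groups))
  cfg <- ref$config
  set.seed(as.integer((as.numeric(master_seed) * 7919 +
                       as.numeric(sample_index) * 104729) %% 2147483647))
  theta_col <- paste0("theta_", group)
  all_reads <- character(0)
  truth <- list(); add5 <- character(0); add3 <- character(0)
  for (id in names(ref$premirnas)) {
    p <- ref$premirnas[[id]]
    depth <- ref$depth_by_pre[[id]]
    n5 <- round(depth * cfg$arm_bias)
    for (arm in c("5p", "3p")) {
      m <- p$matures[p$matures$arm == arm, ]
      n <- if (arm == "5p") n5 else depth - n5
      if (n < 1) next
      base <- substr(p$sequence, m$start, m$end)
      reads <- rep(base, n)
      evs <- ref$events
      evs <- if (is.null(evs)) NULL else
        evs[evs$precursor == id & evs$arm == arm, , drop = FALSE]
      # central substitutions
      if (!is.null(evs)) for (r in which(evs$type == "central")) {
        th <- evs[[theta_col]][r]
        sel <- stats::runif(n) < th
        rel <- evs$position[r] - m$start + 1L
        substr(reads[sel], rel, rel) <- evs$alt[r]
        truth[[length(truth) + 1L]] <- cbind(
          evs[r, c("precursor", "position", "ref", "alt", "type",
                   "expected_category", "germline")],
          data.frame(theta = th, n_reads = n, n_edited = sum(sel)))
      }
      # chained non-templated 3' additions (ordered by position)
      tailed <- rep(FALSE, n)
      if (!is.null(evs)) {
        t3 <- evs[evs$type == "three_prime", , drop = FALSE]
        if (nrow(t3)) {
          t3 <- t3[order(t3$position), , drop = FALSE]
          carried <- rep(TRUE, n)
          for (r in seq_len(nrow(t3))) {
            th <- t3[[theta_col]][r]
            sel <- carried & stats::runif(n) < th
            reads[sel] <- paste0(reads[sel], t3$alt[r])
            truth[[length(truth) + 1L]] <- cbind(
              t3[r, c("precursor", "position", "ref", "alt", "type",
                      "expected_category", "germline")],
              data.frame(theta = th, n_reads = n, n_edited = sum(sel)))
            carried <- sel
            tailed <- tailed | sel
          }
        }
      }
      # templated 3' isomiR extension of untailed reads
      if (cfg$templated_extension_rate > 0) {
        avail <- nchar(p$sequence) - m$end
        if (avail >= 1L) {
          sel <- !tailed & stats::runif(n) < cfg$templated_extension_rate
          if (any(sel)) {
            el <- pmin(sample(1:2, sum(sel), replace = TRUE), avail)
            reads[sel] <- paste0(reads[sel],
                                 substring(p$sequence, m$end + 1L,
                                           m$end + el))
            tailed <- tailed | sel
          }
        }
      }
      # 5' additions (event, else background model)
      ev5 <- if (is.null(evs)) NULL else
        evs[evs$type == "five_prime", , drop = FALSE]
      got5 <- rep(FALSE, n)
      if (!is.null(ev5) && nrow(ev5)) for (r in seq_len(nrow(ev5))) {
        th <- ev5[[theta_col]][r]
        sel <- !got5 & stats::runif(n) < th
        reads[sel] <- paste0(ev5$alt[r], reads[sel])
        got5 <- got5 | sel
        add5 <- c(add5, rep(ev5$alt[r], sum(sel)))
        truth[[length(truth) + 1L]] <- cbind(
          ev5[r, c("precursor", "position", "ref", "alt", "type",
                   "expected_category", "germline")],
          data.frame(theta = th, n_reads = n, n_edited = sum(sel)))
      }
      if (cfg$five_prime_rate > 0) {
        sel <- !got5 & stats::runif(n) < cfg$five_prime_rate
        if (any(sel)) {
          nt <- sample(names(cfg$five_prime_composition), sum(sel),
                       replace = TRUE, prob = cfg$five_prime_composition)
          reads[sel] <- paste0(nt, reads[sel])
          add5 <- c(add5, nt)
        }
      }
      # background 3' tails
      if (cfg$tail_rate > 0) {
        sel <- !tailed & stats::runif(n) < cfg$tail_rate
        if (any(sel)) {
          tl <- pmin(stats::rgeom(sum(sel), cfg$tail_geom_p) + 1L,
                     cfg$tail_max)
          tails <- vapply(tl, function(l)
            paste(sample(names(cfg$tail_composition), l, replace = TRUE,
                         prob = cfg$tail_composition), collapse = ""), "")
          reads[sel] <- paste0(reads[sel], tails)
          add3 <- c(add3, unlist(strsplit(tails, "")))
        }
      }
      all_reads <- c(all_reads, reads)
    }
  }
  # sequencing errors, uniform substitution among the other three bases
  if (cfg$error_rate > 0) {
    lens <- nchar(all_reads)
    n_err <- stats::rbinom(length(all_reads), lens, cfg$error_rate)
    for (i in which(n_err > 0)) {
      pos <- sample.int(lens[i], n_err[i])
      for (pp in pos) {
        cur <- substr(all_reads[i], pp, pp)
        substr(all_reads[i], pp, pp) <- sample(setdiff(RNA_ALPHABET, cur), 1)
      }
    }
  }
  seqs <- paste0(to_dna(all_reads), cfg$adapter)
  qual <- vapply(nchar(seqs), function(L)
    strrep(intToUtf8(cfg$base_quality + 33L), L), "")
  truth_df <- if (length(truth)) do.call(rbind, truth) else NULL
  out <- structure(list(
    reads = data.frame(sequence = seqs, quality = qual,
                       stringsAsFactors = FALSE),
    truth = truth_df,
    additions = list(five_prime = table(add5), three_prime = table(add3)),
    group = group, sample_index = sample_index), class = "sim_sample")
  if (!is.null(fastq)) {
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(seqs),
      Biostrings::PhredQuality(qual))
    names(x) <- sprintf("%s_s%d_r%d", group, sample_index,
                        seq_along(seqs))
    Biostrings::writeQualityScaledXStringSet(x, fastq)
    out$fastq <- fastq
  }
  out
}

#' Simulate a full cohort
#'
#' @param ref a `sim_reference`.
#' @param master_seed master RNG seed; sample `i` of the cohort uses the
#'   stream derived from `(master_seed, i)`.
#' @return Named list of `sim_sample` objects (`<group><k>`), with the
#'   group label vector as attribute `groups`.
#' @export
simulate_cohort <- function(ref, master_seed = 1L) {
  sizes <- ref$config$groups
  out <- list(); idx <- 0L; labels <- character()
  for (g in names(sizes)) {
    for (k in seq_len(sizes[[g]])) {
      idx <- idx + 1L
      out[[sprintf("%s%d", g, k)]] <-
        simulate_sample(ref, g, idx, master_seed)
      labels <- c(labels, g)
    }
  }
  attr(out, "groups") <- labels
  out
}

#' Compare called sites against simulation ground truth
#'
#' Matches called sites with injected events by (precursor, position, alt).
#' An injected event with at least one realized edited read counts as a
#' true positive when called significant and a false negative otherwise
#' (including events left under the read-support threshold by low
#' coverage); significant calls with no matching event are false positives.
#' Level RMSE compares the called editing level with the injected level for
#' matched sites.
#'
#' @param truth a truth table (`sim_sample$truth` or several rbind-ed).
#' @param called a `site_calls` object or its `sites` data.frame.
#' @return A list with `tp`, `fp`, `fn`, `rmse`, `by_category`
#'   (data.frame) and `matched` (joined site/truth table).
#' @export
evaluate_calls <- function(truth, called) {
  sites <- if (inherits(called, "site_calls")) called$sites else called
  if (is.null(truth)) truth <- data.frame(
    precursor = character(), position = integer(), ref = character(),
    alt = character(), expected_category = character(), theta = numeric(),
    n_reads = integer(), n_edited = integer(), stringsAsFactors = FALSE)
  tkey <- paste(truth$precursor, truth$position, truth$alt, sep = "|")
  sig <- sites[sites$significant, , drop = FALSE]
  skey <- paste(sig$precursor, sig$position, sig$alt, sep = "|")
  injected <- truth$n_edited > 0
  tp_mask <- injected & tkey %in% skey
  fn_mask <- injected & !tkey %in% skey
  fp_mask <- !skey %in% tkey[injected]
  m <- match(tkey[tp_mask], paste(sites$precursor, sites$position,
                                  sites$alt, sep = "|"))
  matched <- cbind(truth[tp_mask, , drop = FALSE],
                   called_level = sites$editing_level[m],
                   called_category = sites$category[m])
  rmse <- if (nrow(matched))
    sqrt(mean((matched$called_level - matched$theta)^2)) else NA_real_
  bc <- if (any(injected)) {
    sp <- split(seq_len(sum(injected)), truth$expected_category[injected])
    do.call(rbind, lapply(names(sp), function(cat) data.frame(
      category = cat,
      tp = sum(tp_mask[injected][sp[[cat]]]),
      fn = sum(fn_mask[injected][sp[[cat]]]),
      stringsAsFactors = FALSE)))
  } else NULL
  list(tp = sum(tp_mask), fp = sum(fp_mask), fn = sum(fn_mask),
       rmse = rmse, by_category = bc, matched = matched)
}

#' Simulate a site-by-sample editing-level matrix
#'
#' Direct binomial sampling of editing levels at fixed coverage, without
#' read-level simulation: cell (site, sample) is
#' `Binomial(coverage, theta) / coverage` with `theta` taken from the
#' site's group column. Used for differential-editing power studies where
#' the unit under test is the group comparison itself.
#'
#' @param thetas matrix or data.frame, sites x groups, of true editing
#'   levels per group.
#' @param groups named integer vector of group sizes (names must match
#'   `colnames(thetas)`).
#' @param coverage reads covering each site (default 500).
#' @param seed RNG seed.
#' @return A list with `levels` (sites x samples), `labels` (group per
#'   sample), `thetas`.
#' @export
simulate_level_matrix <- function(thetas, groups, coverage = 500L,
                                  seed = 1L) {
  thetas <- as.matrix(thetas)
  stopifnot(all(names(groups) %in% colnames(thetas)))
  set.seed(seed %% 2147483647L)
  labels <- rep(names(groups), groups)
  lev <- matrix(NA_real_, nrow(thetas), length(labels))
  for (j in seq_along(labels)) {
    th <- thetas[, labels[j]]
    lev[, j] <- stats::rbinom(length(th), coverage, th) / coverage
  }
  rownames(lev) <- rownames(thetas)
  colnames(lev) <- sprintf("%s%d", labels, stats::ave(
    seq_along(labels), labels, FUN = seq_along))
  list(levels = lev, labels = labels, thetas = thetas)
}
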