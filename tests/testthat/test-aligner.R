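test_that("exact reads place on the precursor with no variants or tail", {
  ps <- make_preset()
  sq <- ps[["pre-1"]]$sequence
  aln <- align_to_precursors(reads_df(substr(sq, 6, 27)), ps)
  plc <- aln$placements
  expect_equal(nrow(plc), 1)
  expect_equal(plc$offset, 6L)
  expect_equal(plc$n_mm, 0L)
  expect_equal(plc$tail_len, 0L)
  expect_equal(nrow(aln$variants), 0)
})

test_that("a mismatching terminal base yields the 3'-site variant of the site taxonomy", {
  ps <- make_preset()
  sq <- ps[["pre-1"]]$sequence
  ref27 <- substr(sq, 27, 27)
  alt <- setdiff(c("A", "C", "G", "U"), ref27)[1]
  read <- paste0(substr(sq, 6, 26), alt)
  aln <- align_to_precursors(reads_df(read), ps)
  v <- aln$variants
  expect_equal(nrow(v), 1)
  expect_equal(v$target_pos, 27L)
  expect_equal(v$ref, ref27)
  expect_equal(v$alt, alt)
  expect_equal(v$read_pos, 22L)  # the last read base
})

test_that("a single internal mismatch is reported at its precursor position", {
  ps <- make_preset()
  sq <- ps[["pre-1"]]$sequence
  read <- substr(sq, 6, 27)
  ref14 <- substr(sq, 14, 14)
  alt <- setdiff(c("A", "C", "G", "U"), ref14)[1]
  substr(read, 9, 9) <- alt  # read position 9 = precursor position 14
  aln <- align_to_precursors(reads_df(read), ps)
  plc <- aln$placements
  expect_equal(plc$n_mm, 1L)
  expect_equal(plc$tail_len, 0L)
  v <- aln$variants
  expect_equal(v$target_pos, 14L)
  expect_equal(v$ref, ref14)
  expect_equal(v$alt, alt)
  expect_false(v$in_tail)
})

test_that("non-templated tails follow the maximal-templated-suffix rule", {
  ps <- make_preset()
  sq <- ps[["pre-1"]]$sequence
  # two trailing mismatching bases with a free mismatch budget: the body is
  # maximal, so the first one is absorbed as the internal mismatch and only
  # the second forms the tail; the reported sites are identical either way
  r28 <- substr(sq, 28, 28); r29 <- substr(sq, 29, 29)
  a28 <- setdiff(c("A", "C", "G", "U"), r28)[1]
  a29 <- setdiff(c("A", "C", "G", "U"), r29)[1]
  read <- paste0(substr(sq, 6, 27), a28, a29)
  aln <- align_to_precursors(reads_df(read), ps)
  expect_equal(aln$placements$tail_len, 1L)
  expect_equal(aln$placements$body_len, 23L)
  v <- aln$variants[order(aln$variants$target_pos)]
  expect_equal(v$target_pos, c(28L, 29L))
  expect_equal(v$in_tail, c(FALSE, TRUE))
  # with the budget spent on a true internal mismatch, both bases are tail
  read2 <- read
  ref14 <- substr(sq, 14, 14)
  substr(read2, 9, 9) <- setdiff(c("A", "C", "G", "U"), ref14)[1]
  aln2 <- align_to_precursors(reads_df(read2), ps)
  expect_equal(aln2$placements$tail_len, 2L)
  expect_equal(aln2$placements$n_mm, 1L)
  v2 <- aln2$variants[order(aln2$variants$target_pos)]
  expect_equal(v2$target_pos, c(14L, 28L, 29L))
  expect_equal(v2$in_tail, c(FALSE, TRUE, TRUE))
  # a read overhanging the precursor keeps only templated variant positions
  over <- paste0(substr(sq, 40, 60), "A", "A")
  alnov <- align_to_precursors(reads_df(over), ps)
  keep <- alnov$placements$offset == 40
  expect_true(any(keep))
  aid <- alnov$placements$aln_id[keep]
  expect_true(all(alnov$variants$target_pos[alnov$variants$aln_id %in% aid] <= 60))
})

test_that("genome alignment reports all loci with best-mismatch semantics", {
  set.seed(21)
  core <- paste(sample(c("A", "C", "G", "T"), 22, TRUE), collapse = "")
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  core_mut <- core
  substr(core_mut, 11, 11) <- setdiff(c("A", "C", "G", "T"),
                                      substr(core, 11, 11))[1]
  genome <- c(chrA = paste0(bg(50), core, bg(50), core, bg(30), core_mut,
                            bg(40)))
  g <- align_to_genome(reads_df(core), genome)
  # the exact duplications are reported, the 1-mismatch copy is not (best)
  expect_equal(nrow(g), 2)
  expect_equal(g$n_mm, c(0L, 0L))
  expect_equal(g$start, c(51L, 123L))
  # a read present only as the mutated copy maps there with 0 mm
  g2 <- align_to_genome(reads_df(core_mut), genome)
  expect_equal(nrow(g2), 1)
  expect_equal(g2$start, 175L)
})

test_that("genome alignment equals the exhaustive offset-by-offset oracle", {
  set.seed(77)
  chrs <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 2000, TRUE),
                         collapse = ""))
  reads <- character(0)
  for (i in 1:20) {  # planted reads, some mutated, some reverse-complement
    L <- sample(18:28, 1)
    o <- sample(2000 - L, 1)
    r <- substr(chrs[[1]], o, o + L - 1)
    if (i %% 3 == 0)
      substr(r, sample(L, 1), sample(L, 1)) <- sample(c("A", "C", "G", "T"), 1)
    if (i %% 4 == 0)
      r <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
    reads <- c(reads, r)
  }
  for (i in 1:10)  # random reads, mostly unmappable
    reads <- c(reads, paste(sample(c("A", "C", "G", "T"), 22, TRUE),
                            collapse = ""))
  rd <- reads_df(unique(reads))
  g <- align_to_genome(rd, chrs)
  for (ri in seq_len(nrow(rd))) {
    got <- g[g$read_id == ri, c("chrom", "start", "strand", "n_mm")]
    exp <- oracle_align_genome(rd$sequence[ri], chrs)
    expect_equal(nrow(got), nrow(exp), info = paste("read", ri))
    if (nrow(exp)) {
      o1 <- got[order(got$start, got$strand), ]
      o2 <- exp[order(exp$start, exp$strand), c("chrom", "start", "strand", "n_mm")]
      expect_equal(as.data.frame(o1), o2, ignore_attr = TRUE,
                   info = paste("read", ri))
    }
  }
})

test_that("decomposition is deterministic and respects the mismatch budget", {
  ps <- make_preset(seed = 31, len = 80, m5 = c(5L, 26L), m3 = c(50L, 71L))
  sq <- ps[["pre-1"]]$sequence
  set.seed(99)
  reads <- vapply(1:40, function(i) {
    o <- sample(1:50, 1); L <- sample(18:26, 1)
    r <- substr(sq, o, min(o + L - 1, 80))
    nmut <- sample(0:2, 1)
    for (k in seq_len(nmut)) {
      p <- sample(nchar(r), 1)
      substr(r, p, p) <- sample(c("A", "C", "G", "U"), 1)
    }
    r
  }, "")
  rd <- reads_df(unique(reads[nchar(reads) >= 18]))
  a1 <- align_to_precursors(rd, ps)
  a2 <- align_to_precursors(rd, ps)
  expect_equal(a1$placements, a2$placements)
  expect_equal(a1$variants, a2$variants)
  expect_true(all(a1$placements$n_mm <= 1))
  expect_true(all(a1$placements$tail_len <= 5))
  expect_true(all(a1$placements$body_len >= 16))
  # variants never report identical ref and alt
  expect_true(all(a1$variants$ref != a1$variants$alt))
})
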