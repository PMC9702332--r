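test_that("retention thresholds round to nearest with ties up and floor one", {
  expect_equal(min_sample_threshold(0.2, 5), 1L)
  expect_equal(min_sample_threshold(0.2, 2), 1L)   # floor
  expect_equal(min_sample_threshold(0.5, 5), 3L)   # ties round up
  expect_equal(min_sample_threshold(0.2, 13), 3L)  # 2.6 -> 3
  expect_equal(min_sample_threshold(0.2, 12), 2L)  # 2.4 -> 2
})

fake_calls_pair <- function() {
  # sample A carries the site; sample B covers the anchor (level 0) in one
  # variant and has no coverage in the other
  sites_a <- data.frame(precursor = "pre-1", position = 15L, ref = "A",
                        alt = "G", editing_level = 0.3, significant = TRUE,
                        stringsAsFactors = FALSE)
  cov_a <- data.frame(pre_id = "pre-1", position = 15L,
                      total_count = 100L, stringsAsFactors = FALSE)
  a <- make_calls(sites_a, cov_a)
  b_covered <- make_calls(sites_a[0, ], cov_a)
  b_uncovered <- make_calls(sites_a[0, ],
                            cov_a[0, , drop = FALSE])
  list(a = a, b_cov = b_covered, b_unc = b_uncovered)
}

test_that("merging distinguishes missing cells from covered-but-unedited zeros", {
  fx <- fake_calls_pair()
  agg <- merge_samples(list(s1 = fx$a, s2 = fx$b_cov))
  expect_equal(agg$levels[1, "s1"], 0.3, ignore_attr = TRUE)
  expect_equal(agg$levels[1, "s2"], 0, ignore_attr = TRUE)
  expect_equal(agg$sites$n_significant, 1L)
  agg2 <- merge_samples(list(s1 = fx$a, s2 = fx$b_unc))
  expect_true(is.na(agg2$levels[1, "s2"]))
  expect_equal(agg2$sites$max_level, 0.3)
})

test_that("conflicting reference nucleotides across samples raise a configuration error", {
  fx <- fake_calls_pair()
  bad <- fx$a
  bad$sites$ref <- "C"
  expect_error(merge_samples(list(s1 = fx$a, s2 = bad)), "conflicting")
})

test_that("retention keeps exactly the sites significant in enough samples", {
  set.seed(71)
  ns <- 52L
  mk <- function(nsig) {
    sig <- matrix(FALSE, 1, ns)
    sig[1, seq_len(nsig)] <- TRUE
    sig
  }
  sites <- data.frame(
    name = sprintf("pre-%d_10_A_g", 1:3), precursor = sprintf("pre-%d", 1:3),
    position = 10L, anchor = 10L, ref = "A", alt = "G", category = "A-to-I",
    n_significant = c(10L, 9L, 52L), max_level = 0.5,
    stringsAsFactors = FALSE)
  agg <- structure(list(
    sites = sites,
    levels = matrix(0.2, 3, ns, dimnames = list(sites$name, paste0("s", 1:ns))),
    significant = rbind(mk(10), mk(9), mk(52)), n_samples = ns),
    class = "site_aggregate")
  kept <- retention_filter(agg, 0.2)
  expect_equal(attr(kept, "threshold"), 10L)
  expect_setequal(kept$sites$name, sites$name[c(1, 3)])
  # raising the fraction never enlarges the retained set
  prev <- nrow(retention_filter(agg, 0.05)$sites)
  for (f in c(0.1, 0.2, 0.4, 0.8, 1)) {
    cur <- nrow(retention_filter(agg, f)$sites)
    expect_lte(cur, prev)
    prev <- cur
  }
})

snp_fixture <- function() {
  ps <- make_preset(seed = 72, start = 2001L)
  p <- ps[["pre-1"]]
  lv <- matrix(c(1, 0.4,
                 0.95, 0.6,
                 1, 1), nrow = 3, byrow = TRUE,
               dimnames = list(NULL, c("s1", "s2")))
  sites <- data.frame(
    precursor = "pre-1", position = c(10L, 12L, 14L),
    anchor = c(10L, 12L, 14L),
    ref = substring(p$sequence, c(10, 12, 14), c(10, 12, 14)),
    alt = NA_character_, category = "Other",
    n_significant = 2L, max_level = apply(lv, 1, max),
    stringsAsFactors = FALSE)
  sites$alt <- vapply(sites$ref, function(r)
    setdiff(c("A", "C", "G", "U"), r)[1], "")
  sites$name <- name_site(sites$precursor, sites$position, sites$ref,
                          sites$alt)
  agg <- structure(list(sites = sites, levels = lv,
                        significant = lv > 0, n_samples = 2L),
                   class = "site_aggregate")
  list(ps = ps, agg = agg, p = p)
}

test_that("SNP reclassification needs position, both alleles and a 100% level", {
  fx <- snp_fixture()
  p <- fx$p
  gpos <- vapply(c(10L, 12L, 14L), function(x)
    as.numeric(premir_to_genomic(p, x)), numeric(1))
  st <- fx$agg$sites
  rows <- data.frame(
    chromosome = p$chrom, position = gpos,
    ref = chartr("U", "T", st$ref),
    alt = c(chartr("U", "T", st$alt[1]),       # full match, level 1.0
            chartr("U", "T", st$alt[2]),       # level only 0.95
            setdiff(c("A", "C", "G", "T"),     # allele mismatch
                    chartr("U", "T", c(st$ref[3], st$alt[3])))[1]),
    id = c("rsA", "rsB", "rsC"), stringsAsFactors = FALSE)
  d <- withr::local_tempdir()
  tsv <- file.path(d, "snp.tsv")
  utils::write.table(rows, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  cat <- load_catalog(tsv, "snp")
  out <- snp_reclassify(fx$agg, cat, fx$ps)
  expect_equal(out$sites$category, c("SNP", "Other", "Other"))
  expect_equal(out$sites$snp_match, c("rsA", NA, NA))
  # order independence and idempotence
  cat2 <- load_catalog(tsv, "snp")
  cat2 <- cat2[rev(seq_len(nrow(cat2))), ]
  out2 <- snp_reclassify(snp_reclassify(fx$agg, cat2, fx$ps), cat2, fx$ps)
  expect_equal(out2$sites$category, out$sites$category)
})

test_that("minus-strand sites compare complemented alleles against the catalog", {
  ps <- make_preset(seed = 73, start = 501L, strand = "-")
  p <- ps[["pre-1"]]
  ref <- substr(p$sequence, 20, 20)
  alt <- setdiff(c("A", "C", "G", "U"), ref)[1]
  lv <- matrix(1, 1, 1, dimnames = list(NULL, "s1"))
  agg <- structure(list(
    sites = data.frame(name = name_site("pre-1", 20, ref, alt),
                       precursor = "pre-1", position = 20L, anchor = 20L,
                       ref = ref, alt = alt, category = "Other",
                       n_significant = 1L, max_level = 1,
                       stringsAsFactors = FALSE),
    levels = lv, significant = lv > 0, n_samples = 1L),
    class = "site_aggregate")
  comp <- function(x) chartr("ACGT", "TGCA", chartr("U", "T", x))
  rows <- data.frame(chromosome = p$chrom,
                     position = premir_to_genomic(p, 20L),
                     ref = comp(ref), alt = comp(alt), id = "rsM",
                     stringsAsFactors = FALSE)
  d <- withr::local_tempdir()
  tsv <- file.path(d, "m.tsv")
  utils::write.table(rows, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- snp_reclassify(agg, load_catalog(tsv, "snp"), ps)
  expect_equal(out$sites$category, "SNP")
  # the uncomplemented alleles must NOT match
  rows2 <- rows; rows2$ref <- chartr("U", "T", ref)
  rows2$alt <- chartr("U", "T", alt)
  if (rows2$ref != rows$ref) {
    tsv2 <- file.path(d, "m2.tsv")
    utils::write.table(rows2, tsv2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out2 <- snp_reclassify(agg, load_catalog(tsv2, "snp"), ps)
    expect_equal(out2$sites$category, "Other")
  }
})

test_that("cohort intersection reproduces constructed membership and directions", {
  mk <- function(names, case_lv, ctrl_lv) {
    lv <- cbind(case = case_lv, ctrl = ctrl_lv)
    rownames(lv) <- names
    a <- make_aggregate(lv)
    a$sites$name <- names
    a
  }
  a <- mk(c("s1", "s2", "s3"), c(0.5, 0.2, 0.4), c(0.1, 0.3, 0.4))
  b <- mk(c("s1", "s2"), c(0.6, 0.1), c(0.2, 0.4))
  c3 <- mk(c("s1", "s4"), c(0.3, 0.2), c(0.5, 0.1))
  out <- intersect_cohorts(list(A = a, B = b, C = c3),
                           group_labels = list(A = c("case", "ctrl"),
                                               B = c("case", "ctrl"),
                                               C = c("case", "ctrl")))
  expect_equal(out$common_sites, "s1")
  m <- out$membership
  expect_equal(m$A[m$name == "s3"], TRUE)
  expect_equal(m$B[m$name == "s3"], FALSE)
  expect_equal(sum(m$A), 3); expect_equal(sum(m$B), 2); expect_equal(sum(m$C), 2)
  expect_equal(out$directions$A, "up")
  expect_equal(out$directions$C, "down")
  # disjoint cohorts intersect empty
  d1 <- mk("x1", 0.1, 0.2); d2 <- mk("x2", 0.1, 0.2)
  expect_length(intersect_cohorts(list(A = d1, B = d2))$common_sites, 0)
})
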