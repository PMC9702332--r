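base_events <- function() {
  data.frame(
    precursor = c(1, 1, 2, 2),
    type = c("central", "three_prime", "five_prime", "central"),
    arm = c("5p", "5p", "5p", "3p"),
    offset = c(9, 1, 1, 5),
    ref = c("A", NA, "G", "C"),
    alt = c("G", "A", "C", "U"),
    theta = c(0.3, 0.4, 0.25, 0.2),
    germline = FALSE)
}

test_that("identical config and seed give identical references and reads", {
  cfg <- sim_config(n_precursors = 3, depth = 80, groups = c(g = 1),
                    events = base_events())
  r1 <- generate_reference(cfg, seed = 5)
  r2 <- generate_reference(cfg, seed = 5)
  expect_identical(vapply(r1$premirnas, `[[`, "", "sequence"),
                   vapply(r2$premirnas, `[[`, "", "sequence"))
  expect_identical(as.character(r1$genome), as.character(r2$genome))
  s1 <- simulate_sample(r1, "g", 1, master_seed = 3)
  s2 <- simulate_sample(r2, "g", 1, master_seed = 3)
  expect_identical(s1$reads, s2$reads)
  # written files are byte-identical across runs
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- generate_reference(cfg, seed = 5, dir = d1)$files
  f2 <- generate_reference(cfg, seed = 5, dir = d2)$files
  for (k in names(f1))
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]))
  # different sample indices draw from distinct streams
  s3 <- simulate_sample(r1, "g", 2, master_seed = 3)
  expect_false(identical(s1$reads$sequence, s3$reads$sequence))
})

test_that("with no events and no errors every read is a perfect mature insert", {
  cfg <- sim_config(n_precursors = 3, depth = 60, error_rate = 0,
                    groups = c(g = 1))
  ref <- generate_reference(cfg, seed = 8)
  s <- simulate_sample(ref, "g", 1, master_seed = 2)
  matures <- unlist(lapply(ref$premirnas, function(p)
    substring(p$sequence, p$matures$start, p$matures$end)))
  inserts <- sub(paste0(cfg$adapter, "$"), "", s$reads$sequence)
  expect_setequal(unique(chartr("T", "U", inserts)), unique(matures))
  expect_true(all(grepl(paste0(cfg$adapter, "$"), s$reads$sequence)))
})

test_that("realized editing fractions fall in the 99% binomial band", {
  cfg <- sim_config(n_precursors = 1, depth = 1000, arm_bias = 0.9,
                    error_rate = 0, groups = c(g = 1),
                    events = data.frame(precursor = 1, type = "central",
                                        arm = "5p", offset = 9, ref = "A",
                                        alt = "G", theta = 0.3,
                                        germline = FALSE))
  ref <- generate_reference(cfg, seed = 12)
  s <- simulate_sample(ref, "g", 1, master_seed = 4)
  tr <- s$truth[s$truth$type == "central", ]
  lo <- qbinom(0.005, tr$n_reads, 0.3)
  hi <- qbinom(0.995, tr$n_reads, 0.3)
  expect_gte(tr$n_edited, lo)
  expect_lte(tr$n_edited, hi)
})

test_that("germline variants appear in every read and in the SNP catalog", {
  cfg <- sim_config(n_precursors = 2, depth = 50, error_rate = 0,
                    groups = c(g = 1),
                    events = data.frame(precursor = 1, type = "central",
                                        arm = "5p", offset = 6, ref = "C",
                                        alt = "U", theta = 1,
                                        germline = TRUE))
  ref <- generate_reference(cfg, seed = 13)
  s <- simulate_sample(ref, "g", 1, master_seed = 6)
  tr <- s$truth
  expect_equal(tr$n_edited, tr$n_reads)
  expect_equal(nrow(ref$snp_catalog), 1)
  ev <- ref$events
  p <- ref$premirnas[[ev$precursor]]
  expect_equal(ref$snp_catalog$position, premir_to_genomic(p, ev$position))
})

test_that("an exact paralog duplicates the precursor locus in the genome", {
  cfg1 <- sim_config(n_precursors = 2, groups = c(g = 1),
                     allow_minus_strand = FALSE)
  ref1 <- generate_reference(cfg1, seed = 14)
  cfg2 <- sim_config(n_precursors = 2, groups = c(g = 1),
                     allow_minus_strand = FALSE,
                     paralogs = data.frame(source = 1, mode = "exact",
                                           depth_ratio = NA))
  ref2 <- generate_reference(cfg2, seed = 14)
  seg <- Biostrings::DNAString(chartr("U", "T",
    ref2$premirnas[["sim-mir-1"]]$sequence))
  n1 <- length(Biostrings::matchPattern(
    Biostrings::DNAString(chartr("U", "T",
      ref1$premirnas[["sim-mir-1"]]$sequence)),
    ref1$genome[[1]]))
  n2 <- length(Biostrings::matchPattern(seg, ref2$genome[[1]]))
  expect_equal(n1, 1)
  expect_equal(n2, 2)
  expect_equal(nrow(ref2$paralog_loci), 1)
})

test_that("background 5' additions realize the configured C-biased composition", {
  comp <- c(C = 0.7, A = 0.1, G = 0.1, U = 0.1)
  cfg <- sim_config(n_precursors = 4, depth = 600, error_rate = 0,
                    groups = c(g = 1), five_prime_rate = 0.4,
                    five_prime_composition = comp)
  ref <- generate_reference(cfg, seed = 15)
  s <- simulate_sample(ref, "g", 1, master_seed = 9)
  tab <- s$additions$five_prime
  n <- sum(tab)
  expect_gt(n, 500)
  got <- as.numeric(tab[names(comp)]) / n
  got[is.na(got)] <- 0
  # within ~4 sd of multinomial sampling noise
  tol <- 4 * sqrt(comp * (1 - comp) / n)
  expect_true(all(abs(got - comp) < pmax(tol, 0.02)))
})

test_that("call evaluation counts undercovered injected events as misses", {
  truth <- data.frame(precursor = "p", position = c(10L, 20L),
                      ref = "A", alt = "G", type = "central",
                      expected_category = "A-to-I", germline = FALSE,
                      theta = 0.3, n_reads = c(100L, 5L),
                      n_edited = c(30L, 2L), stringsAsFactors = FALSE)
  called <- data.frame(precursor = "p", position = 10L, ref = "A",
                       alt = "G", category = "A-to-I",
                       editing_level = 0.31, significant = TRUE,
                       stringsAsFactors = FALSE)
  ev <- evaluate_calls(truth, called)
  expect_equal(ev$tp, 1)
  expect_equal(ev$fn, 1)  # the low-coverage event is a miss, never an FP
  expect_equal(ev$fp, 0)
  expect_equal(ev$rmse, 0.01, tolerance = 1e-9)
  # perfect calls on both -> no misses
  called2 <- rbind(called, data.frame(
    precursor = "p", position = 20L, ref = "A", alt = "G",
    category = "A-to-I", editing_level = 0.4, significant = TRUE,
    stringsAsFactors = FALSE))
  ev2 <- evaluate_calls(truth, called2)
  expect_equal(ev2$fn, 0)
  expect_equal(ev2$fp, 0)
})
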