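test_that("GLI-likeness requires the CCxC frame in either orientation", {
  expect_true(is_gli_like("AGACCACCCAAA"))
  expect_true(is_gli_like("TTTGGGTGGTCT"))  # reverse complement orientation
  expect_false(is_gli_like("AAAAAAAAAAAA"))
  expect_false(is_gli_like("AGAGGACCCAAA"))
  expect_error(is_gli_like("ACGT"), "12")
  expect_identical(is_gli_like(default_gbm_words()),
                   rep(TRUE, length(default_gbm_words())))
})

test_that("confidence tiers are exhaustive and deterministic over presence size", {
  expect_identical(classify_confidence(c("LD", "CD", "MB", "NP")), "HC")
  expect_identical(classify_confidence(c("LD", "NP")), "MC")
  expect_identical(classify_confidence(c("LD", "CD", "MB")), "MC")
  expect_identical(classify_confidence("NP"), "LC")
  expect_error(classify_confidence(character(0)), "at least one")
  expect_error(classify_confidence(c("a", "b", "c", "d", "e")), "exceeds")
  for (n in 1:4) {
    tier <- classify_confidence(letters[1:n], n_datasets = 4)
    expect_identical(tier, c("LC", "MC", "MC", "HC")[n])
  }
})

test_that("library canonicalizes words and merges presence across orientations", {
  lib <- motif_library(c("AGACCACCCAAA", "TTTGGGTGGTCT"),
                       presence = list("LD", "NP"))
  expect_identical(nrow(lib), 1L)
  expect_identical(lib$word, "AGACCACCCAAA")
  expect_identical(lib$tier, "MC")
  expect_identical(lib$datasets, "LD,NP")
  expect_error(motif_library("AGACCACCCAANA"), "12")
})

test_that("enriched-word discovery matches the Fisher exact oracle", {
  set.seed(23)
  word <- "GACCACCCAAGT"
  pos <- vapply(rand_seq(50, 60), function(s) {
    p <- sample(nchar(s) - 12L, 1); substr(s, p, p + 11L) <- word; s
  }, character(1), USE.NAMES = FALSE)
  neg <- rand_seq(50, 60)
  found <- discover_enriched_words(pos, neg, word_length = 12)
  expect_identical(found$word[1], canonical_kmer(word))
  expect_identical(found$n_pos[1], 50L)
  # p agrees with fisher.test on the same 2x2 table
  ft <- fisher.test(matrix(c(found$n_pos[1], 50 - found$n_pos[1],
                             found$n_neg[1], 50 - found$n_neg[1]), 2,
                           byrow = TRUE), alternative = "greater")
  expect_equal(found$p[1], ft$p.value, tolerance = 1e-12)

  # no enrichment when the sets coincide
  expect_identical(nrow(discover_enriched_words(pos, pos, word_length = 12)), 0L)
  expect_error(discover_enriched_words(pos, neg, word_length = 2), ">= 3")
})

test_that("a 1-of-50 vs 0-of-50 word fails the 0.05 threshold (Fisher p = 0.5)", {
  base <- strrep("A", 30)
  pos <- c(paste0(base, "GACCACCCAAGT", base), rep(strrep("T", 72), 49))
  neg <- rep(strrep("G", 72), 50)
  found <- discover_enriched_words(pos, neg, word_length = 12, alpha = 0.05)
  expect_false(canonical_kmer("GACCACCCAAGT") %in% found$word)
})

test_that("iterative construction reaches a fixed point and recovers implanted words", {
  set.seed(41)
  seedw <- "AGACCACCCAAA"
  # all sequences contain the seed: library is exactly the seed, 1 iteration
  all_seed <- vapply(rand_seq(30, 80), function(s) {
    substr(s, 20, 31) <- seedw; s
  }, character(1), USE.NAMES = FALSE)
  lib <- iterative_library_build(list(D1 = all_seed), seed_words = seedw)
  expect_identical(lib$word, canonical_kmer(seedw))
  expect_identical(lib$tier, "HC")  # present in all (here: the only) datasets

  # two disjoint GLI-like words, each in half the sequences, both recovered
  w1 <- "AGACCACCCATT"; w2 <- "CTACCACCCAGA"
  half1 <- vapply(rand_seq(40, 80), function(s) {
    substr(s, 10, 21) <- w1; s
  }, character(1), USE.NAMES = FALSE)
  half2 <- vapply(rand_seq(40, 80), function(s) {
    substr(s, 50, 61) <- w2; s
  }, character(1), USE.NAMES = FALSE)
  lib2 <- iterative_library_build(list(D1 = c(half1, half2)))
  expect_true(all(canonical_kmer(c(w1, w2)) %in% lib2$word))

  # no GLI-like word present: only seed words actually present survive
  lib3 <- iterative_library_build(list(D1 = rand_seq(30, 80)),
                                  seed_words = seedw)
  expect_identical(nrow(lib3), 0L)
})

test_that("presence bookkeeping across datasets drives the tiers", {
  set.seed(43)
  w <- "AGACCACCCAAA"
  with_w <- function(n) vapply(rand_seq(n, 60), function(s) {
    substr(s, 15, 26) <- w; s
  }, character(1), USE.NAMES = FALSE)
  datasets <- list(LD = with_w(20), CD = with_w(20),
                   MB = rand_seq(20, 60), NP = rand_seq(20, 60))
  lib <- iterative_library_build(datasets, seed_words = w)
  row <- lib[lib$word == canonical_kmer(w), ]
  expect_identical(row$tier, "MC")
  expect_identical(row$datasets, "CD,LD")
})

test_that("build_pwm computes pseudocount-adjusted frequencies", {
  p <- build_pwm(c("AG", "TG"), pseudocount = 0)
  expect_equal(p$freqs[, 1], c(A = 0.5, C = 0, G = 0, T = 0.5))
  expect_equal(p$freqs[, 2], c(A = 0, C = 0, G = 1, T = 0))

  p1 <- build_pwm("CA", pseudocount = 0)
  expect_equal(unname(p1$freqs[, 1]), c(0, 1, 0, 0))

  p2 <- build_pwm("A", pseudocount = 1)
  expect_equal(p2$freqs[, 1], c(A = 0.4, C = 0.2, G = 0.2, T = 0.2))

  expect_error(build_pwm(c("AG", "AGG")), "equal length")
  expect_true(all(abs(colSums(build_pwm(c("ACGT", "AAAA"), 0.01)$freqs) - 1)
                  < 1e-9))
})

test_that("matrix similarity is 1 at consensus, 0 at the per-column worst", {
  pwm <- build_pwm(c("AGAC", "AGAC", "AGGC", "ATAC"), pseudocount = 0.01)
  consensus <- "AGAC"
  expect_equal(matrix_similarity(pwm, consensus), 1.0)
  worst <- paste(apply(pwm$freqs, 2, function(f) names(which.min(f))[1]),
                 collapse = "")
  expect_equal(matrix_similarity(pwm, worst), 0.0)
  expect_error(matrix_similarity(pwm, "AG"), "length")
  expect_error(matrix_similarity(pwm, "AGNN"), "N")

  # uninformative column contributes equally to Max and Min: hand-built case
  pwm2 <- build_pwm(c(rep("AG", 7), "CG", "GG", "TG"), pseudocount = 0)
  expect_equal(matrix_similarity(pwm2, "CG"), 0.0)
  expect_equal(matrix_similarity(pwm2, "AG"), 1.0)
})

test_that("genome GBM scan equals the naive substring oracle", {
  lib <- toy_library()
  g <- c(chr1 = strrep("A", 1000))
  substr(g[["chr1"]], 501, 512) <- "AGACCACCCAAA"
  m <- scan_genome_for_gbm(g, lib)
  expect_identical(m$start, 500L)
  expect_identical(m$end, 512L)
  expect_identical(m$strand, "+")

  g2 <- c(chr1 = strrep("A", 1000))
  substr(g2[["chr1"]], 501, 512) <- "TTTGGGTGGTCT"
  m2 <- scan_genome_for_gbm(g2, lib)
  expect_identical(m2$start, 500L)
  expect_identical(m2$strand, "-")
  expect_identical(m2$name, "AGACCACCCAAA")

  set.seed(61)
  words <- canonical_kmer(c(default_gbm_words(), rand_seq(16, 12)))
  lib3 <- motif_library(words)
  g3 <- c(c1 = paste(sample(c("A", "C", "G", "T"), 20000, TRUE),
                     collapse = ""),
          c2 = paste(sample(c("A", "C", "G", "T"), 5000, TRUE),
                     collapse = ""))
  got <- scan_genome_for_gbm(g3, lib3)
  want <- naive_gbm_scan(g3, lib3$word)
  expect_identical(nrow(got), nrow(want))
  expect_identical(got$start, want$start)
  expect_identical(got$strand, want$strand)
  expect_identical(got$name, want$name)
})

test_that("N in the genome blocks matches", {
  lib <- toy_library()
  g <- c(chr1 = paste0(strrep("A", 100), "AGACCNCCCAAA", strrep("A", 100)))
  expect_identical(nrow(scan_genome_for_gbm(g, lib)), 0L)
})

test_that("GKO mutates the invariant core C and removes matches on rescan", {
  lib <- toy_library()
  expect_identical(
    gko_mutate("AGACCACCCAAA",
               tibble::tibble(start = 0L, strand = "+",
                              word = "AGACCACCCAAA")),
    "AGACCAGCCAAA")

  # two disjoint matches, both cores mutated; rescan finds none
  s <- paste0("TT", "AGACCACCCAAA", strrep("T", 20), "TTTGGGTGGTCT", "TT")
  m <- scan_sequences_for_gbm(s, lib)
  expect_identical(nrow(m), 2L)
  mut <- gko_mutate(s, m)
  expect_identical(nrow(scan_sequences_for_gbm(mut, lib)), 0L)
  expect_identical(nchar(mut), nchar(s))

  # frame inconsistency: core position altered before the call
  bad <- s
  substr(bad, 9, 9) <- "T"
  expect_error(gko_mutate(bad, m), "inconsistency")
})

test_that("library TSV and match BED exports round-trip", {
  lib <- motif_library(default_gbm_words(),
                       presence = list("LD", c("LD", "NP"),
                                       c("LD", "CD", "MB", "NP"), "MB"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_motif_library(lib, f)
  back <- read_motif_library(f)
  expect_equal(as.data.frame(back), as.data.frame(lib))

  g <- c(chr1 = strrep("A", 1000))
  substr(g[["chr1"]], 101, 112) <- "AGACCACCCAAA"
  m <- scan_genome_for_gbm(g, lib)
  fb <- withr::local_tempfile(fileext = ".bed")
  write_gbm_matches_bed(m, fb)
  bed <- read_bed(fb)
  expect_identical(bed$start, m$start)
  expect_identical(bed$name, m$name)
})
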