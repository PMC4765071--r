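test_that("GC-matched background honors tolerance, exclusion and determinism", {
  g <- generate_genome(200000, gc = 0.45, seed = 3)
  gp <- generate_positive_peaks(g, default_grammar(), 40, seed = 4)
  bg <- sample_gc_matched_background(gp$genome, gp$peaks, gc_tol = 0.02,
                                     seed = 5)
  expect_identical(nrow(bg$regions), 40L)
  pos_gc <- gc_content(region_sequence(gp$genome, gp$peaks))
  expect_true(all(abs(bg$regions$gc - pos_gc[bg$regions$matched_to]) <= 0.02))
  expect_false(any(overlaps_any(bg$regions, gp$peaks)))
  expect_identical(bg$regions$end - bg$regions$start,
                   gp$peaks$end[bg$regions$matched_to] -
                     gp$peaks$start[bg$regions$matched_to])

  bg2 <- sample_gc_matched_background(gp$genome, gp$peaks, gc_tol = 0.02,
                                      seed = 5)
  expect_identical(bg$regions, bg2$regions)

  bg3 <- sample_gc_matched_background(gp$genome, gp$peaks[1:5, ],
                                      n_per_positive = 3, seed = 6)
  expect_identical(nrow(bg3$regions), 15L)

  # unsatisfiable matching errors out naming the positive: a lone GC-rich
  # island in an AT genome has no GC match elsewhere
  g_at <- c(chr1 = paste0(strrep("AT", 2000), strrep("G", 100),
                          strrep("AT", 2000)))
  island <- regions_tbl("chr1", 4000, 4100)
  expect_error(
    sample_gc_matched_background(g_at, island, gc_tol = 0.1, seed = 7,
                                 max_attempts = 50),
    "positive region")
})

test_that("windows are centered on the GBM midpoint and edge windows dropped", {
  g <- c(chr1 = strrep("A", 5000))
  m <- tibble::tibble(contig = "chr1", start = 1000L, end = 1012L,
                      strand = "+", name = "AGACCACCCAAA", tier = "HC")
  w <- extract_window(m, g)
  expect_identical(w$start, 706L)
  expect_identical(w$end, 1306L)

  m2 <- m; m2$start <- 10L; m2$end <- 22L
  expect_identical(nrow(extract_window(m2, g)), 0L)
  m3 <- m; m3$start <- 4995L - 12L; m3$end <- 4995L
  expect_identical(nrow(extract_window(m3, g)), 0L)

  set.seed(8)
  starts <- sample(300:4000, 50)
  mm <- tibble::tibble(contig = "chr1", start = starts, end = starts + 12L,
                       strand = "+", name = "w", tier = "LC")
  ww <- extract_window(mm, g)
  expect_true(all(ww$end - ww$start == 600L))
  expect_true(all(abs((ww$start + 300L) - (ww$gbm_start + 6L)) == 0))
})

test_that("scan_and_score reports per-model scores consistent with score_sequences", {
  set.seed(9)
  g <- generate_genome(100000, seed = 10)
  gp <- generate_positive_peaks(g, default_grammar(), 10, seed = 11)
  lib <- motif_library(default_gbm_words())
  m_zero <- toy_model(bias = -1)
  m_gbm <- toy_model(weights = c(GACCACCC = 1), bias = -0.5)
  scored <- scan_and_score(gp$genome, lib, list(zero = m_zero, gbm = m_gbm))
  expect_gt(nrow(scored), 0)
  expect_true(all(scored$call_zero == "negative"))
  expect_equal(scored$score_zero, rep(-1, nrow(scored)))
  seqs <- region_sequence(gp$genome, scored)
  expect_equal(scored$score_gbm, score_sequences(m_gbm, seqs))
  expect_true(all(scored$call_gbm[scored$score_gbm > 0] == "positive"))
  # windows sorted
  expect_identical(scored$start, sort(scored$start))
})

test_that("positive-call fraction is monotone non-increasing in the bias", {
  set.seed(12)
  g <- generate_genome(100000, seed = 13)
  gp <- generate_positive_peaks(g, default_grammar(), 15, seed = 14)
  lib <- motif_library(default_gbm_words())
  fractions <- vapply(c(-2, -1, 0, 1, 2), function(b) {
    m <- toy_model(weights = c(GACCACCC = 1), bias = -b)
    sc <- scan_and_score(gp$genome, lib, list(m = m))
    mean(sc$call_m == "positive")
  }, numeric(1))
  expect_true(all(diff(fractions) <= 0))
})

test_that("classifier correlation handles subsets, edge cases and the closed form", {
  sc <- tibble::tibble(score_a = c(1, 2, 3), score_b = c(2, 4, 7))
  expect_equal(classifier_correlation(sc, "a", "b"), 5 / sqrt(2 * 114 / 9),
               tolerance = 1e-12)
  expect_equal(round(classifier_correlation(sc, "a", "b"), 4), 0.9934)

  sc2 <- tibble::tibble(score_a = c(-1, 0.5, 2, 3), score_b = c(-1, 0.5, 2, 3))
  expect_equal(classifier_correlation(sc2, "a", "b"), 1.0)
  sc3 <- tibble::tibble(score_a = c(-1, 0.5, 2, 3),
                        score_b = -c(-1, 0.5, 2, 3))
  expect_equal(classifier_correlation(sc3, "a", "b"), -1.0)

  # nested subsets: high confidence within positive within all
  set.seed(15)
  sc4 <- tibble::tibble(score_a = rnorm(200, 0.5), score_b = rnorm(200, 0.5))
  n_all <- sum(rep(TRUE, 200))
  n_pos <- sum(sc4$score_a > 0 & sc4$score_b > 0)
  n_hc <- sum(sc4$score_a >= 1 & sc4$score_b >= 1)
  expect_true(n_hc <= n_pos && n_pos <= n_all)

  expect_error(classifier_correlation(sc[1:2, ], "a", "b"), "fewer than 3")
  sc5 <- tibble::tibble(score_a = rep(1, 5), score_b = 1:5)
  expect_error(classifier_correlation(sc5, "a", "b"), "variance")
  expect_error(classifier_correlation(sc, "a", "missing"), "not found")
})

test_that("weight profiles localize weights and sum to score minus bias", {
  m <- toy_model(weights = c(GACCACCC = 2), bias = -1)
  s <- paste0(strrep("A", 5), "GACCACCC", strrep("T", 10))
  pr <- weight_profile(m, s)
  expect_identical(nrow(pr), nchar(s) - 8L + 1L)
  expect_equal(pr$weight[pr$offset == 5], 2)
  expect_equal(sum(pr$weight != 0), 1)
  expect_equal(sum(pr$weight), score_sequences(m, s) - m$bias)

  set.seed(16)
  model <- toy_model(weights = c(GACCACCC = 1.5, TTTTACGT = -2), bias = 0.3)
  for (sq in rand_seq(20, 50)) {
    pr <- weight_profile(model, sq)
    expect_equal(sum(pr$weight), score_sequences(model, sq) - model$bias)
    # reverse complement mirrors the profile
    pr_rc <- weight_profile(model, revcomp(sq))
    expect_equal(pr_rc$weight, rev(pr$weight))
  }

  # N windows contribute zero
  pr_n <- weight_profile(m, paste0("GACCACCC", "N", "GACCACCC"))
  expect_equal(pr_n$weight, c(2, rep(0, 8), 2))
})

test_that("profiles export to bedGraph with merged runs", {
  m <- toy_model(weights = c(GACCACCC = 2), bias = 0)
  s <- paste0(strrep("A", 5), "GACCACCC", strrep("T", 10))
  pr <- weight_profile(m, s)
  f <- withr::local_tempfile(fileext = ".bedGraph")
  profile_to_bedgraph(pr, "chr1", 1000L, f)
  bg <- read_bedgraph(f)
  expect_identical(bg$start[1], 1000L)
  expect_equal(sum((bg$end - bg$start) * bg$value), sum(pr$weight))
  expect_true(all(bg$start[-1] >= bg$end[-nrow(bg)]))
})

test_that("scored windows export as a readable BED6+ table", {
  g <- c(chr1 = strrep("A", 2000))
  substr(g[["chr1"]], 1001, 1012) <- "AGACCACCCAAA"
  lib <- motif_library(default_gbm_words())
  m <- toy_model(weights = c(GACCACCC = 1), bias = -0.5,
                 platt_a = -1, platt_b = 0)
  scored <- scan_and_score(g, lib, list(ld = m))
  f <- withr::local_tempfile(fileext = ".tsv")
  export_scored_windows(scored, f)
  back <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_identical(nrow(back), nrow(scored))
  expect_equal(back$score_ld, scored$score_ld)
  expect_true(all(c("posterior_ld", "call_ld") %in% names(back)))
})
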