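test_that("generated genomes hit the target GC and are seed-reproducible", {
  g <- generate_genome(100000, gc = 0.42, seed = 7)
  expect_identical(nchar(g[[1]]), 100000L)
  expect_lt(abs(gc_content(g[[1]]) - 0.42), 0.01)
  expect_identical(g, generate_genome(100000, gc = 0.42, seed = 7))
  expect_false(identical(g, generate_genome(100000, gc = 0.42, seed = 8)))
  expect_error(generate_genome(100000, gc = 1.0), "gc")
  expect_error(generate_genome(100000, gc = 0), "gc")
  expect_error(generate_genome(10, gc = 0.4), "length")
})

test_that("positive peaks carry retrievable implants at truth coordinates", {
  g <- generate_genome(300000, seed = 17)
  gp <- generate_positive_peaks(g, default_grammar(), 60, seed = 18)
  expect_identical(nrow(gp$peaks), 60L)
  # non-overlapping peaks
  srt <- sort_regions(gp$peaks)
  expect_true(all(srt$start[-1] >= srt$end[-nrow(srt)]))
  # every truth implant is retrievable from the genome on its strand
  got <- region_sequence(gp$genome, gp$truth)
  expect_identical(got, gp$truth$word)
  # every truth GBM rescans to a library match at the same position
  lib <- motif_library(default_gbm_words())
  matches <- scan_genome_for_gbm(gp$genome, lib)
  gbm_truth <- gp$truth[gp$truth$type == "gbm", ]
  expect_true(all(gbm_truth$start %in% matches$start))
  # refusal when the genome cannot host the request
  expect_error(generate_positive_peaks(generate_genome(5000, seed = 1),
                                       default_grammar(), 50, seed = 2),
               "cannot place")
})

test_that("single-GBM fraction tracks p_single_gbm at the default 0.88", {
  g <- generate_genome(2500000, seed = 27)
  gp <- generate_positive_peaks(g, default_grammar(), 1000, seed = 28)
  per_peak <- table(gp$truth$peak[gp$truth$type == "gbm"])
  frac_single <- mean(per_peak == 1)
  expect_lt(abs(frac_single - 0.88), 0.03)
})

test_that("cofactor implants sit near the configured midpoint offset", {
  g <- generate_genome(1000000, seed = 37)
  gp <- generate_positive_peaks(g, default_grammar(), 300, seed = 38)
  seqs <- region_sequence(gp$genome, gp$peaks)
  pr <- motif_positional_profile(seqs, unname(default_grammar()$cofactor_words),
                                 bin_width = 40)
  # symmetric two-sided placement: fold to absolute offsets
  folded <- tapply(pr$count, abs(pr$bin_center), sum)
  mode_offset <- as.numeric(names(which.max(folded)))
  expect_lte(abs(mode_offset - 200), 40)
})

test_that("multi-dataset studies reproduce their sharing design exactly", {
  design <- c("LD+CD+MB+NP" = 26L, "LD" = 10L, "CD+NP" = 5L)
  st <- generate_multidataset_study(default_grammar(), design, seed = 5)
  expect_identical(sort(names(st$datasets)), c("CD", "LD", "MB", "NP"))
  v <- venn_overlap(st$datasets)
  got <- setNames(v$count, v$subset)
  expect_identical(got[["CD+LD+MB+NP"]], 26L)
  expect_identical(got[["LD"]], 10L)
  expect_identical(got[["CD+NP"]], 5L)
  expect_identical(sum(v$count), 41L)

  # empty design gives an empty study
  st0 <- generate_multidataset_study(default_grammar(),
                                     c("LD" = 0L, "NP" = 0L), seed = 5)
  expect_true(all(vapply(st0$datasets, nrow, integer(1)) == 0L))

  # renaming datasets permutes the outputs consistently
  design_b <- c("A+B+C+D" = 26L, "A" = 10L, "B+D" = 5L)
  st_b <- generate_multidataset_study(default_grammar(), design_b, seed = 5)
  mapping <- c(A = "LD", B = "CD", C = "MB", D = "NP")
  for (nm in names(mapping)) {
    expect_identical(nrow(st_b$datasets[[nm]]),
                     nrow(st$datasets[[mapping[[nm]]]]))
  }
})

test_that("feature tracks cover enhancers and background at their probabilities", {
  g <- generate_genome(500000, seed = 47)
  gp <- generate_positive_peaks(g, default_grammar(), 50, seed = 48)
  tr <- generate_feature_track(gp$peaks, p_enh = 1, p_bg = 0, seed = 49)
  expect_identical(sort(tr$regions$start), sort(gp$peaks$start))
  expect_true(all(overlaps_any(gp$peaks, tr)))

  tr2 <- generate_feature_track(gp$peaks, p_enh = 1, p_bg = 0, seed = 49)
  expect_identical(tr$regions, tr2$regions)

  bg <- sample_gc_matched_background(gp$genome, gp$peaks, seed = 50)
  set.seed(51)
  tr3 <- generate_feature_track(gp$peaks, p_enh = 0.8,
                                background_regions = bg$regions, p_bg = 0.3,
                                seed = 52)
  p_hit_pos <- mean(overlaps_any(gp$peaks, tr3))
  p_hit_neg <- mean(overlaps_any(bg$regions, tr3))
  expect_gt(p_hit_pos, p_hit_neg)
})

test_that("trained classifiers recover implanted enhancers on a fresh genome", {
  study <- make_training_study(seed = 57, n_pos = 150,
                               genome_length = 400000L)
  model <- train_kmer_svm(study$positives, study$negatives, seed = 58)
  # fresh genome carrying implanted enhancers plus bare GBM decoys (motif
  # word only, none of the surrounding grammar)
  g2 <- generate_genome(300000, seed = 59)
  gp2 <- generate_positive_peaks(g2, default_grammar(), 40, seed = 60)
  set.seed(61)
  words <- default_gbm_words()
  decoy <- NULL
  placed <- 0L; tries <- 0L
  while (placed < 40L && tries < 5000L) {
    tries <- tries + 1L
    st <- sample.int(300000L - 612L, 1L) + 300L
    cand <- regions_tbl("chrS", st, st + 12L)
    if (any(overlaps_any(cand, gp2$peaks))) next
    if (!is.null(decoy) && any(overlaps_any(cand, decoy))) next
    cand$strand <- sample(c("+", "-"), 1L)
    cand$word <- sample(words, 1L)
    decoy <- rbind(decoy, cand)
    placed <- placed + 1L
  }
  genome <- gliscan:::apply_implants(
    gp2$genome, tibble::tibble(contig = "chrS", start = decoy$start,
                               end = decoy$end, strand = decoy$strand,
                               word = decoy$word))
  lib <- motif_library(default_gbm_words())
  scored <- scan_and_score(genome, lib, list(m = model))
  is_enh <- overlaps_any(scored, gp2$peaks)
  expect_gt(sum(is_enh), 35)          # nearly all enhancer GBMs windowed
  expect_gt(sum(!is_enh), 35)         # decoys present as the contrast class
  # every enhancer window is called positive, and the full-grammar windows
  # outscore the bare-motif decoys
  expect_gte(mean(scored$score_m[is_enh] > 0), 0.95)
  expect_gt(mean(scored$score_m[is_enh]), mean(scored$score_m[!is_enh]))
  expect_gt(roc_auc(scored$score_m, is_enh), 0.5)
  # against motif-free background sequence the discrimination is sharp
  set.seed(62)
  bg_scores <- score_sequences(model, rand_seq(100, 600, gc = 0.42))
  auc_bg <- roc_auc(c(scored$score_m[is_enh], bg_scores),
                    c(rep(TRUE, sum(is_enh)), rep(FALSE, 100)))
  expect_gte(auc_bg, 0.9)
})
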