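#!/usr/bin/env Rscript
# Stage 4 — genome-wide prediction.
#
# Builds an evaluation genome carrying 150 implanted enhancers plus 150
# bare GBM decoy sites, finds every genomic GBM, extracts the 600 bp window
# centered on each, and scores the windows with two classifiers: the stage-3
# model and an independent model trained on a second synthetic study.
# Writes the scored-window table (BED6+) and the inter-classifier score
# correlations over all / positive-only / high-confidence windows.

suppressPackageStartupMessages({library(gliscan); library(tibble)})

seed <- 1L
out <- "results/scan"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

model_a <- read_kmer_model("results/model/kmer_model.tsv")
message("Training the comparison classifier on an independent study ...")
study_b <- make_training_study(seed = seed + 1000L, n_pos = 500L,
                               genome_length = 1200000L)
model_b <- train_kmer_svm(study_b$positives, study_b$negatives,
                          seed = seed + 1000L)

message("Building the evaluation genome (150 enhancers + 150 decoys) ...")
grammar <- default_grammar()
genome <- generate_genome(1000000L, gc = grammar$gc, seed = seed + 2001L)
gp <- generate_positive_peaks(genome, grammar, 150L, seed = seed + 2002L)
set.seed(seed + 2000L)
decoy <- NULL
while (is.null(decoy) || nrow(decoy) < 150L) {
  st <- sample.int(1000000L - 612L, 1L) + 300L
  cand <- regions_tbl(names(genome), st, st + 12L)
  if (any(overlaps_any(cand, gp$peaks))) next
  if (!is.null(decoy) && any(overlaps_any(cand, decoy))) next
  cand$strand <- sample(c("+", "-"), 1L)
  cand$word <- sample(grammar$gbm_words, 1L)
  decoy <- rbind(decoy, cand)
}
genome_eval <- gliscan:::apply_implants(
  gp$genome, tibble(contig = decoy$contig, start = decoy$start,
                    end = decoy$end, strand = decoy$strand,
                    word = decoy$word))

lib <- motif_library(grammar$gbm_words)
scored <- scan_and_score(genome_eval, lib, list(a = model_a, b = model_b))
export_scored_windows(scored, file.path(out, "scored_windows.tsv"))
write_bed(gp$peaks, file.path(out, "true_enhancers.bed"))
write_gbm_matches_bed(scan_genome_for_gbm(genome_eval, lib),
                      file.path(out, "gbm_matches.bed"))

message(sprintf("  %d windows scored; %.1f%% positive under classifier A",
                nrow(scored), 100 * mean(scored$score_a > 0)))
message(sprintf("  score range A: %.2f .. %.2f", min(scored$score_a),
                max(scored$score_a)))
corrs <- data.frame(
  subset = c("all", "positive_only", "high_confidence"),
  pearson_r = vapply(c("all", "positive_only", "high_confidence"),
                     function(ss) classifier_correlation(scored, "a", "b", ss),
                     numeric(1)))
write.table(corrs, file.path(out, "classifier_correlations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("  Pearson r (all / positive / high-confidence): %.2f / %.2f / %.2f",
                corrs$pearson_r[1], corrs$pearson_r[2], corrs$pearson_r[3]))
message("Wrote scored windows and correlations under ", out)
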