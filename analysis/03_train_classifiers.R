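#!/usr/bin/env Rscript
# Stage 3 — train and evaluate the canonical 8-mer spectrum SVM.
#
# Reads the positive and GC-matched negative sequences from stage 1, runs
# the repeated stratified 80/20 holdout (five repeats: per-repeat ROC and
# PRC curves and areas), then trains the final classifier on all data,
# calibrates its posterior and writes the per-k-mer weight model.

suppressPackageStartupMessages(library(gliscan))

seed <- 1L
out <- "results/model"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

positives <- unname(read_fasta("results/study/positives.fa"))
negatives <- unname(read_fasta("results/study/negatives.fa"))
message("Loaded ", length(positives), " positives / ", length(negatives),
        " negatives")

message("Repeated 80/20 holdout (5 repeats) ...")
ev <- evaluate_repeated_holdout(positives, negatives, n_repeats = 5L,
                                seed = seed)
write.csv(ev$per_repeat, file.path(out, "holdout_auc.csv"),
          row.names = FALSE)
curves <- do.call(rbind, lapply(seq_along(ev$roc_curves), function(r) {
  cbind(repeat_id = r, ev$roc_curves[[r]])
}))
write.csv(curves, file.path(out, "roc_curves.csv"), row.names = FALSE)
prcs <- do.call(rbind, lapply(seq_along(ev$prc_curves), function(r) {
  cbind(repeat_id = r, ev$prc_curves[[r]])
}))
write.csv(prcs, file.path(out, "prc_curves.csv"), row.names = FALSE)
message(sprintf("  mean ROC AUC %.3f, mean PRC AUC %.3f",
                ev$mean_roc_auc, ev$mean_prc_auc))

message("Training the final calibrated classifier ...")
model <- train_kmer_svm(positives, negatives, seed = seed)
write_kmer_model(model, file.path(out, "kmer_model.tsv"))
top <- weight_table(model)[1:50, ]
write.table(top, file.path(out, "top_weights.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("  top weighted 8-mers: ", paste(head(top$kmer, 5), collapse = ", "))
message("Wrote model, holdout AUCs and curves under ", out)
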