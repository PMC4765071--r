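#!/usr/bin/env Rscript
# Stage 1 — simulate the study inputs.
#
# Builds the default synthetic training study: an i.i.d. genome, 1,000
# enhancer peaks carrying the GLI grammar (a GBM near the peak midpoint,
# one cofactor word ~200 bp off-center, a second GBM in 12 % of peaks) and
# a GC-matched background of equal size. Everything downstream (training,
# scanning, evaluation) reads the files written here.

suppressPackageStartupMessages(library(gliscan))

seed <- 1L
out <- "results/study"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("Simulating the default study (seed ", seed, ") ...")
study <- make_training_study(seed = seed, n_pos = 1000L)

write_fasta(study$genome, file.path(out, "genome.fa"))
write_bed(study$peaks, file.path(out, "peaks.bed"))
write_bed(study$background$regions, file.path(out, "background.bed"))
write.table(study$truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_fasta(setNames(study$positives, study$peaks$name),
            file.path(out, "positives.fa"))
write_fasta(setNames(study$negatives, study$background$regions$name),
            file.path(out, "negatives.fa"))

per_peak <- table(study$truth$peak[study$truth$type == "gbm"])
pos_gc <- gc_content(study$positives)
bg_gc <- study$background$regions$gc
message(sprintf("  %d peaks; single-GBM fraction %.3f (grammar default %.2f)",
                nrow(study$peaks), mean(per_peak == 1),
                study$grammar$p_single_gbm))
message(sprintf("  GC matching: max |dGC| = %.4f (tolerance 0.02)",
                max(abs(pos_gc[study$background$regions$matched_to] - bg_gc))))
message("Wrote genome, peaks, background and truth tables under ", out)
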