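---
title: "Predicting Hedgehog-responsive enhancers with GBM libraries and k-mer spectrum SVMs"
author: "gliscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting Hedgehog-responsive enhancers with GBM libraries and k-mer spectrum SVMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gliscan` turns a sequence of analyses — motif library construction from
ChIP peak sets, k-mer SVM training, genome-wide window scoring, overlap
evaluation — into a tested pipeline. This vignette explains the models and
procedures, the parameters that matter, the synthetic-data generators used
in place of restricted-access ChIP and ENCODE data, and the numerical
choices made where the design was genuinely open.

## The GBM 12-mer library

GLI transcription factors recognize a ~9 bp core (consensus
`GACCACCCA`) whose 6th-position C is invariant; concordant C/C (or G/G)
at the 5th and 7th positions of the 12-mer frame are required for
binding. We represent candidate binding sites as exact 12-mers stored in
canonical orientation (the lexicographic minimum of the word and its
reverse complement), so a word and its reverse complement are one library
entry.

The library is built per dataset by an iterative loop:

1. remove every sequence matching the current library (a sequence matches
   if it contains a library word or its reverse complement);
2. in the remainder, test every 12-mer occurring in the positive set for
   enrichment against a negative set (by default, base-shuffled copies of
   the same sequences) with the one-sided Fisher exact test, Bonferroni
   corrected over all tested words;
3. keep enriched words that pass the structural GLI-likeness filter
   (positions 4, 5 and 7 of the 12-mer are C in either orientation — the
   near-invariant `CCxC` run);
4. repeat until no accepted word remains (iteration cap 25; hitting the
   cap is an error, not a silent stop).

Words are then tiered by dataset presence: found in all datasets → high
confidence (HC), in two or more → medium (MC), in one → low (LC).
Exact-word enrichment with a structural filter replaces external motif
discovery/comparison tools; the loop logic — match, remove, re-discover —
is the part of the procedure this package treats as essential, while the
word-discovery engine is interchangeable. A consequence is that libraries
built here from synthetic data are small and exact; they do not attempt to
reproduce any particular published word list.

The one-sided Fisher p-value is computed as the hypergeometric tail
(`phyper`), which is algebraically identical to `fisher.test`'s
`alternative = "greater"` p-value but vectorizes over the ~10^5 candidate
words of a realistic run; equality with `fisher.test` is asserted in the
test suite.

## Matrix similarity (MSS)

For comparing sequences against a frequency matrix we implement the
MATCH-style information-weighted similarity: with column frequencies
$f(i,b)$ and information weights $I(i) = \sum_b f \ln(4f)$ (taking
$0\ln 0 = 0$),

$$\mathrm{MSS} = \frac{\mathrm{Current} - \mathrm{Min}}
                     {\mathrm{Max} - \mathrm{Min}},\qquad
  \mathrm{Current} = \sum_i I(i)\, f(i, b_i),$$

where Max and Min use each column's largest and smallest *observed*
(positive) frequency. Excluding zero-frequency bases from the attainable
range matters only for unsmoothed matrices (PWMs built by this package use
pseudocount 0.01, natural logarithms): a base with frequency zero cannot
occur in any motif-consistent sequence, so it should not stretch the score
range; a sequence that nevertheless uses one floors at 0. A fully
degenerate matrix (Max = Min) scores 1.

## The k-mer spectrum SVM

Sequences are represented by occurrence counts of canonical 8-mers over
all positions (windows containing N are skipped). For even $k$ the
canonical space has $(4^k - 4^{k/2})/2 + 4^{k/2}$ dimensions — 32,896 at
$k = 8$. Counts are deliberately **not** normalized: with raw counts the
decision function $f(x) = w \cdot x + b$ decomposes exactly as
$s = b + \sum_i w(\mathrm{kmer}_i)$ over positions, which is what makes
per-base weight profiles along an enhancer meaningful and makes scores
strand-invariant by construction. The divergence risk is that scores are
length-sensitive; all scored windows are therefore fixed-length (600 bp),
and edge windows are discarded rather than clipped.

Training solves the linear soft-margin SVM (C-SVC, default cost
$C = 1$ — no tuning is attempted, as cost only rescales the margin on
these separable-by-construction fixtures) via `kernlab::ksvm` on a
precomputed linear kernel of the sparse count matrix; weights are
recovered as $w = X_{SV}^\top \alpha$. The decision function is oriented
so positives score high (a label-order convention of the solver, fixed by
checking class means). Platt calibration
$P(\text{positive} \mid s) = 1/(1 + e^{As + B})$ is fitted on training
scores by the standard Newton iteration with smoothed targets
$t_+ = (N_+ + 1)/(N_+ + 2)$, $t_- = 1/(N_- + 2)$; for any useful
classifier $A < 0$, making the posterior monotone in the score.

Evaluation uses stratified random 80/20 splits repeated five times
(the repeat index offsets the seed, so the whole evaluation is
reproducible bit for bit). ROC AUC is computed rank-based
(Mann–Whitney), crediting tied pairs one half — exactly the all-pairs
concordance probability, which the tests verify against a brute-force
oracle and an independent implementation (pROC). PRC area uses right-step
interpolation $\sum_j (R_j - R_{j-1}) P_j$.

## Genome-wide scanning

Every exact occurrence of a library word (either strand; overlaps
allowed; a site equal to both a word and its reverse complement reported
once) seeds a window $[m - 300, m + 300)$ centered on the 12-mer midpoint
$m = \mathrm{start} + 6$. "Centered on the motif" is read as the motif
midpoint, not its start. Windows are scored by each supplied classifier;
the sign of the score is the call, and "high confidence" is
operationalized as raw score ≥ 1 (the computable form of posterior
probability ≈ 1). Pearson correlations between classifiers are reported
over all windows, windows both call positive, and high-confidence
windows; these subsets are nested by construction.

GC-matched background sampling is vectorized rejection sampling: for each
positive, same-length regions are drawn uniformly (contigs weighted by
placeable positions) until one lands off the positive intervals with
|ΔGC| ≤ 0.02 (tolerance default; 10,000 rounds cap, then an error naming
the unmatched positive). All-N candidates are rejected since their GC is
undefined.

## In silico GLI-site knockout (GKO)

The knockout mutates the invariant core C — position 6 of the 9-mer core,
i.e. position 7 of the 12-mer in its GLI-frame orientation — to G; for
matches whose GLI frame runs on the minus strand the complementary
substitution is applied at the mirrored coordinate. The 12-mer frame is
fixed by the convention that the 9-mer core occupies positions 2–10,
consistent with the `CCxC` run at positions 4–7; the "position 6" of the
mutagenesis protocol is read in the 9-mer core frame, since that is the
frame in which the mutated base is the invariant C. Finding any other
base at the target position signals a frame inconsistency and is an
error, not a silent skip. Tests verify that rescanning after knockout
removes every targeted match and creates none.

## Overlap evaluation

Enrichment of predicted positives over predicted negatives in a feature
track uses the pooled two-proportion Z-test, one-sided in the direction
positives > negatives (matching the directional claim being tested);
overlap means ≥ 1 shared bp, strand-blind, since no overlap fraction is
part of the contract. When the pooled proportion is 0 or 1 the statistic
is undefined and the result is flagged rather than fabricated.
Venn counts merge all regions across datasets and assign each merged
region the subset of datasets contributing ≥ 1 bp. Gene annotation is a
deliberate simplification of regulatory-domain tools: the two nearest
TSSs by absolute distance (ties broken by gene name), with signed
distances.

## The synthetic-data generators

The generators produce the statistical structure the analysis assumes,
not realistic genomes:

* **Genome** — i.i.d. bases at a target GC (default 0.42, mouse-like).
  No repeats, no Markov structure, no composition heterogeneity.
* **Positive peaks** — 600 bp regions; one GBM near the peak midpoint
  (offset SD 30 bp) with probability 0.88 — the mean of the single-site
  fractions observed across the four ChIP contexts the design emulates —
  otherwise two (the second uniform in the peak); one cofactor word
  (E-box-like `GCACCTGT` or Sox-like `CTTTGTTC`) at ±N(200, 50) bp from
  the midpoint, emulating the off-center cofactor enrichment seen in real
  peak sets; all implants on random strands, overwriting bases in place so
  coordinates stay exact. Implant positions are recorded as truth and are
  verifiable by substring inspection.
* **Sharing designs** — peaks are allocated to named dataset subsets;
  peaks sit in disjoint slots with ≥ 1 bp gaps, so interval merging can
  never fuse them and the Venn counter reproduces the design exactly.
* **Feature tracks** — each supplied enhancer region is covered with
  probability `p_enh` and each background region with probability `p_bg`.
  The background regions are an explicit argument because the enrichment
  design (0.8 vs 0.3 over 200 regions each) needs the negative-group
  overlap probability controlled exactly.

What passing tests on these fixtures shows: the machinery (counting,
matching, scoring, statistics) is correct, and the classifier recovers a
planted grammar against GC-matched background. What it does not show:
performance on real ChIP data, where peaks carry heterogeneous motif
grammars, repeats, and composition biases absent from i.i.d. genomes.
Relatedly, windows around *bare* GBM words (no cofactor context) are
separated from full-grammar enhancers only by the single cofactor word,
so that contrast is intrinsically weak in the default grammar — the
pipeline's discriminative power on the synthetic study comes from
motif-vs-background contrast, as it does in the emulated analysis.

## Problem sizes and determinism

The default study is 1,000 positives and 1,000 GC-matched negatives of
600 bp on a 2.4 Mb genome; evaluation fixtures use 100 kb–1.5 Mb genomes
with 40–200 peaks. These sizes keep a full desk run (tests plus the
acceptance script) in the minutes range while leaving every statistical
check well-powered. Every stochastic operation takes an explicit integer
seed and is bit-reproducible given it; repeated-holdout repeats and
script stages derive their seeds from one base seed by fixed offsets.

## Known limitations

* Exact-word (12-mer) matching has no mismatch tolerance; degenerate
  binding sites are represented by enumerating words, not by PWM
  scanning (the MSS scorer exists but is not used for genome matching).
* Odd k and gapped/mismatch kernels are unsupported.
* The discovery step tests exact words only and will fragment a long
  degenerate motif into many words.
* `kernlab`'s SMO on a precomputed kernel scales quadratically in
  sequences; the pipeline is designed for 10^3–10^4 training sequences,
  not 10^5.
* BAM/bigWig input is out of scope; intervals and tracks come and go as
  BED/bedGraph text.
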