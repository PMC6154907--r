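---
title: "Detecting viral contigs from relative synonymous codon usage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting viral contigs from relative synonymous codon usage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Viral metagenomics sequences all DNA in a clinical specimen, assembles the
reads into contigs, and asks which contigs are viral. Alignment-based
classifiers (BLAST, profile HMMs) leave a large fraction of contigs
"unknown" because divergent viruses have no close homolog in any database.
`viroscu` implements an alignment-free complement: many viral families
encode proteins with heavily skewed codon usage relative to their host, so a
contig's *relative synonymous codon usage* (RSCU) profile carries a weak but
exploitable class signal. The package extracts RSCU features from open
reading frames (ORFs) on both strands of every contig, trains random-forest
and feed-forward neural-network classifiers to produce `p(virus)` per
sample, evaluates them with leave-one-experiment-out cross-validation, and
ranks codons by Gini importance. A synthetic contig generator with a planted
codon-usage divergence makes the entire pipeline testable without any
external data.

## Feature model

For amino acid $i$ with $n_i$ synonymous codons, the RSCU of codon $j$ is

$$ f_{ij} = \frac{x_{ij}}{\tfrac{1}{n_i}\sum_{j=1}^{n_i} x_{ij}}, $$

the observed count divided by the count expected if all synonyms were used
equally. $f_{ij} = 1$ means no bias; the maximum is the family size $n_i$
(at most 6, for Leu/Ser/Arg). Methionine (ATG) and tryptophan (TGG) have a
single codon and carry no usage signal, and the three stop codons are not
amino-acid coding, so the feature vector has $64 - 2 - 3 = 59$ entries. The
canonical column order — amino-acid single-letter code, then codon
alphabetically — is part of the feature-table file contract
(`rscu_codon_order()`).

Two modelling decisions were genuinely open and are fixed as follows:

* **Zero-count families.** The formula divides by the family total; when an
  amino acid never occurs in a sample's ORFs we define the RSCU of its
  codons as 0 rather than NaN. This keeps the matrix dense and encodes
  "absent" distinguishably from "unbiased" (which is 1).
* **Pooling.** Counts are pooled across all ORFs of a strand before the
  formula is applied — one RSCU vector per strand of each contig, not a
  per-ORF average. The strand, not the ORF, is the sample unit.

## ORF scanning

Because a metagenomic contig's strand of origin is unknown, both the
sequence and its reverse complement are scanned, and the two directions are
treated as independent samples. In each of the three frames of a strand, an
ORF opens at the first ATG after the previous in-frame stop (or the
sequence start) and closes at the next in-frame stop codon; the coding
stretch runs from the first base of ATG up to but excluding the stop.

Conventions that the length rule ("at least 120 nucleotides between a start
and a stop codon") does not pin down:

* The 120 nt minimum is measured on the coding stretch, start codon
  included, stop codon excluded — the standard coding-region convention.
* Only the *first* ATG after a break opens an ORF. Nested later ATGs would
  re-count the same downstream codons and double-weight them in the pooled
  RSCU, so they are ignored.
* A reading that hits the end of the contig without a stop codon is not an
  ORF: the definition requires a closing stop.
* A triplet containing N terminates the current candidate without emitting
  it; ambiguous codons cannot be counted, and a partially-ambiguous ORF
  would distort the usage vector. Scanning resumes at the next ATG.
* Alternative start codons (GTG, TTG) are not recognized, and only the
  standard genetic code's stops (TAA, TAG, TGA) are used.

A strand becomes a training sample only if it carries at least two
qualifying ORFs (`min_orfs = 2`). The retention rule is applied per strand:
each strand is an independent sample and is kept or discarded on its own
ORF count, so a contig contributes 0, 1 or 2 rows. (The alternative
readings — "≥2 ORFs on at least one strand keeps both" or "≥2 in total" —
would admit strands whose own codon counts are too sparse for a meaningful
usage vector.)

## Classifiers

**Random forest** (`train_random_forest()`, backed by `ranger`): the
default configuration is 5000 trees, balanced class weights
($w_c = N / (2 N_c)$) and no resampling, which was the best-performing
combination for this task; trees consume raw RSCU values since monotone
feature scaling cannot change a split. Up/down-sampling variants are
exposed as configuration, not defaults. Training is deterministic given
(data, config, seed) with single-threaded tree growth.

**Feed-forward neural network** (`train_neural_net()`): fully-connected
ReLU layers (default two of 1024 units), dropout 0.25 after each hidden
layer, a sigmoid output, trained for 10 epochs with Adam starting at 1e-4
and multiplied by 0.95 after each epoch. Class imbalance is handled by
per-class loss weights $w_c = (N/(2N_c))^p$ with `class_weight_power`
$p = 0.25$ by default: $p = 0$ is uniform weighting, $p = 1$ fully balanced,
and intermediate powers interpolate. Choices the architecture description
leaves open are fixed as: binary cross-entropy loss, minibatch size 128,
per-feature z-score standardization fitted on the training fold only
(trees do not need it; gradient training does), He-style initialization,
and inverted dropout. The network is the package's own compact dense-layer
engine in base R matrix algebra, so fitted models are plain, serializable R
objects and training is exactly reproducible from the seed.

## Evaluation

Contigs from the same sequencing run are far more similar to each other
than to contigs from other runs; random k-fold splitting would leak that
similarity across the train/test boundary and inflate accuracy. The primary
splitter is therefore *leave-one-experiment-out* (`loeo_split()`): one fold
per run, testing on the entire held-out run. Both strand samples of a
contig share its experiment, so they can never straddle a fold. The
stratified `kfold_split()` (for single-experiment corpora such as gene-level
databases) groups by contig ID for the same reason.

Fold results are combined two ways: *micro* averaging pools every test
sample into one ROC (runs with more samples weigh more), *macro* averaging
computes one ROC per fold and averages with equal weight. Further
conventions:

* AUROC is the trapezoid area of the threshold-sweep ROC with tied scores
  grouped into a single operating point, which equals the Mann-Whitney
  pairwise concordance with ties counted one half; the test suite checks
  this equivalence exactly against a brute-force pair count and against
  pROC.
* The macro ROC *curve* is vertically averaged: mean TPR over folds,
  interpolated on a fixed 101-point FPR grid. (Any averaging convention for
  the curve is a choice; vertical averaging keeps the macro AUROC — defined
  as the plain mean of per-fold areas — and the plotted curve consistent to
  first order.)
* A fold whose test run lacks one class has no defined ROC and is dropped
  from macro averaging with a warning; micro averaging is unaffected.
* Classification at a threshold uses `score >= t` (inclusive).
* Precision that is undefined because no sample was predicted in a class is
  reported as 0 with an explicit `precision_defined = FALSE` flag.

Because the virus class is rare (~3%), overall accuracy is meaningless — an
all-negative classifier already scores 97% overall precision. Per-class
precision/recall/F1 at a stated threshold and the virus-class
precision-recall trade-off curve (`precision_recall_tradeoff()`) are the
operative summaries; the trade-off table is how a screening user picks a
high-precision threshold for candidate triage.

## Feature importance

A feature's Gini importance in one tree is the sum of impurity decreases at
the splits that use it. `gini_importance()` normalizes per tree (so each
tree contributes equally), then reports the mean and the across-tree
variance; the reporting protocol trains a fresh 1000-tree forest on the
full dataset. The variance is reported deliberately: RSCU values of
synonymous codons are strongly anti-correlated within a family (with two
synonyms, almost perfectly), and correlated features compete — whichever is
used first in a tree absorbs the shared information — so per-tree
importances of informative synonyms swing widely even when their means are
stable. Codons are displayed grouped by amino acid with the largest
families first, with per-family importance sums.

When called on a feature table the per-tree path grows the forest one
bootstrap tree at a time (a random forest is exactly a collection of
independently bootstrapped trees), which makes per-tree importances
observable; called on an already-fitted forest it falls back to the
normalized aggregate importance with variance reported as `NA`.

## The synthetic data generator

`generate_dataset()` emulates the regime the classifier is meant for:
multiple sequencing experiments of assembled contigs, a rare viral class
(default prevalence 3%), and codon-usage profiles that differ between the
classes only in *synonymous codon choice*. Amino-acid composition is drawn
uniformly over the 18 multi-codon amino acids for both classes, so any
downstream classification accuracy is attributable to RSCU alone — the
exact feature family the method uses — and not to amino-acid or nucleotide
composition shortcuts.

The planted divergence lives on six codons (TCG, CGC, CGA, GCG, GTA, CCG).
At the calibrated level (`divergence = 1`) the expected RSCU of TCG is 0.39
in non-viral vs 0.60 in viral contigs and CGC 0.53 vs 0.80 — the class
means observed for the two most discriminative codons in real metagenomic
data — and the other four codons follow the same low-in-host,
higher-in-virus pattern (0.40-0.52 vs 0.72-0.90). `divergence` scales all
six gaps linearly down to 0, where the two profiles are identical and the
task is undecidable by construction.

Structural choices worth knowing:

* **Planted ORFs and frame breakers.** Each contig is a chain of planted
  forward-strand ORFs (ATG + profile-drawn codons + stop) separated by
  intergenic spacers that contain stops in every frame of both strands.
  Inside each ORF a short frame-breaker codon run (Leu-Ile-Asn-Tyr, from
  families that never carry planted signal) is spliced in every ~25 codons;
  its junctions spell stop codons in both shifted forward frames and its
  reverse complement stops all three reverse frames. Without it, spurious
  shifted-frame ORFs overlapping the planted ones contribute scrambled
  codons that dilute the planted usage signal by a third or more and break
  the calibration between profile and realized class means.
* **Batch effects.** Each experiment draws one logit-normal shift (sd
  `batch_effect_sd`, default 0.10) applied to the codon probabilities of
  *both* class profiles, then renormalized per family: run-level codon
  composition drifts while the within-run class contrast is preserved,
  which is exactly what makes leave-one-experiment-out genuinely harder
  than within-run splitting.
* **Sizing.** Contig lengths default to 1200-4000 nt with 2-5 ORFs. The
  choice comes from a power analysis of per-sample codon-sampling noise: a
  strand sample of $n$ codons sees roughly $n/18$ draws per amino-acid
  family, and the per-codon class separation at the calibrated divergence
  is a fraction of the within-class standard deviation, so several hundred
  codons per sample are needed before the six-codon signal is recoverable
  at all. Shorter contigs push the task toward chance regardless of the
  classifier — a real phenomenon (short contigs genuinely carry less usage
  information), but one that would make the default regime uninformative as
  a test bed.
* **Indel noise.** `indel_noise_rate` inserts or deletes single bases
  uniformly, emulating assembly frameshifts; a frameshift truncates or
  destroys planted ORFs and degrades recovery, which the test suite checks
  as a monotone effect. The default is 0; it is a stress knob, not part of
  the calibrated regime.

What the generator does *not* emulate: real genome architecture (gene
density, overlapping genes, strand mixtures), amino-acid composition
differences between proteomes, GC-content gradients, chimeric or
misassembled contigs, and any phylogenetic structure. Passing the suite
therefore shows that the pipeline recovers a planted synonymous-usage
signal under class imbalance and batch effects — not that real viral
contigs are this separable; on real data the attainable AUROC is
considerably lower.

## Numerical and reproducibility choices

* One global seed fans out to per-stage seeds by a fixed integer derivation
  (`seed * 1009 + stage * 7919` modulo a large prime), so pipeline stages
  can be rerun in isolation and reproduce; all RNG use is wrapped so the
  caller's RNG state is never disturbed.
* Forest training and prediction default to one thread; `ranger` results
  are then bit-reproducible for a given seed.
* ROC interpolation uses `approx(ties = max)` so duplicated FPR values take
  the highest TPR of the duplicate group.
* The test suite and the acceptance script run the study conditions at desk
  scale: 10 experiments of 200 contigs, 200-tree forests for
  cross-validation, a 1000-tree forest for importance, and a reduced-width
  network (the 2x1024 default is meant for real corpora). These sizes are
  stated here as the package's chosen experiment sizes and are the ones all
  reported numbers refer to.

## Known limitations

* RSCU needs ORFs: contigs with fewer than two ORFs on both strands are
  discarded, biasing against short or fragmented contigs.
* The two strand samples of one contig are treated as independent although
  they are derived from the same molecule; splitting is grouped so this
  never leaks across folds, but pooled metrics count such pairs twice.
* Virus-class recall at the default 0.5 threshold is low under 3%
  prevalence even with class weighting; the intended use is ranked triage
  via the precision-recall trade-off, not a hard 0.5 cut.
* Only the standard genetic code is supported.
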