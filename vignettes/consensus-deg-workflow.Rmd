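---
title: "Consensus differential expression for myometrial bulk RNA-seq: models and methods"
author: "myoseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus differential expression for myometrial bulk RNA-seq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoseq)
```

## The scientific problem

Human labour is a dynamic process: the myometrium (uterine smooth muscle)
transitions from quiescence through early labour (cervical dilatation of at
most 3 cm) to established labour (more than 3 cm), and fetal membrane rupture
(ROM) may occur anywhere along the way. Bulk RNA-seq of myometrial biopsies
grouped by these clinical classifications — early labour (TEaL), established
labour (TEsL), labour without ROM (TL-ROM) and with ROM (TL+ROM), each
compared against the same term-no-labour reference (TNL) — asks which genes
change expression as labour begins, progresses, and responds to membrane
rupture. Because such cohorts are small (6–8 biopsies per group) and the
tissue is heterogeneous, single-method differential expression calls are
fragile. This package implements a consensus workflow: a gene is only carried
forward when at least two of three independent negative-binomial testers
agree, and is only reported when its fold change survives a floor on
near-zero expression.

## Gene models and read counting

Annotation is reduced to one flattened model per gene. Transcripts whose
biotype (or tag) matches `retained_intron` (case-insensitive) are excluded
first — their intron-spanning exons would otherwise inflate the exonic
footprint of the gene — and the remaining exons are merged into disjoint
intervals. Two choices deserve a note:

* **Adjacent intervals are merged.** Intervals with a zero-length gap at
  base resolution (end + 1 = next start) occupy the same bases as their
  union, so merging them changes no downstream quantity.
* **Genes whose transcripts are all retained-intron are dropped** (with a
  warning) rather than kept as zero-length models, because a zero exonic
  length is an undefined TPM denominator. This situation is an annotation
  pathology rather than a biological statement.

Counting is fragment-based and deliberately strict. A mate is assigned to a
gene only when strictly more than 90% of its aligned (CIGAR M) bases fall in
the gene's merged exons; soft-clipped bases and N gaps do not enter the
denominator. Only alignments with `NH:i:1` (uniquely mapped) count, a
fragment increments a gene only when every mapped mate passes for that same
gene, and reads qualifying for two or more genes are discarded as ambiguous
(assigning them to both would break the conservation identity assigned +
rejected = total, which the tests enforce). Assignment is unstranded by
default: the strictness of the overlap rule, not strand, is the workhorse of
specificity here, and the counting rule itself makes no reference to strand.

TPM uses the standard length-normalized definition: per-kilobase rates
renormalized to one million per sample, with merged exonic length as the
denominator.

## The three testers and the consensus rule

All three testers model counts as negative binomial with mean `mu` and
dispersion `phi` (variance `mu + phi * mu^2`), share median-of-ratios size
factors (rescaled to geometric mean one), and are *simplified
re-implementations of three paradigms* — they are not reproductions of any
external package, and the consensus layer treats them as pluggable:

1. **Exact conditional test** (`nb_exact_test`). Counts are scaled to a
   common effective library size and summed per group; conditional on the
   total, the two-sided p value sums the probabilities of all splits no more
   likely than the observed one. With `phi = 0` this collapses to the
   two-sided binomial split, which the tests verify by direct enumeration.
2. **Wald test on a log-link NB model** (`nb_wald_test`). Group means are
   fitted by Newton iterations with known dispersion and size-factor
   offsets; the Wald statistic is the log fold change over its information-
   based standard error. A half-count pseudocount on the fitted group means
   keeps genes observed in only one group testable (no shrinkage estimator
   of the fold change is attempted). Genes with zero counts everywhere are
   reported as not testable, not as p = 1.
3. **Empirical-Bayes model posterior** (`eb_posterior_test`). Marginal
   likelihoods of an equal-mean and a group-specific-mean model are
   Monte-Carlo averages over an empirical prior: (mean, dispersion) pairs
   sampled, under a fixed seed, from the moment estimates of the dataset's
   own genes. Under the group-specific model the group means are independent
   draws, so its marginal likelihood factorizes over groups. Model weights
   are estimated by iterating expected model frequencies, and the default q
   value is the cumulative mean posterior-of-null in posterior order, with
   BH on (1 − posterior) available as an alternative convention.

Dispersion is estimated by per-gene method of moments on normalized counts,
then shrunk toward a log-linear mean–dispersion trend with weight
`d / (d + prior_df)`, where `d` is the residual degrees of freedom and
`prior_df = 10` by default; estimates are floored at `1e-8`. This is a fixed,
documented compromise: at 6–8 samples per group the raw moment estimate is
noisy, and the trend supplies stability without attempting any package's
exact shrinkage machinery.

Per method, p values are BH-adjusted over testable genes only — methods
legitimately differ in which genes they can test, which is why the consensus
treats a missing q as "not significant" rather than as an error. A gene is a
**shared DEG** when at least two methods give q ≤ 0.05 (both thresholds
inclusive and configurable).

The PCA overview uses `log2(normalized count + 1)` as the
variance-stabilizing transform. This is a deliberate simplification of
regularized-log approaches: it is monotone, fast, and adequate for a sample-
level overview; it does not shrink low-count genes, so PC loadings of very
low-expression genes are noisier than under a true regularized transform.

## Fold-change filtering

Fold changes are ratios of group **median** TPM (medians resist the high
between-sample variance typical of labouring myometrium), always larger over
smaller, so fc ≥ 1. Any median below 1 TPM is raised to 1 before the ratio is
taken: a gene at 0.02 vs 0.9 TPM would otherwise show a 45-fold change that
is pure noise. A shared DEG is **robust** when fc ≥ 1.5 (inclusive). The
filter is applied to *all* shared genes — the floor simply has no effect when
both medians are at least 1 — and a gene whose floored medians coincide has
fc = 1, no direction, and never passes. Direction (up/down) is always stated
for the alternative group relative to the shared reference.

## Venn partitioning and enrichment

Robust up- and down-regulated lists from all contrasts against the common
reference are partitioned by membership signature; the all-ones region is the
set of genes shared by every labour classification. Gene identity is the
annotation's gene id; symbol mapping is a presentation concern left to the
caller.

GO over-representation uses the hypergeometric upper tail (one-sided Fisher)
against an expression-based background: a gene enters the background when its
median TPM is at least 1.5 (inclusive) in at least one of the two compared
groups. Testing up- and down-regulated sets separately keeps direction
information that a combined test would lose. BH adjustment is applied within
each GO class (BP/MF/CC) to match per-class reporting, with a global option.
Terms absent from the background are skipped rather than reported at p = 1.
The annotation is used exactly as supplied — no ancestor propagation over the
GO graph is attempted, so pre-propagated annotations are the caller's
responsibility. Enrichment is computed on membership counts only; fold
changes accompany the gene lists as annotation but do not enter the test
statistic, since no well-defined count-and-magnitude combination is standard.

## qPCR quantification and statistics

Standard curves are least-squares fits of Ct against log10 copies;
`ct_to_copies` inverts them, and noise-free data round-trip to machine
precision (a test). Targets are normalized to two housekeeper genes by the
geometric mean of the two per-housekeeper ratios — algebraically
`target / geomean(hk1, hk2)`, an identity the tests exploit — then log10
transformed, which makes the lognormal expression values approximately
normal and justifies Welch-type parametric tests. Technical Ct replicates
are averaged before copy conversion by default (Ct is the machine's native
scale); averaging copies after conversion is available.

For group comparisons:

* **Welch's t** and **Welch's heteroscedastic ANOVA** avoid the equal-
  variance assumption that small clinical groups rarely satisfy.
* **Dunnett's T3 post hoc** refers pairwise Welch statistics to the
  studentized maximum modulus with per-pair Satterthwaite df; under
  independence of the r comparisons this tail is exactly
  `1 - (2 F_t(|t|) - 1)^r`, the form implemented here. Because the pairwise
  statistics are in fact positively correlated, the procedure is mildly
  conservative — the test suite verifies family-wise error at or below
  nominal in a null simulation rather than exactly at it.
* **Mann-Whitney** uses full enumeration over rank assignments — midranks,
  so ties are handled exactly — whenever the combined sample size is at most
  20, and a tie-corrected normal approximation without continuity correction
  above that.
* **Kruskal-Wallis** computes the tie-corrected H and, for small designs
  (up to 3 groups, total N ≤ 25), an *exact permutation p* via a dynamic
  programme over the joint rank-sum distribution — feasible where naive
  enumeration (~10^9 partitions at N = 22) is not, and exercised against
  brute-force enumeration on small cases in the tests. The chi-square
  approximation serves larger designs. The exact mode matters: at these
  sample sizes the chi-square approximation misstates p by more than 0.01,
  and the package's recomputed demographics p values (0.306, 0.067, 0.594)
  agree with published small-cohort values only under exact computation.
  Dunn's post hoc on mean ranks uses Bonferroni adjustment.

In-silico PCR is exact-substring matching of the forward primer and the
reverse complement of the reverse primer, in both template orientations, so
results are invariant under reverse complementation of the template. No
mismatch tolerance or melting-temperature model is attempted — primers
designed against unique sites either match exactly or not at all.

## The synthetic-data generators

Every stage is testable offline because the generators plant known truth:

* `make_annotation` builds multi-transcript genes whose retained-intron
  transcripts carry a genuine intron-spanning exon, so exclusion visibly
  changes the flattened model.
* `simulate_reads` writes plain-text SAM (valid @SQ headers; CIGARs limited
  to M/N/S) with three planted classes: clean pairs fully inside merged
  exons, multimapped pairs (`NH:i:2` plus a secondary record), and pairs
  with one mate at 0.8 exon overlap — constructed to fail the strict >0.9
  rule. Truth counts clean fragments only, so correct counting must
  reproduce truth exactly and tally the planted noise by reason.
* `simulate_counts` draws negative-binomial counts with lognormal baseline
  means, a spiked fraction of true DEGs, and lognormal library-size factors
  (sd 0.2) rescaled to geometric mean one so size-factor estimation is
  non-trivial. Defaults — baseline log-mean `log(100)`, log-sd 1, dispersion
  0.1, 10% spiked at fold change 4, groups of 8 — describe a moderately
  deep bulk RNA-seq experiment at the cohort sizes above: dispersion 0.1 is
  typical for human tissue replicates, and a log-sd of 1 spans roughly two
  orders of magnitude of expression.
* `simulate_go` assigns terms at a baseline membership probability of 0.05
  and over-represents spiked genes in planted terms at a configurable odds
  ratio; `simulate_qpcr` draws Ct values from a log-linear standard curve
  with Gaussian noise.

All randomness flows from one integer seed through per-stream derived seeds;
the caller's RNG state is never touched, and equal seeds give byte-identical
output files.

What the generators do **not** emulate — and what green tests therefore do
not establish about real data — includes sequencing-error and quality-score
profiles, GC and positional bias, correlated gene-gene expression, cell-type
mixtures within a biopsy, batch structure, and annotation errors. The
recovery figures from synthetic runs (sensitivity ≈ 1, empirical FDR ≈ 0.05
at fold change 4 with 8 vs 8 samples) are upper bounds on real-data
performance, not predictions.

## Numerical choices and degenerate inputs

* Thresholds are inclusive where stated: q ≤ 0.05, fc ≥ 1.5, background
  median ≥ 1.5; the read-overlap rule is strictly > 0.9.
* The exact conditional test includes ties in probability (outcomes exactly
  as likely as observed) with a `1e-12` relative guard.
* Newton fitting of group means is capped at 50 iterations with step
  clamping; information is floored to avoid division by zero.
* All-zero genes are untestable everywhere (absent q), and an all-zero
  sample has all-zero TPM.
* A count matrix in which no gene is expressed in every sample makes the
  median-of-ratios reference undefined; the error message points to the
  `pseudo_reference` fallback (positive-count geometric means).
* PCA on samples with zero total variance returns no components, with a
  warning, rather than fabricating coordinates.
* Exact tests break p-value ties conservatively (≥ comparisons), and the
  eb tester's tied posteriors share the largest cumulative-mean q among
  them.

## Problem sizes used in the checks

The bundled tests and the acceptance script run entirely from generated or
bundled data at sizes chosen to exercise every code path while completing a
full run in minutes: interval-merge equivalence on 1000 random genes,
counting on a few thousand simulated fragments, tester calibration on 2000
genes at 8 vs 8, and five seeded replicates of the end-to-end recovery run.
Larger inputs change runtimes, not code paths.

## Known limitations

* The testers are paradigm re-implementations; version-exact agreement with
  any released DE package is a non-goal, and published DEG counts obtained
  with specific package versions on the original alignments are not
  reproducible from this package alone.
* The workflow covers two-group contrasts against a common reference; GLM
  designs with covariates or batch terms are out of scope.
* `log2(x + 1)` under-stabilizes very low counts relative to regularized
  transforms.
* The empirical-Bayes tester's prior is sampled from the data's own moment
  estimates; on very small gene sets (hundreds of genes) the prior is
  coarse and its q values correspondingly conservative.
* GO analysis treats the annotation as flat; enrichment of a term does not
  propagate to its ancestors.
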