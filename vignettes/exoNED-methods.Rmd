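---
title: "Detecting neuroendocrine differentiation from EV small-RNA profiles: methods"
author: "exoNED"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{exoNED methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exoNED)
```

## Background

Castration-resistant prostate cancer (CRPC) treated with androgen-pathway
inhibitors can trans-differentiate into an androgen-independent
neuroendocrine phenotype (CRPC-NE). That switch is hard to diagnose:
biopsy is often infeasible in widely metastatic disease and circulating
neuronal markers lack specificity. Serum extracellular vesicles (EVs)
carry miRNA and protein cargo from tumor cells, so a liquid biopsy
reading the EV small-RNA repertoire — plus an EV protein marker,
thrombospondin 1 (THBS1) — is an attractive alternative. exoNED
implements that analysis chain as reusable, tested components, together
with a synthetic-data generator so every stage can be validated without
access to patient sequencing.

The canonical cohort shape throughout the package is 21 adenocarcinoma
(class 0, "Adeno") versus 7 neuroendocrine (class 1, "NE") samples —
leave-pair-out cross-validation over that shape enumerates 21 × 7 = 147
held-out pairs.

## isomiR calling

Reads are assigned to a mature-miRNA reference by exact
substring-anchored matching. The variant classes are: `canonical` (read
equals the mature sequence), `iso_3p_addition` (mature plus up to
`maxModLen` extra 3' nucleotides), `iso_3p_trim` (3'-shortened mature),
`iso_5p` (5' extension or truncation only) and `other` (changes at both
ends); anything else is `unassigned`. We chose exactness over scored
alignment deliberately: with no mismatch tolerance every call is
auditable, and on simulated reads the generator's ground truth is an
exact oracle. `maxModLen` defaults to 4 nt; the minimum classifiable
read length is 14 nt, matching the lower end of isomiR lengths seen in
EV cargo (14–24 nt).

The seed is the 7-mer at mature positions 2–8 (1-based, inclusive) — a
stated convention, since "seed" is sometimes quoted as 2–7. Seed
integrity requires the parent seed to sit at positions 2–8 *of the
read*: pure 3' variants always keep it, any 5' register shift breaks it.
This is the read-level restatement of the biological observation that EV
isomiRs differ from the native miRNA at the 3' end while preserving
targeting. Ambiguous reads resolve by class priority (canonical >
3'-addition > 3'-trim > 5' > other) and then lexicographic parent name,
so output is deterministic.

Features for counting are one per (parent, class, exact sequence);
canonical features are named by parent, isomiRs as
`parent|class|len<k>` with a `|v2` suffix on length collisions. The `|`
delimiter is also how downstream code recognizes isomiR features.

## Differential expression

Normalization is median-of-ratios over features expressed in every
sample (the DESeq-family estimator; cross-checked against DESeq2 in the
test suite), with a total-count fallback when no feature is shared. The
per-feature test is a negative-binomial Wald test: dispersion
(`variance = mu + alpha * mu^2`) is estimated by method of moments
within each class, pooled with degrees-of-freedom weights and floored
at 1e-8; the statistic is the log ratio of class means over its
delta-method standard error, referred to a standard normal. This is
deliberately simpler than a full empirical-Bayes pipeline — no
dispersion shrinkage, Cook's filtering or independent filtering — and
that simplification is the package's main modeling deviation from the
heavyweight DE tools. Simulation shows it is adequately calibrated at
the sample sizes we target (empirical type-I error ~0.05 at n = 20/20;
see the acceptance checks).

Fold changes use a pseudo-count of 0.5 on each class mean; all-zero
features report p = 1 and log2FC = 0; classes with identical per-feature
values give exactly log2FC = 0. Significance defaults to BH-adjusted
p < 0.05 **and** |FC| > 2. A raw-p mode (`useAdjusted = FALSE`) is
provided because the two filters circulate in both forms; the adjusted
form is the default since FDR control is what the headline feature lists
require. "Low expressors" are removed *before* BH adjustment using an
expression floor, default mean normalized count >= 10 — the term has no
standard quantification, so the floor is exposed as a parameter.

## Classifier construction

The seed feature set is the significant DE features, with three modes:
`mature_only` (isomiRs excluded — the primary panel), `with_isomirs`,
and `tissue_concordant` (only features significantly altered, in the
same direction, in both serum EVs and matched tissue).

Boruta is implemented in-package: each iteration appends a permuted
shadow copy of every feature, fits a random forest, and scores a hit for
each real feature whose impurity importance exceeds the best shadow.
Hit counts are tested two-sided against Binomial(iterations, 1/2) with
Bonferroni correction over the still-undecided features; iteration stops
early once all features are decided (cap 50). The Bonferroni variant is
a stated choice — the literature also uses two-step corrections — and
its false-confirmation rate is measured directly in the acceptance
checks (<1% on pure noise).

Leave-pair-out cross-validation holds out every (NE, Adeno) pair once.
Feature selection runs *inside* each fold on the training samples only;
the fold's forest is trained on the confirmed features, falling back to
tentative features and then to the full seed set so every fold scores.
Both held-out samples receive the NE probability; the AUC is the
fraction of pairs ranking the NE sample higher, with half credit for
ties (the tie rule is ours; the LPOCV literature leaves it open).
Features are ranked by selection frequency, then mean impurity
importance, then name. Panel sizes are data outcomes, not parameters;
`rankFeatures(k = ...)` truncates on request. AUC confidence intervals,
when wanted, come from a percentile bootstrap over pairs (`aucCI`,
1000 resamples by default) and are labeled as bootstrap intervals.

Numerical choices for the forests: 500 trees for a deployed model, 100
(or 50 for permutation sweeps) in tests and cross-validation; feature
subsample `floor(sqrt(p))`; impurity importance; `min.node.size = 1`.
The last matters: probability forests otherwise default to terminal
nodes of 10, which on folds of ~26 samples collapses trees to their
roots and makes all scores constant. Every forest receives an explicit
seed; LPOCV derives fold seeds as `(seed + 7919 k) mod 2147483646 + 1`,
which is part of the documented reproducibility contract (the test
suite's independent fold enumeration relies on it).

## Compartment concordance, ΔΔCt, and the THBS1 ELISA

Concordance between EV and tissue alterations uses significance in each
compartment, not raw sign agreement: a feature's direction is the sign
of its log2FC *when significant* and `ns` otherwise, and the call
(concordant up/down, discordant, EV-only, tissue-only, ns) is a total
function of the two directions. qPCR validation uses the comparative-Ct
rule, fold = 2^-ΔΔCt.

The ELISA standard curve is a four-parameter logistic — the standard
model for sandwich immunoassays; a plain "standard curve" does not pin
down a family, and 4PL is what plate readers fit. Fitting is
Levenberg–Marquardt least squares; the 4PL's two symmetric
parameterizations are normalized post-fit to the increasing form
(upper > lower, slope > 0). Interpolation is the closed-form inverse,
and ODs at or beyond the asymptotes are flagged missing rather than
extrapolated. The diagnostic threshold rule calls a sample NE when its
THBS1 concentration is **at or above** the threshold (default 7 ng/ml):
EV THBS1 rises with neuroendocrine differentiation, so the inequality
direction follows even though it is rarely written out. Sensitivity and
specificity are stored exactly and displayed as integer percents.

## The synthetic-data generator

`simulateCounts` emulates the count substrate: NB counts with
`variance = mu + alpha mu^2`, baseline means log-uniform over
`10^0.5`–`10^3.5`, library sizes log-uniform over 0.5–2 million applied
as multiplicative factors (so median-of-ratios normalization is actually
exercised), and a planted DE subset whose class-1 means shift by
`2^(+/-lfc)` with alternating signs. Dispersion defaults to 0.2, a
mid-range value for bulk small-RNA counts; 0 means Poisson. The default
cohort is 21 vs 7. `simulateReads` emits reads per variant class with 3'
dominance by default (45% canonical, 30% 3'-addition, 15% 3'-trim, 10%
5'), and `simulateElisa` adds Gaussian OD noise (default sd 0.02) to a
4PL curve. All generators are seeded and bit-reproducible, and every
read/feature appears exactly once in the returned ground truth.

What the generator does *not* emulate: sequencing error, adapters and
quality decay; multi-mapping and genomic alignment; correlated feature
families; batch effects; dispersion trends with expression; novel-locus
discovery. Passing tests therefore demonstrate that the algorithms
recover what they are specified to recover under the stated statistical
model — not that real serum EV libraries meet that model.

For parameter-recovery scenarios the planted features are drawn with
baseline means `10^1.5`–`10^3.5` (roughly 30–3000 normalized counts):
recall is only meaningful for features expressed above the low-expressor
floor, so the recovery condition plants effects where the study's own
filter would keep them.

## Problem sizes used by the checks

The packaged checks run at the sizes the analysis is designed for: null
calibration over 200 label permutations of the 21-vs-7 cohort
(50-tree forests, selection off — permutation nulls need no nested
selection); signal recovery over 5 seeds with 12 planted features at
|log2FC| = 2 and dispersion 0.1; Boruta calibration on 40-sample tables
with 50–100 features over 50 seeds; DE calibration over 2000 null
features at n = 20/20; the isomiR oracle over 5000 simulated reads. The
acceptance script reruns the same battery at moderately reduced
replicate counts (100 permutations, 3 recovery seeds, 25 Boruta seeds),
sizes chosen so the whole script completes in a couple of minutes while
keeping Monte-Carlo error well inside the assertion margins.

## Known limitations

* The DE test's moment-based dispersion is noisy at very small n; below
  ~10 samples per class the test leans on the pseudo-count and the
  normal reference and should be read as a screening tool.
* Exact-match isomiR calling cannot absorb sequencing errors; on real
  FASTQ data an upstream error-correction or a mismatch-tolerant mapper
  would be needed before these classes are trusted.
* The LPOCV AUC is an in-cohort estimate; no external validation cohort
  logic is provided.
* Novel-miRNA discovery (hairpin prediction) and piRNA analysis are out
  of scope; unassigned reads are counted, never discovered as new loci.

## A compact end-to-end example

```{r example, eval = FALSE}
cfg <- defaultRunConfig()
cfg$simulate$n_features <- 200L
out <- runPipeline(cfg, outDir = "exoNED_demo")
str(out$files)
```
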