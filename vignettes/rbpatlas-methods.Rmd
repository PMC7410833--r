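---
title: "Methods: models, procedures and design choices in rbpatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, procedures and design choices in rbpatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbpatlas)
```

# Scope

`rbpatlas` implements the computational core of large-scale RNA-binding
protein (RBP) functional mapping: quantifying in vivo binding from eCLIP
(IP versus size-matched input), in vitro specificity from RNA Bind-N-Seq
(RBNS), and the statistics that connect binding to splicing, expression,
chromatin and subcellular localization. Everything runs on synthetic data
generated by the package itself, with planted ground truth, so that each
estimator can be validated by parameter recovery and null calibration.

This vignette records the models, the parameters that matter, and the
design decisions taken where a published description leaves the choice
open.

# The synthetic data model

`make_transcriptome()` lays genes on one linear chromosome, 0-based
half-open coordinates throughout. The first gene slots follow a fixed
plan (a coding host gene with a long intron hosting a miRNA, a tRNA
gene, a noncoding gene, a standalone miRNA), guaranteeing that all 11
annotation labels exist whenever `n_genes >= 5`. Coding genes have 4-6
exons of 120-280 nt; most introns are 260-900 nt with at least one of
1.5-2.6 kb per gene so distal-intron territory exists. Expression is
log-normal TPM per cell type, with every 7th gene planted strongly
differential and every 11th cell-type-specific so that the cross-cell
categories are all populated.

`binding_truth()` bundles what the generators plant and what the
estimators must recover: enriched elements with fold `lambda`,
per-repeat-family selection weights, an RBNS consensus with per-occurrence
selection factor `s`, and per-exon splicing regulation `dpsi`. Elements
are planted in the proximal intron immediately downstream of the regulated
exons, so the planted eCLIP signal and the planted splicing response
coincide -- the configuration a splicing map is designed to reveal.

Read simulation (`simulate_eclip()`) samples input reads proportional to
expression times region weight (exonic bases weight 1, intronic 0.1, a
small intergenic floor), and IP reads with the planted `lambda` and
repeat-family weights multiplied in. PCR duplicates are whole-record
copies sharing mapping start/stop and the 10-nt UMI -- exactly the key
the deduplicator collapses on. The generator does not model sequencing
errors, fragment-length distributions or crosslink-position bias, so
passing tests demonstrate correctness of the estimators under the
declared sampling model, not robustness to those real-data artefacts.

For RBNS (`simulate_rbns()`), input reads are uniform random oligos and
pulldown reads are selected with relative odds $s^m$, where $m$ counts
(overlapping) motif occurrences. Selection is implemented as weighted
multinomial resampling from a candidate pool (default 5x the library
size): per-candidate Bernoulli rejection with a correct envelope accepts
only about one candidate in a thousand at realistic `s`, whereas
resampling realizes the same selection odds unbiasedly at practical cost.
The model was chosen because it admits a closed-form expected enrichment:

$$ R(k) \;=\; \frac{E[c_k\, s^{m}]}{E[s^{m}]\; E[c_k]} $$

with $c_k$ the occurrence count of k-mer $k$ in a uniform random read.
`rbns_expected_r()` evaluates both expectations exactly by dynamic
programming over a suffix automaton ($4^{M-1}$ states, $M$ the longer of
motif and query), giving an analytic oracle for the whole
simulate-then-estimate loop. At $2\times10^5$ reads the measured top
R value for a planted UGCAUG at $s = 10$ agrees with the analytic value
within Monte-Carlo error (about 3.2).

Knockdown tables (`simulate_kd_tables()`) draw control inclusion levels
from Beta(2, 2) -- the native-psi distribution is not dictated by any
published account, so it is a configurable modelling choice
(`psi_shape`). Null events carry p ~ Uniform(0,1); planted events draw p
from Beta(0.05, 1) truncated to $\le 10^{-4}$, which guarantees that a
planted event with $|\Delta\psi| \ge 0.06$ passes the significance
thresholds (p < 0.05, FDR < 0.1, $|\Delta\psi|$ > 0.05) after
Benjamini-Hochberg adjustment for any table size used here. Null events
are drawn only from exons without planted regulation, so native
backgrounds are unbound by construction.

# eCLIP quantification

**Repeat families.** Read pairs mapping to the multi-copy element
database keep only their lowest-mismatch mappings; within a family the
highest-priority transcript is the primary match; equal-best mappings
spanning two or more families are discarded from quantification.
Antisense mappings belong to a derived `antisense_<family>` counterpart,
except for the combined simple-repeat family. A unique genomic mapping
beats the repeat mapping only when its pair-summed alignment score is
better by strictly more than 24 (two mismatches per read); the boundary
case goes to the repeat, a reading documented and tested explicitly.
PCR deduplication keeps one record per (target, start, stop, UMI); the
survivor is the lexicographically smallest read id, an order-independent
choice that leaves counts unchanged.

**Relative information.** Per element, $p_i \log_2(p_i/q_i)$ bits, with
$p_i, q_i$ the IP and input fractions of total usable reads (discarded
multi-family pairs are excluded from the normalizers, since they are
discarded from quantification). Elements with zero reads in exactly one
library receive a pseudo-fraction of half the reciprocal library depth;
the quantity is otherwise undefined at zeros and the choice only affects
vanishing tails. The merged-replicate variant averages the two IP
fractions.

**Regions and peaks.** Region-level enrichment uses the 2x2 table of
in-region versus remaining reads for IP and input. The p-value is
Fisher's exact test, replaced by the Yates-corrected chi-square when all
observed and expected cells exceed 5; eligibility requires at least 10
reads in one library and at least 10 expected in the other given the
depth ratio; significance is fold $\ge$ 4 and p $\le 10^{-5}$. The
Fisher p is computed in-package as a vectorized hypergeometric tail sum
(identical convention to `stats::fisher.test`, which serves as an
independent cross-check in the tests); the in-package version exists
because the test suite compares it against exhaustive enumeration over
every 2x2 table with margins up to 30, a sweep far outside
`fisher.test`'s performance envelope.

Reproducible peaks merge overlapping replicate peaks (>= 1 nt, same
strand), score them by geometric means of log2 fold enrichment and
-log10 p, and filter at fold >= 8, p <= 0.001. The reproducibility
criterion itself is a surrogate: candidates are ranked by fold
enrichment within each replicate and the `idr_threshold` fraction with
the largest rank-percentile discordance is flagged irreproducible. This
controls the flagged fraction, not a mixture-model posterior; the scorer
is an injectable function so a full irreproducible-discovery-rate fit
can be swapped in without touching the thresholds around it. A
pass-rate-calibrated cutoff (retaining only candidates whose rank
discordance would be this small under independence with probability
`idr_threshold`) was evaluated and rejected: whenever replicate scores
have narrow dynamic range -- which is exactly the synthetic regime --
it rejects essentially everything, including perfectly reproducible
planted peaks.

**Annotation.** Within one gene, the label priority is tRNA > miRNA >
miRNA-proximal (500 nt) > CDS > 3'UTR > 5'UTR > 5' splice site (100 nt)
> 3' splice site (100 nt) > proximal intron (500 nt) > distal intron >
noncoding exonic; across genes each gene is first reduced to its best
label and the cross-gene order (tRNA > miRNA > CDS > 3'UTR > 5'UTR >
miRNA-proximal > noncoding exonic > 5'ss > 3'ss > proximal > distal) is
applied to those. Overlap is >= 1 nt on half-open intervals, same strand
only; peaks outside all genes are `intergenic` (a documented extension:
every peak gets exactly one label). The test suite checks all 242
ordered label pairs against an independent rule table.

# RBNS enrichment and motif logos

R values are pulldown over input k-mer frequencies with overlapping
occurrences counted (the masking step speaks of *all* occurrences, so
counting must see them too); 0.5 pseudo-occurrences per k-mer keep R
finite. Two identities are asserted to numerical precision on every
profile: $\sum_k q_k R_k = 1$ and Z standardization (mean 0, sd 1).

The logo algorithm: repeatedly take the most enriched 5-mer on the
current masked libraries, give it weight R - 1, mask all its occurrences
in both pulldown and input (masking writes N, which can seed no k-mer,
so no chimeric k-mers form across mask boundaries), and recompute;
stop when the candidate's Z-score -- always computed from the original,
unmasked R values -- drops below 3 (2.8 for eCLIP logos, the threshold
that makes eCLIP logos comparable in size). Accepted 5-mers join the
first motif whose seed they match with mismatches + |offset| <= 2
(ties: lower cost, then smaller |offset|, then upstream; the exact
tie-break is unstated in any published account, so it is fixed here for
reproducibility), otherwise they seed a new motif. PWMs weight covered
positions by the 5-mer weights, give unaligned flank positions 25% per
nucleotide, and trim outer positions with more than 75% unaligned
weight. Robustness: the pools are split in half (replicate peak sets for
eCLIP) and a full-data 5-mer enters the final logos only when both
halves independently recovered the same motif -- membership is judged by
alignment within cost 1 (one shift or one mismatch), not exact 5-mer
identity, because full masking makes the choice among shifted variants
of one motif (UGCAU versus GCAUG for a planted UGCAUG) a coin flip
between halves; tolerance beyond cost 1 would let unrelated noise
5-mers corroborate each other in null pools. Final logos are built with
full-data weights.

Ties at the top R value resolve to the lexicographically smallest k-mer,
so runs are reproducible.

# Splicing maps

Events pass at p < 0.05, FDR < 0.1, $|\Delta\psi| > 0.05$, split by
direction; native events are the non-significant skipped exons with
control inclusion strictly between 0.05 and 0.95. The meta-region is
four splice-site-anchored blocks of 50 exonic + 300 intronic nt
(matching the visual extent of standard splicing-map figures; fully
configurable), oriented 5'-to-3' and masked -- not zero-filled -- where
a window runs past its feature. Per-position density is IP minus input
in reads per million; the combiner is a function argument because the
input-normalization inside published splicing-map tooling is not
specified at this level, and subtraction of two RPM tracks is the
simplest choice that is linear and null-centred at zero.

The map subtracts the native-event mean; the uncertainty band is the
0.5th/99.5th percentile of means over 1,000 samplings of native events
of matched size. Samplings are drawn **with replacement**: a
without-replacement draw of $n$ from $N$ natives shrinks the variance of
the resampled mean by the finite-population factor $(N-n)/(N-1)$ and
makes the band anti-conservative (measured: 3-7% of null positions
escape a 99% band instead of the nominal ~1%). With replacement, the
resampled mean has the variance of an independent event set of that
size, and measured null escape is ~1.4% with 2,000 natives. Note the
residual inflation when the native pool is small: the native mean's own
sampling noise enters the map but not the band, so calibration holds in
the regime where natives far outnumber events -- the realistic one.

Map correlation concatenates the KD-included and KD-excluded vectors,
using only classes present on both sides (a class is absent when its
event count fell below the minimum, 100 skipped exons or 50 alternative
splice-site events). Cross-RBP maps reuse the same machinery with
another RBP's densities, and the class envelope reports the mean with a
10th-90th percentile spread.

# Integration statistics

Differential expression is strong/moderate/weak at $|\log_2 FC|$ of 2
and 1; splicing at $|\Delta\psi|$ of 0.30 and 0.15 (events at or below
0.05 are not classified). Tandem-UTR calls require |Bayes factor| >= 5
and p < 0.05 on both grouped orderings of the four pairwise comparisons
(higher-read knockdown vs lower-read control, and the reverse).

Binding-expression overlap uses the Fisher/Yates chooser above on an
abundance-matched background (genes whose region passed the 10-read
eligibility rule), runs only when more than 10 genes changed, and
Bonferroni-adjusts over the comparisons actually executed -- skipped
comparisons do not enter the family denominator. ChIP comparisons:
base-level Jaccard indices within promoter (1-kb TSS windows) and
non-promoter space; signal enrichment at eCLIP peaks against flanks ten
peak-lengths per side (one-sided Wilcoxon rank-sum, p <= 0.001, no
multiplicity correction, as stated for the original analysis); and the
resampled dependence test -- each round pairs every TSS-bound gene with
a TPM-decile-matched unbound gene, one-tailed Fisher on the 2x2, with
dependence declared at >= 95 rejections out of 100 rounds. Decile
matching operationalizes "similar expression" consistently with the
matched-control procedure for skipped exons, which also matches on
deciles of wild-type expression and inclusion.

Wilcoxon tests are delegated to `stats::wilcox.test` (exact for small
untied samples, normal approximation with continuity and tie correction
otherwise) rather than re-implemented.

Spliced reads must span an annotated junction with >= 10 nt in each
exon; unspliced reads must cross an exon-intron boundary with >= 10 nt
on each side; the classes are mutually exclusive and reads under 20 nt
are never classified. RBPs are nuclear at nuclear:cytoplasmic ratio
>= 2, cytoplasmic at <= 0.5.

# Problem sizes and the pipeline demonstration

`run_pipeline()` exercises every stage on one seeded synthetic data set
and writes TSV/BED outputs plus a JSON manifest of file digests; reruns
with the same configuration and seed are byte-identical. The default
configuration uses 80 genes, 2x10^5 read pairs per library, 3x10^4 RBNS
reads, 600 splicing events with 110 regulated, 1,000 native samplings
and 100 resampling rounds -- sizes at which every stage has signal to
find while a full run stays interactive. Planted elements in the demo
use fold 16 with 20 additional 3'UTR elements: a planted fold equal to
the 8-fold peak threshold sits exactly on the calling decision boundary,
which is the wrong place to demonstrate the pipeline; the calibration
and recovery tests plant the canonical values (lambda 8, s 10, dpsi 0.3)
via dedicated truths.

# Known limitations

- The reproducibility scorer is a rank-consistency surrogate with quota
  semantics, not a fitted mixture posterior; inject a full
  irreproducible-discovery-rate implementation for production use on
  real replicate score distributions.
- The read simulator is uniform within region weights: no crosslink
  pileups, no fragment-length model, no sequence bias. Estimator
  behaviour under those artefacts is untested by design.
- The background-peak sampler preserves the distance to the nearest
  region boundary for CDS/intron peaks using the track the peak falls
  in; nested isoform structures with conflicting boundaries fall back
  to the containing track's edges.
- Mutually-exclusive-exon and retained-intron classes reuse the density
  machinery only (no dedicated meta-region geometry), matching the
  package's skipped-exon/alternative-splice-site focus.
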