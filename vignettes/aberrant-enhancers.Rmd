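---
title: "Identifying aberrant enhancers in paired tumor/normal designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying aberrant enhancers in paired tumor/normal designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancerAE)
```

## The problem and the model

Enhancers are distal regulatory elements marked by H3K4me1 (with
H3K27ac when active) whose dysregulation — by DNA methylation change,
histone-modifier dysregulation, or altered enhancer transcription — is a
recurring feature of hepatocellular and other carcinomas. `enhancerAE`
implements an integrative pipeline over paired tumor/normal cohorts
that:

1. builds a merged enhancer catalog from per-sample histone-mark peaks
   and chromatin-state calls, recording each merged enhancer's
   *concurrence* (the number of samples supporting it);
2. calls differentially expressed enhancers (DEEs, via enhancer RNA),
   differentially expressed genes (DEGs), and differentially methylated
   loci/regions (DML/DMRs) with a paired test;
3. links intergenic DEEs to DEGs whose TSS lies within 1 Mb of the
   enhancer center through Spearman correlation (rho >= 0.7,
   Bonferroni p < 0.01), and genic differentially methylated enhancers
   (DMEs) to DEGs through methylation-expression correlation
   (|rho| >= 0.5, BH-FDR <= 0.01);
4. scores cross-cohort concurrence of DEEs and links, and
   platform-aware replication of DME-DEG pairs (raw and
   platform-adjusted rates);
5. confirms enhancer-gene pairs against TAD/loop topology and applies a
   six-gene risk score with a log-rank-minimizing cutoff.

Every stage is driven by a synthetic-data generator with planted ground
truth, so the full pipeline is testable offline.

## Differential testing

All expression matrices are normalized to fragments per million
(FPM = count / library size x 1e6) and tested on the log2(FPM + 1)
scale with a per-feature paired t-test across patients, followed by
Benjamini-Hochberg correction across features. Thresholds follow the
discovery protocol: |log2 fold change| > 0.5 (strict) and BH-FDR < 0.05
for DEEs and DEGs, |LFC| > 1 for the histone-modifier screen. Gene-level
differential expression deliberately uses the *same* paired t-test as
the eRNA stage rather than a shrinkage-based count model: one defined
test keeps discovery and replication cohorts exactly comparable and the
pipeline self-contained; the cost is somewhat less power at small
counts, which the planted-effect recovery tests quantify.

Degenerate features are handled explicitly: all-zero paired differences
give p = 1, constant nonzero differences give p = 0, both with a
message. The log2 pseudocount is 1 throughout.

Methylation uses paired t-tests on beta values directly. A DML is a CpG
with BH-FDR < 0.05 and |mean delta-beta| >= 0.1; a DMR is a maximal run
of >= 5 same-direction DMLs with consecutive gaps <= 500 bp. These
three DMR parameters are explicit package defaults (all configurable),
chosen to harmonize with the genic-DME requirement of at least five
CpGs; they are deliberately simple rank-based substitutes for
smoothing-based DMR callers, which are out of scope.

## Catalog construction choices

* Overlap semantics are >= 1 bp everywhere: H3K4me1/H3K27ac
  active-classification, promoter exclusion, and genic classification.
  Book-ended intervals merge, matching default interval-merge behavior.
* Promoters span 1,500 bp upstream to 500 bp downstream of the TSS,
  strand-aware (computed with `GenomicRanges::promoters()`).
* Merged enhancers shorter than 50 bp or overlapping any promoter are
  removed; the genic/intergenic partition uses the transcript span.
* Whole H3K4me1 peaks are classified active when any H3K27ac overlap
  exists; sub-region classification is a documented alternative we did
  not adopt.
* Samples without H3K27ac contribute peaks with state `unknown`; they
  still count toward concurrence, mirroring designs where one sample
  lacks the second mark.
* All on-disk coordinates are 0-based half-open BED; GRanges conversion
  happens at the package boundary.

## Linking choices

* The Bonferroni family for intergenic links is the set of
  distance-eligible (DEE, DEG) pairs actually tested — the method
  section of typical studies leaves the family implicit, and this is
  the most conservative defensible choice.
* The intergenic criterion rho >= 0.7 is positive-only (as printed);
  the genic criterion uses |rho| >= 0.5, so anti-correlated
  methylation-expression links are retained.
* Genic DME distance is measured from the nearest enhancer edge to the
  TSS; intergenic distance from the enhancer center.
* The ">= 5 CpGs" DME gate counts CpGs inside the enhancer-DMR overlap
  (configurable to whole-enhancer counting).
* eRNA-methylation and gene-methylation correlations use the mean beta
  across the enhancer per sample.
* Super-enhancer clusters chain same-direction DEEs along a chromosome
  while consecutive gaps stay <= 50 kb and each new member shares a
  linked DEG with the chain. The 50 kb default is chosen so a
  representative ~344 kb cluster of 35 enhancers (~10 kb mean gap)
  chains into one unit. The reported DEG set is the union over members;
  a strict mode intersects instead (every member linked to every
  reported gene). Clusters are reported at >= 5 members and >= 5 DEGs.
* Direction consistency between a DEE and its linked DEG is *not*
  imposed beyond the positive-rho gate.

## Replication scoring

Concurrence of a DEE is 1 + the number of replication cohorts calling
it significant *in the same direction*; direction-blind counting would
inflate concurrence. A link's concurrence additionally requires the DEG
(same direction) and the link criteria in that cohort.

For genic DME-DEG pairs replicated on a sparse methylation platform
(450k-array-like), failures split into type I (no covered CpG in the
DME — untestable) and type II (covered but not significant). The raw
replication rate is 100 x successes / total; the platform-adjusted rate
is 100 x successes / (successes + type II), which discounts pairs the
platform could never test. Rates are computed in full precision and
rendered to two decimals; empty categories report NA, never 0.

## Downstream analyses

TAD confirmation asks whether the enhancer center and the target TSS
fall in the same TAD (point containment; any one TAD suffices when TADs
overlap — whole-interval containment is available as a strict mode);
loop confirmation requires the enhancer to overlap one anchor and the
TSS the other, in either orientation. Gene-set enrichment is a
hypergeometric upper tail over a user-supplied background with BH
correction, reading standard GMT files.

The prognostic score is a fixed linear combination over six genes
(PLOD2 0.424, HOXD9 0.109, BOP1 0.184, RAB26 -0.134, KLRK1 -0.185,
RGL4 -0.0547). The expression scale feeding the score is
caller-supplied; consequently any absolute cutoff is scale-dependent
and the package's cutoff search operates on the observed scores: it
scans candidate cutoffs between the 10th and 90th score percentiles
(bounds that prevent degenerate splits), minimizes the two-group
log-rank p-value, and breaks ties toward the median. Cox/LASSO
coefficient estimation, nomograms and time-dependent ROC are out of
scope; coefficients are taken as constants.

## What the generator emulates — and what it does not

`sim_config()` defaults encode the emulated study design: 33
tumor/normal pairs profiled for RNA and methylation, 11 ChIP-seq
samples (one without H3K27ac), about a third of enhancer calls active,
just over half of merged enhancers concurrent in >= 2 samples, planted
expression effects of |log2FC| = 2, planted methylation effects of
|delta-beta| = 0.3, target link correlation 0.95, and 1 Mb TADs.

Counts are negative binomial around a log2-scale mean combining a
per-feature baseline, a per-patient factor shared by the tumor and
normal libraries of a patient, heavy independent per-sample noise, the
planted tumor shift, and — for planted links — a per-patient latent
factor shared between the enhancer's eRNA and its target gene. Two
modelling points deserve emphasis:

* The shared latent is patient-level, so it cancels in paired tests
  (planted links remain detectable as DEEs/DEGs) while still inducing
  cross-sample correlation.
* The independent per-sample noise is deliberately large (sd 1.5 log2
  units). Two co-differential but *unlinked* features are correlated
  across a tumor/normal cohort through their common tumor shift alone;
  the noise keeps that nuisance correlation around 0.3, well below the
  0.7 retention gate, which is what makes linking precision a
  meaningful quantity. The latent scale is derived from the target
  correlation and capped so that count dynamics do not saturate at
  zero; the realized median Spearman of planted links is ~0.85-0.9
  (targeted, not exact).
* Each planted link owns its enhancer, gene, and latent factor
  exclusively; otherwise shared genes would dilute realized
  correlations.

Methylation betas are clipped normals around a per-CpG baseline
(simpler than beta-binomial sampling and adequate for the rank
statistics used downstream). Planted DMR directions for
methylation-associated DEEs follow the classical coupling (hypo with
activation); DME links cover all four hyper/hypo x up/down categories,
with the latent coupling signed so tumor shifts and the latent
reinforce one another.

Planted DEE directions are split 50/50 between activated and repressed
so every category of downstream logic is exercised; real tumor cohorts
can be strongly skewed toward activation, and the generator makes no
attempt to reproduce that skew, nor GC/mappability structure, read-level
noise, or realistic genome coordinates. Passing the planted-truth tests
therefore demonstrates the *correctness of the statistical machinery*
under a plausible generative model, not performance on real sequencing
data.

Sub-50 bp planted templates are emitted without positional jitter so
the planted length-filter violations remain below threshold after
union-merging; all other peaks are jittered by up to 25 bp per edge,
which is small relative to the >= 800 bp separation the genome layout
guarantees, so merged catalog intervals correspond 1:1 to templates and
concurrence can be validated against the generator's bookkeeping.

Survival defaults to exponential times with hazard proportional to
exp(score); a threshold variant with a hazard jump at a planted score
cutoff exists to exercise the cutoff search. Problem sizes used
throughout the tests — 2 x 10 Mb chromosomes, 160 genes, 300 template
enhancers, 600 genes for null calibration, a 200-patient survival
cohort — are the package's chosen simulation scale: large enough for
stable error-rate estimates (>= 500 null features for type-I checks),
small enough that the whole suite re-simulates everything from seeds.

## Numerical and degenerate-input conventions

* Spearman correlations use average ranks for ties and the
  t-approximation for p; constant vectors return rho = 0, p = 1 with a
  message.
* BH and Bonferroni corrections go through `stats::p.adjust` /
  `pmin(1, m p)` with the family size always stated by the caller.
* Thresholds are strict or non-strict exactly as the calling rules
  state: |LFC| > 0.5, FDR < 0.05, rho >= 0.7, |rho| >= 0.5,
  FDR <= 0.01, overlap >= 200 bp, fraction >= 0.3, >= 5 CpGs, length
  >= 50 bp (i.e. < 50 bp excluded), long enhancers > 3 kb.
* The log-rank statistic is computed by `survival::survdiff` and
  checked in the tests against an independent hand implementation of
  the observed-minus-expected arithmetic.
* Cutoff-search ties (p within 1e-12) resolve toward the median score.

## Known limitations

* The paired t-test on log2 counts has no dispersion shrinkage; very
  small cohorts (< ~10 pairs) will be underpowered relative to
  count-model approaches.
* The DMR caller does not smooth and will fragment regions whose DMLs
  drop below the FDR gate mid-run.
* Replication requires cohorts to share the discovery catalog's
  feature identifiers; probe-to-region mapping for real array
  annotation files is out of scope.
* Hi-C confirmation treats TADs as given intervals; nested/overlapping
  TAD structure is honored only through the "any containing TAD" rule.
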