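---
title: "Methods: linking differential methylation to lncRNA and cis-target expression"
author: "dmrlinc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking differential methylation to lncRNA and cis-target expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Tissue studies that pair whole-genome bisulfite sequencing (WGBS) with
RNA-seq on the same case/control cohort allow a cascade of cis-regulatory
inferences: differentially methylated regions (DMRs) between groups, long
non-coding RNAs (lncRNAs) whose expression tracks the methylation of a
nearby DMR, and protein-coding transcripts whose expression in turn tracks
a nearby lncRNA. `dmrlinc` implements that cascade as a tested pipeline —
coverage filtering, DMR calling, differential expression, windowed
correlation integration, cell-type deconvolution and cross-dataset
verification — together with a synthetic-data generator that plants a known
regulatory chain, so every stage can be validated without access to any
restricted cohort.

The discovery rule at the heart of the pipeline is deliberately simple and
mirrors common practice in integrative epigenomics:

* a lncRNA is *DMR-regulated* when its transcript lies within 20 kb of a
  DMR and its normalized expression is negatively correlated with the DMR's
  per-sample mean methylation (Pearson, raw $p < 0.05$, $r < 0$);
* a protein-coding transcript is a *cis target* when it lies within 500 kb
  of a DMR-regulated lncRNA and its expression is negatively correlated
  with the lncRNA's ($p < 0.05$, $r < 0$).

Each surviving (DMR, lncRNA, protein) combination is emitted as a
*triplet* carrying both correlations, both distances and both effect
directions.

## Stage models and assumptions

### Coverage filtering

Per CpG and sample, coverage below 6× is treated as *missing* (counts
zeroed) rather than as 0% methylation — counting a shallow site as
unmethylated would bias region means downward. A site is kept only when at
least 50% of the samples in *each* group have ≥ 6× coverage. Both
thresholds are exposed (`min_cov`, `min_frac`).

### DMR calling

The caller is a documented, simplified substitute for smoothing-based WGBS
callers (the stage contract — intervals, q-values, per-sample region betas
— is what downstream stages consume; externally called regions can be
injected via `dmr_bed` to bypass it entirely):

1. per-site group difference $d_i = \bar\beta_{case,i} - \bar\beta_{ctrl,i}$,
   smoothed by a centered running mean over $k = 5$ neighboring CpGs
   within a chromosome (partial windows at edges, missing sites skipped);
2. candidate regions are maximal same-sign runs with $|d_i| > 0.1$,
   inter-CpG gaps ≤ 1000 bp and ≥ 5 CpGs, **trimmed** at both ends to the
   outermost CpGs whose *raw* difference also exceeds the cutoff;
3. the region statistic is the coverage-weighted **mean** smoothed
   difference $\sum_i w_i d_i / \sum_i w_i$ ($w_i$ = total coverage);
4. significance comes from a genome-wide max-statistic label-permutation
   null: each of 100 random group-label permutations is re-analyzed
   end-to-end and its largest $|stat|$ recorded; a region's p-value is the
   $+1$-smoothed fraction of permutation maxima at or above its own
   $|stat|$, and q-values are Benjamini–Hochberg over candidates, with
   $q < 0.05$ flagged significant.

Two of these choices deserve justification because the design was
genuinely open:

*Trimming (step 2).* The running mean bleeds a strong region's signal into
1–2 flanking background CpGs. At realistic background CpG spacing those
flanks sit hundreds to thousands of bp away, so untrimmed intervals can be
several times longer than the underlying region, which destroys
reciprocal-overlap-based evaluation (and inflates the interval handed to
every downstream window). Trimming to raw-supported CpGs is the standard
boundary-refinement remedy.

*Mean rather than additive statistic (step 3).* With an additive statistic
$\sum_i w_i d_i$, larger regions get larger statistics at identical effect
size. The permutation null then has a severe size bias: label permutations
that partially align with the true grouping (hypergeometric overlap 9–10
of 11 cases, which occurs a few times per 100 draws) let the *largest*
true regions re-emerge with 2/3–5/6 of their effect, and those null maxima
swamp the statistics of smaller true regions. Empirically this capped
sensitivity at ~2/3 with Poisson-distributed region sizes. The
coverage-weighted mean equalizes power across sizes; since no non-identity
permutation of an 11/13 cohort can reproduce a full group difference, true
regions dominate every permutation maximum. The minimum-region-size and
cutoff rules retain the guard against small noise runs.

### Differential expression

A two-group negative-binomial Wald test standing in for full DE machinery:
median-of-ratios size factors; per-transcript dispersion $\alpha$ by
method of moments on size-factor-normalized counts, estimated *within*
groups (df-weighted) so a real group effect is not booked as dispersion,
floored at $10^{-8}$; an NB log-link GLM with log size factors as offset,
fit by IRLS at fixed $\alpha$; Wald p-values from the normal
approximation. No dispersion shrinkage or fold-change moderation is
attempted — the correlation cascade only needs calibrated per-transcript
tests (empirical type-I error at nominal 0.05 is ~0.06 at $n = 24$,
$\mu = 100$, $\alpha = 0.05$). DE selection uses strict thresholds
`padj < 0.05` and `|log2FC| > 0.5`; the 0.5 is interpreted on the log2
scale, consistent with standard DE output conventions. Normalization for
all correlation stages is `log2(count/sf + 1)`, a variance-taming
monotone transform; nothing downstream depends on more than monotonicity
plus rough variance stabilization.

### Integration

Distances are measured span-to-span (transcript body vs region interval)
on the same chromosome, zero when overlapping; strand is ignored
throughout. Correlations are Pearson (Spearman behind a flag), with
pairwise deletion of samples missing a region beta and a t-distribution
p-value on $n-2$ df. The discovery filter uses *raw* p-values at 0.05 —
deliberately replicating the common single-pair testing practice —
while BH-adjusted values are reported as an extra column so users can
apply FDR control if they wish. A lncRNA correlated with several DMRs
appears once per pair; both pair-level and distinct-lncRNA counts are
recoverable from the output.

### Deconvolution

DMRs are mapped onto reference probe loci by coordinate containment
(half-open; first locus by coordinate when several hit, averaging behind a
flag), and each sample's DMR-beta vector is regressed on the reference
cell-type profiles by Huber M-estimation (tuning constant 1.345, ≤ 50
iterations, no intercept). Negative coefficients are truncated to zero
and the rest renormalized to the simplex. The reference profile is an
input, never shipped data.

### Verification

Discovered (lncRNA, protein) pairs are re-correlated in independent
normalized matrices with the *same* `correlate()` implementation as
discovery. Confirmation requires the discovery rule ($r < 0$, $p < 0.05$)
by default; a two-sided "any significant correlation" mode exists because
a plausible reading of the verification step is sign-agnostic.
Confirmation fractions are computed only over datasets where both
identifiers are present (denominator discipline); unmatched identifiers
are surfaced, not fuzzy-matched.

## The synthetic-data generator

`sim_config()` defaults state the emulated world: 11 case vs 13 control
samples; planted DMRs averaging 288 bp and 15 CpGs (both Poisson);
a planted group difference $\Delta\beta = 0.3$; Poisson(30) coverage;
beta-binomial methylation counts with overdispersion $\rho = 0.02$;
negative-binomial expression with $\alpha = 0.05$; 30 planted
DMR→lncRNA→protein cassettes and 150 + 150 decoy transcripts. Where the
emulated study reports no value, defaults were chosen once as typical for
mucosal WGBS/RNA-seq cohorts and are not revisited: a 2 × 25 Mb toy
genome and 20 000 background CpGs (real WGBS is ~100× denser; scaled for
desk runtime), background baselines U(0.2, 0.8), base expression means of
200 counts.

The planted causal chain is
$\beta_{d,s} \to \text{lncRNA}_{j,s} \to \text{protein}_{k,s}$:
lncRNA log-means are $a_j + c_{lnc}\,\beta_{d,s}$ with $c_{lnc} = -4$ on
the *realized* per-sample region beta, and protein log-means are
$c_k + c_{prot}\, z_{j,s}$ with $c_{prot} = -1$ on the standardized log of
the *realized* lncRNA count — so the protein is coupled to the lncRNA,
not directly to the DMR, matching the interpretation that the lncRNA
mediates. Decoys have group-independent means, and half of them are
placed *inside* cassette windows so that window filtering alone cannot
recover the truth; correlation filtering must do the work.

Planted cassettes are spaced at least 2.2× the 500 kb protein window
apart, so cassettes cannot cross-pair by construction. Real genomes are
not like this — neighborhoods overlap, and a transcript can sit in several
DMRs' windows — which is precisely what makes attribution ambiguous in
real data. A green recovery test therefore establishes that the pipeline
recovers an *identifiable* planted chain at the stated effect sizes; it
does not establish attribution performance under overlapping regulatory
neighborhoods, batch effects, read-level artifacts or strand-specific
methylation, none of which are simulated.

## Numerical choices and degenerate inputs

* Permutation p-values use the $+1/(n+1)$ estimator, so zero p-values are
  impossible and q-value granularity is $1/(n_{perm}+1)$.
* `bh_adjust` is the exact step-up with cummin monotonicity enforcement;
  note that BH is *not* idempotent in general (re-adjusting an adjusted
  vector can only move values up), so adjusted columns must never be fed
  back through it.
* All-zero transcripts get $p = 1$, $\log_2 FC = 0$; IRLS that fails to
  converge in 100 iterations is flagged and set to $p = 1$ with a warning;
  linear predictors are clamped to $\pm 30$ to survive one-group-zero
  transcripts.
* Correlations with fewer than 3 complete pairs or zero variance are
  excluded with a warning rather than reported.
* Exact case/control beta ties classify as hypo, with a warning.
* Regions losing every CpG to the coverage filter are dropped with a
  warning; samples with no surviving CpG in a region get a missing beta
  and are removed pairwise in correlations.
* Gzip is detected by magic bytes, not extension, and written with a
  zeroed timestamp so identical simulations are byte-identical.

## Known limitations

The DMR caller is not a replacement for purpose-built WGBS callers: it has
no biological-variance smoothing, no covariates and a single-resolution
running mean. The DE stage has no dispersion shrinkage, so very-low-count
transcripts are noisier than in mature DE packages. Raw-p correlation
filtering (inherited from the discovery rule the pipeline replicates) does
not control FDR over pairs — use the reported BH columns when that
matters. Verification assumes identifier compatibility up to an alias
table. Trans-chromosomal regulation, TSS-anchored windows (available
behind a flag but untested against truth), and 3D-conformation-aware
target assignment are out of scope.
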