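---
title: "Methods: gamma-delta TCR repertoire analysis with gdrepertoire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gamma-delta TCR repertoire analysis with gdrepertoire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model of the data

`gdrepertoire` analyses bulk-sequenced T-cell receptor gamma (TRG) and
delta (TRD) repertoires that arrive as clonotype tables: one row per
rearrangement with a read count, the CDR3 junction in nucleotides and
amino acids (anchored by the conserved cysteine and phenylalanine), V/D/J
segment calls, and 0-based junction coordinates relative to the CDR3
nucleotide string (-1 meaning undefined). Read-level processing
(alignment, assembly, UMI handling) is out of scope; the package consumes
tables in AIRR Rearrangement TSV or an 11-column legacy dialect and treats
stored frequency columns as advisory, always recomputing frequencies from
counts. Gene calls are truncated at the allele separator (`TRGV9*01` to
`TRGV9`) and multi-call fields keep the first call, because every
downstream statistic operates at segment level.

## Quality control and error correction

Library-level QC rejects a library when any rule trips: fewer than
`min_reads` total reads (default 1000), at most `min_clonotypes`
clonotypes (default 10), or an off-target TRA/TRB read fraction above
`max_offtarget_fraction` (default 0.5). Cohorts of this kind rarely come
with published cut-offs, only with the values of the libraries that were
kept or discarded (in the motivating cohort, a discarded blood library
had 26 reads against a median near one million; others had 7-10
clonotypes, or 67-91% off-target reads against a 12.5% median). The
defaults are chosen to separate those kept/discarded values and are
fully configurable.

Clonotype-level cleaning then runs in a fixed, documented order:
functional filtering (out-of-frame or stop/frameshift-containing CDR3s
are dropped; when no explicit flag is present, functionality is derived
as "nt length divisible by 3 and no `*`/`_` in the aa string"), segment
restriction (only functional TRGV2/3/4/5/8/9 and TRDV1-8 are kept;
pseudogenes such as TRGV10 and TRAV-incorporating hybrids are removed),
and finally error-correction merging. A low-abundance "child" clonotype
is absorbed by the highest-count "parent" with identical V, J and CDR3
length, Hamming distance at most 1 and a child/parent count ratio at most
0.1. There is no field-wide standard for the mismatch and ratio
parameters; the defaults follow common repertoire error-correction
practice. Children are scanned in ascending count order
with lexicographic tie-breaks, and the scan is repeated until no merge
applies: this makes the operation idempotent (a strict single pass cannot
guarantee idempotence, because an absorbing parent's growth can newly
qualify a remaining pair) while leaving all simple cases unchanged.
Merging conserves total reads exactly. Neighbour search uses the fact
that a Hamming-1 pair must agree exactly on one half of the sequence;
the half-bucketing kernel is compiled (see `src/`).

## Repertoire statistics

Segment usage, V-J pairing, spectratypes and mean CDR3 length support two
weightings: `reads` (clone-frequency weighted, the default, matching how
chord diagrams and spectratype figures are usually drawn) and
`clonotypes` (each distinct clonotype counts once). Pooled V-J profiles
average per-sample profiles with equal weight per sample, so deep
libraries do not dominate. Junctional (NDN) inserts are computed from the
junction coordinates with negative gaps clamped to zero, since
exonucleolytic overlap is not negative insertion; rows lacking the needed
coordinates yield `NA` and are excluded from aggregates. TCR convergence
is the number of distinct nucleotide clonotypes divided by the number of
distinct amino-acid groups, keyed within (V, J) context so identical
CDR3s on different segments are not conflated; the underlying published
definition is silent on segment context, and the aa-only variant can be
obtained by rekeying, but the contextual form is the default and the one
tested.

## Diversity and clonality

The estimators operate on the frequency-of-frequencies spectrum `f_k`
(how many clonotypes occur exactly `k` times):

* Shannon-Wiener: `-sum p_i ln p_i` in nats by default (repertoire tools
  use both natural and base-2 logs, so the base is a parameter).
* Inverse Simpson: `1 / sum p_i^2`.
* Chao1: `S_obs + f1^2 / (2 f2)`, falling back to the bias-corrected
  `S_obs + f1 (f1 - 1) / 2` when no doubletons exist.
* Efron-Thisted: `S_obs` plus the truncated alternating series
  `sum_k (-1)^(k+1) f_k` up to `min(max k, 20)` terms; when the series
  does not decay (`|f_K| > |f_1|`) the Euler transformation is applied,
  and the correction is floored at zero.
* D50: the fraction of clonotypes, ranked by decreasing abundance, needed
  to reach 50% of reads.

Frequency compartments partition (0, 1] into small (at most 0.05%),
medium (0.05-0.5%], large (0.5-5%] and hyperexpanded (above 5%), with the
boundary membership chosen so the four ranges partition (0, 1] — published
descriptions of such compartments sometimes print non-contiguous edges,
and a partition is the only self-consistent reading. Both a
clonotype-count fraction and a read-space fraction are reported per bin
because a "proportion of small clonotypes" is ambiguous between the two.
Diversity can be computed on whole
samples and on within-segment renormalised sub-repertoires (frequencies
rescaled to sum to 1 per V segment), making per-segment diversity
independent of the segment's overall share. No rarefaction is applied by
default (a `downsample` option exists); skin libraries are shallower and
under-sampling caveats apply to cross-tissue comparisons.

## Overlap and publicity

Clonotype keys are `(V, J, CDR3)` triples on the amino-acid basis by
default (how clonotypes are conventionally named), with a nucleotide
basis available. A key is *public* when seen in at least two distinct
subjects — paired blood/skin samples of one person never make a key
public. Pairwise similarity is the Jaccard index on key sets, which is
deliberately frequency-blind. Paired blood-skin tables report both
compartment frequencies and their arithmetic mean.

## Nonparametric association

Spearman correlation, the Mann-Whitney U test and Fisher's exact test are
delegated to R's `stats` implementations, whose conventions match what
this pipeline needs: exact enumeration for small samples without ties
(Spearman n <= 9, smaller Mann-Whitney group <= 8), the t-approximation
`rho sqrt((n-2)/(1-rho^2))` and the tie-corrected continuity-corrected
normal approximation otherwise, and the minimum-likelihood two-sided
convention for Fisher's test — the dominant convention in the field and
the one that reproduces the motivating cohort's CMV-serostatus result
(p = 0.031). Multiple testing uses Benjamini-Hochberg, applied within
each feature family. For age correlations in the patient group, the
`k_oldest` (default 4) oldest patients above the oldest control's age are
excluded first, because no age-matched controls exist for them; both the
count and the rule are parameters.

## The synthetic cohort generator

`sim_config()`/`generate_cohort()` produce cohorts with known ground
truth so every pipeline stage can be validated end to end. What the
defaults emulate, and the one-time choices behind them:

* **Usage priors.** Blood TRG is dominated by TRGV9-TRGJP (prior 0.55,
  with TRGV9-TRGJ2 at 0.10 and the remainder spread over TRGV2/3/4/5/8);
  blood TRD by TRDV2-TRDJ1 (0.60) with TRDV1 and TRDV3 minorities. Skin
  priors are near-uniform over the functional TRGV segments with a TRGJ2
  skew, and balance TRDV1/TRDV2. These are qualitative targets matching
  typical published blood/skin usage profiles, not asserted values.
* **CDR3 lengths** are per-segment discrete-Gaussian mixtures on
  amino-acid length: TRGV9 centred at 15 (sd 1.6), the other TRGV at 13
  (sd 1.3) — which places roughly 70-85% of blood TRG read mass in the
  13-17 aa window — bimodal TRDV1 (13/17) and TRDV3 (12/16), unimodal
  TRDV2 at 16 aa (about 48-51 nt).
* **Clone sizes** follow a truncated discrete power law (exponent 2.5 by
  default), the standard heavy-tailed model for clone-size distributions,
  realised by multinomial sampling at the library depth.
* **Richness and covariates.** A patient's expected blood richness is
  `exp(log richness_base + beta_pasi z(PASI) + beta_age z(age))` with
  lognormal subject noise (sd 0.25); controls receive the base richness.
  Defaults `beta_pasi = beta_age = -0.5` encode severity- and age-driven
  repertoire contraction. Covariates: age normal (patients 44 +/- 12,
  controls 38 +/- 10, truncated), PASI lognormal with median 16, disease
  duration lognormal with median 9 years, CMV IgG a seronegative spike
  plus a positive lognormal, sex 75% male — matching the motivating
  cohort's marginal distributions.
* **Scale.** Defaults are desk scale: 20 patients and 15 controls, 20000
  reads per blood library and 2000 per skin library, base richness 900
  (matching the ~930 distinct blood clonotypes per library typical of
  such cohorts), skin richness 8% of blood. Real libraries are roughly
  25-fold deeper; depth only sharpens the same structure.
* **Imperfections.** 1.5% of clonotype identities are out-of-frame
  passengers (down-weighted 10x, as nonsense-mediated decay suppresses
  out-of-frame transcripts) and 0.5% use pseudogene/TRAV-hybrid segments
  (down-weighted 3x); together they cost 1-3% of reads at filtering,
  inside the 95-99% read-retention band typical of this cleaning. 1% of
  reads are re-emitted as 1-mismatch singleton error children whose reads
  are taken from their parents (so depth is exact). Expanded clonotypes
  carry a synonymous nucleotide variant with probability
  `convergence_rate` (default 0.15). A germline-like public pool (five
  TRGV9-TRGJP, three TRGV4-TRGJ2, one TRGV2-TRGJ2 and two TRDV2-TRDJ1
  sequences, including CALWEVQELGKKIKVF) is injected into each subject's
  blood with probability 0.5 using one fixed codon realisation, so pool
  clonotypes are shared at the nucleotide level too.

What the generator does **not** emulate: biophysically realistic VDJ
recombination, thymic selection, and — importantly — the broad
convergent-recombination background that makes real blood TRG
repertoires substantially public (reported public fractions near 19% in
blood TRG). Synthetic background CDR3s are random, so publicity comes
only from the injected pool and the realised public fractions are far
smaller than real ones (TRG still more public than TRD, preserving the
qualitative ordering). Tests therefore validate publicity *mechanics*
against injected ground truth, not published public percentages; the same
caution applies to any cohort-derived number, which depends on the
deposited sequencing data rather than on this package.

## Numerical choices and degenerate inputs

Frequencies must sum to 1 within 1e-6 and all profile outputs renormalise
to 1 within 1e-9; empty repertoires yield empty profiles rather than NaN,
and single-sample publicity or mean length of an empty sample are flagged
errors. D50 uses a stable descending sort with a 1e-12 slack on the 50%
threshold so exact-half cumulative sums are not missed to floating point.
Merging tie-breaks (highest count, then lexicographic CDR3) make QC
byte-reproducible; `generate_cohort()` is deterministic given `seed`, and
the pipeline writes per-stage TSVs with checksums so reruns can be
compared file by file.

## Validation strategy and problem sizes

The test suite validates each statistic against an independently coded
brute-force oracle (direct formula loops, exhaustive permutation /
hypergeometric enumeration) on hundreds of random small repertoires, and
the whole pipeline against the generator's ground truth: read
conservation and at least 95% read retention over 20 seeded cohorts of
10 subjects; recovery of a `beta_pasi = -0.5` severity effect on blood
TRG richness in at least 95 of 100 seeded 30-patient cohorts with the
type-I error of the same test calibrated over 500 null cohorts; and exact
publicity classification of injected public clonotypes. These problem
sizes are the package's chosen desk-scale validation conditions; larger
cohorts only slow the suite without changing what it demonstrates.
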