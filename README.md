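# gdrepertoire

Analysis of bulk-sequenced **gamma-delta T-cell receptor (TRG/TRD)
repertoires** from clonotype tables, for immunologists studying how
disease, age, sex and CMV exposure reshape the circulating and cutaneous
γδ T-cell compartment (the motivating setting is psoriasis vulgaris
patients versus healthy controls).

The package covers the whole desk-side pipeline downstream of read
alignment:

* **I/O** — AIRR Rearrangement TSV and a legacy 11-column clonotype
  dialect, with segment-level gene-call normalisation and subject
  metadata binding (`parse_airr`, `parse_legacy_table`,
  `write_clonotype_table`, `attach_metadata`).
* **QC & error correction** — library acceptance rules (depth, repertoire
  size, TRA/TRB off-target fraction), functional filtering, restriction
  to functional TRGV2/3/4/5/8/9 and TRDV1-8 segments, and merging of
  low-abundance clonotypes into Hamming-distance-1 parents at a 10:1
  count ratio (`qc_cohort`, `merge_error_clonotypes`). Merging conserves
  reads exactly.
* **Repertoire statistics** — V/J/V-J usage, CDR3 spectratypes (aa/nt,
  read- or clonotype-weighted), junctional (NDN) insert sizes, and TCR
  convergence: distinct nucleotide sequences encoding the same CDR3
  amino-acid sequence within a V-J context.
* **Diversity & clonality** — Chao1 (`S_obs + f1²/(2·f2)`, bias-corrected
  when `f2 = 0`), the Efron–Thisted unseen-species series (Euler-
  transformed when non-decaying), Shannon–Wiener (`−Σ pᵢ ln pᵢ`), inverse
  Simpson (`1/Σ pᵢ²`), D50 (fraction of ranked clonotypes holding 50% of
  reads), small/medium/large/hyperexpanded frequency compartments, and
  per-V-segment renormalised diversity.
* **Overlap & publicity** — clonotype keys `(V, J, CDR3)`, public
  clonotypes (present in ≥ 2 subjects), pairwise Jaccard matrices, paired
  blood–skin sharing.
* **Clinical association** — Spearman, Mann–Whitney and Fisher exact
  tests (exact enumeration for small samples, minimum-likelihood
  two-sided Fisher convention) with Benjamini–Hochberg correction and the
  age-analysis rule that excludes the oldest unmatched patients.
* **Synthetic cohorts** — a seeded generator (`sim_config`,
  `generate_cohort`) that emulates canonical TRGV9-TRGJP / TRDV2-TRDJ1
  dominance, per-segment (partly bimodal) CDR3 length mixtures, Zipf-like
  clone sizes, public clonotype pools, convergence, sequencing-error
  children, and configurable PASI/age effects on repertoire richness —
  the ground truth every pipeline stage is validated against.
* **Orchestration** — `run_pipeline()` chains simulate (or ingest) → QC →
  statistics → diversity → overlap → association through per-stage TSVs
  with a checksummed manifest and a markdown report.

## Worked example

```r
library(gdrepertoire)

cfg <- sim_config(n_pv = 6, n_hc = 4, seed = 7)   # 10 subjects, desk scale
sim <- generate_cohort(cfg)
qc  <- qc_cohort(sim$cohort)

table(qc$report$verdict)
#> pass
#>   40
s <- qc$cohort$samples[["PV01_blood_TRG"]]
s
#> <rep_sample> PV01_blood_TRG  subject PV01  blood TRG
#>   449 clonotypes, 21060 reads (1436 off-target)

round(head(segment_usage(s, "VJ"), 3), 3)
#>  TRGV9-TRGJP  TRGV9-TRGJ2 TRGV2-TRGJP2
#>        0.508        0.118        0.057

diversity_profile(s)
#>        sample_id stratum s_obs       d50 chao1 efron_thisted shannon inv_simpson
#> 1 PV01_blood_TRG     all   449 0.0935412   449           449 5.31688    80.60829

feats <- do.call(rbind, lapply(
  Filter(function(x) x$tissue == "blood" && x$chain == "TRG",
         qc$cohort$samples),
  function(x) data.frame(subject_id = x$subject_id,
                         richness = nrow(x$clonotypes))))
correlate_features(feats, qc$cohort$subjects, covariate = "pasi",
                   group = "PV")
#>    feature covariate n        rho    p_value p_adjusted
#> 1 richness      pasi 6 -0.8285714 0.05833333 0.05833333
```

Reading the output: after QC all 40 simulated libraries pass and 99.6% of
reads survive filtering; the patient's blood TRG repertoire is dominated
by the canonical TRGV9-TRGJP rearrangement (50.8% of reads); its D50 of
0.094 means fewer than a tenth of clonotypes hold half the reads
(oligoclonal expansion); and richness falls with disease severity
(Spearman rho = −0.83 across the 6 patients — at n = 6 this small demo
cohort sits just above the 0.05 threshold; the full validation uses 30
patients).

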