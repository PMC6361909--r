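# qfinger

Quality-consistency evaluation of herbal-extract HPLC-DAD fingerprints, for
analysts who need to judge whether commercial batches of a multi-component
extract are chemically consistent — and which constituents drive a measured
bioactivity — from wide-format peak-area tables rather than raw
chromatograms.

## What it computes

The core is the **averagely linear quantified fingerprint method (ALQFM)**.
Each sample's co-possessing-peak vector x⃗ = (x₁…xₙ) is scored against the
reference fingerprint y⃗ (the peak-wise mean of all batches), with sample
mass m_S and reference mass m_R:

- **S_L** — average linear qualitative similarity: the mean of the Pearson
  correlation r(x⃗, y⃗) and the ratio-uniformity term
  Σ(xᵢ/yᵢ) / √(n·Σ(xᵢ/yᵢ)²); distribution only, blind to content level.
- **b** — mass-corrected OLS slope of x on y,
  [nΣxᵢyᵢ − ΣxᵢΣyᵢ] / [nΣyᵢ² − (Σyᵢ)²] · (m_R/m_S) · 100%.
- **R%** — apparent content similarity, (Σxᵢ/Σyᵢ)·(m_R/m_S)·100%.
- **α** = |R/b − 1| — internal consistency of the two content estimates.
- **P_L** — average linear quantitative similarity,
  ½·[r·b + ΣxᵢΣxᵢyᵢ/(Σyᵢ√Σxᵢ²√Σyᵢ²)·(m_R/m_S)·100%], the content-sensitive
  headline score: a batch at concentration c× the reference scores
  S_L = 1, P_L = 100c%, α = 0.

The (S_L, P_L, α) triple maps to quality grades 1–8 through nested bands
(grade ≤ 5 = qualified). Around this sit multi-wavelength **fusion**
fingerprints (weighted concatenation of per-channel peak vectors), marker
**quantitation** with the percent-of-mean P_mC content index, hierarchical
**clustering** (average linkage, squared Euclidean), **ASAE** antioxidant
activity from DPPH-quench responses via linear calibration, and a
**PLS1 spectrum–effect model** (NIPALS, Q²-selected components, Hotelling
T² outlier screening, bootstrap Latin partition train/test split, VIP
marker ranking). A synthetic-data generator with known ground truth
(`simulate_fingerprints()`) makes every stage testable; a bundled reference
dataset of 30 commercial glycyrrhiza extract batches
(`ge_marker_contents()`, `ge_alqfm_scores()`) anchors the numbers.

## Worked example

```r
library(qfinger)
report <- run_full_evaluation(list(simulate = list(), seed = 1))
report
#> <run_report: 30 samples, channels 203nm/220nm/250nm/280nm/344nm/fusion, seed 1>
#>   qualified per channel: 203nm 28, 220nm 29, 250nm 29, 280nm 29, 344nm 18, fusion 29
#>   P_mC~P_L r: 203nm 0.192, 220nm 0.693, 250nm 0.665, 280nm 0.881, 344nm -0.025, fusion 0.628
#> <pls_summary: A = 3 | R2 95.6%, Q2 92.8%, RMSEE 0.02433, RMSECV 0.02838, RMSEP 0.02477 | outliers: none>
```

One call simulates a 30-batch, five-wavelength study, scores every batch
per channel and on the fused channel (29 of 30 simulated batches qualify on
the fusion fingerprint), correlates the content index with P_L, clusters
the batches and fits the activity model (3 components explaining 95.6% of
the activity variance, cross-validated Q² 92.8%, RMSE values in mM).

The bundled reference tables reproduce the study's headline statistics:

```r
ge <- ge_marker_contents()
contents <- ge[, c("LQA", "LQT", "LQG", "GLA", "ISS", "ISG")]
rownames(contents) <- ge$sample_id
column_summary(contents)
#>   compound      mean        sd   rsd_pct
#> 1      LQA 16.361633 5.9050624 36.090910
#> 3      LQG  2.478600 0.8997049 36.298915
#> 4      GLA 82.797100 7.5603454  9.131172
#> ...
activity_range(ge$asae_mM)
#> $min 0.1365   $max 0.2809   $fold 2.06
```

Glycyrrhizic acid (GLA) dominates at 82.8 mg/g on average; liquiritin
apioside and liquiritigenin fluctuate most across manufacturers (RSD ≈
36%); measured antioxidant activities span a 2.06-fold range. The
measured-vs-predicted activity regression over the calibration-set batches
gives R² = 0.888.

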