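# radstrat — multi-lesion CT-radiomics patient stratification

Metastatic lung adenocarcinoma patients carry several CT-visible lesions, but
molecular status (actionable oncogenic alterations vs wild-type), treatment
response and survival are patient-level quantities. `radstrat` implements the
statistical pipeline that bridges that gap, starting from a lesion-level
radiomic feature table (image processing and feature extraction are out of
scope):

1. **Feature filtering & normalization** — inter-segmentation ICC(2,1) > 0.85
   with a non-near-zero variance; center-scaling on the pooled lesion
   population, then Yeo-Johnson transformation with profile-ML λ.
2. **Patient-level integration** — three representations per patient: the
   lesion **centroid** (coordinate-wise mean), the **largest lesion** (maximal
   volume), and the **biopsied lesion** (when identified); plus the
   lesion-to-centroid dispersion statistics
   `d_j = ||x_j − c||₂`, summarized by their mean and range (max − min), a
   proxy for intra-patient radiophenotypic heterogeneity.
3. **Hierarchical consensus clustering** of each representation (Ward on
   Euclidean inside resamples, average linkage on 1 − consensus; k chosen by
   the Δ-area of the consensus CDF with PAC tie-break; small-cluster merging),
   compared across representations by the adjusted Rand index.
4. **Association statistics** — odds ratios `OR = ad/bc` with Wald 95%
   intervals `exp(log OR ± 1.96·√(1/a+1/b+1/c+1/d))`, univariable logistic
   screening, and backward stepwise logistic models with elimination traces.
5. **Outcomes** — Kaplan–Meier/log-rank and Cox models (Efron ties).
6. **Model comparison** — AUROC on the out-of-bag side of 1000 stratified
   Monte Carlo cross-validation splits, paired across nested feature sets.
7. **Synthetic cohort generator** — a first-class module emulating the
   cohort structure the analysis assumes (361 patients, ≥ 2 lesions each,
   median 4; latent radiophenotype clusters linked to molecular groups;
   group-dependent dispersion; outcome models on cluster and dispersion;
   duplicate segmentations with a configurable true ICC), so that the entire
   pipeline is testable without patient data.

## Worked example

```r
library(radstrat)

# a synthetic cohort at the default study conditions
cohort <- generate_cohort(synth_config(seed = 20260925))
cohort
#> Synthetic multi-lesion cohort: 361 patients, 1634 lesions, 20 features
#> nsOA  sOA   WT
#>   68  197   96

# reproducibility filter and normalization
dup  <- generate_duplicate_segmentations(cohort$lesions, 0.9, seed = 1)
filt <- filter_features(cohort$lesions, compute_icc(cohort$lesions, dup))
tr   <- transform_features(filt$table)

# patient representations and dispersion
rep_ <- integrate_patients(tr$table)
head(rep_[, c("patient_id", "n_lesions", "dispersion_mean", "dispersion_range")], 3)
#>   patient_id n_lesions dispersion_mean dispersion_range
#> 1      P0001         2        2.107510        0.0000000
#> 2      P0002         8        1.856029        0.6661004
#> 3      P0003         8        2.722619        0.9440252

# consensus clustering of the centroid representation
cc <- consensus_cluster(representation_matrix(rep_, "centroid"),
                        k_range = 2:6, n_resamples = 200, seed = 7)
cc$chosen_k
#> [1] 2

# published contingency counts -> univariable odds ratio
odds_ratio_wald(25, 7, 22, 83)   # never-smoker, nsOA vs wild-type
#>   estimate   ci_low  ci_high      p_value degenerate
#> 1 13.47403 5.154457 35.22182 1.127897e-07      FALSE
```

The odds ratio 13.47 (5.15–35.22) reproduces, to the printed precision, the
published univariable never-smoker association for the non-smoker-alteration
vs wild-type contrast, computed from the published contingency counts (all
twelve published univariable contrasts are shipped as
`published_contingency()` and reproduce the same way).

## Analysis workflow

The `analysis/` directory holds the numbered, narrated drivers of the full
workflow; each writes its tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R      # cohort tables + ground truth
Rscript analysis/02_filter_normalize.R     # ICC filter, Yeo-Johnson
Rscript analysis/03_integrate_cluster.R    # representations, consensus, ARI
Rscript analysis/04_associations_outcomes.R# ORs, stepwise models, KM/Cox
Rscript analysis/05_evaluate_models.R      # MCCV feature-set comparison
```

On the default synthetic cohort this prints, among other things: the
dispersion range lower in nsOA than wild-type (Kruskal–Wallis p = 2.3e-10),
a dispersion-range Cox hazard ratio of 2.12 (1.54–2.93) for overall survival,
and a mean MCCV AUROC rising from 0.633 (clinical-radiological features) to
0.645 when the largest-lesion cluster is added — the qualitative pattern the
method is designed to expose. See `vignettes/multilesion-radiomics.Rmd` for
the model, its assumptions, and what the synthetic cohort does and does not
emulate.

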