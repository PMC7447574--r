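# subtypeDAE

Molecular subtype discovery from multi-omics cancer cohorts with a
denoising autoencoder, and transfer of the discovered subtypes to
expression-only cohorts with a sparse logistic classifier.

The package is for computational biologists who have per-patient omics
matrices (mRNA expression, miRNA expression, gene-level copy number) plus
survival follow-up, and who want to ask: *does this cohort split into
molecular subtypes, do the subtypes differ in survival, and can the
subtype call be reduced to a small gene signature usable on cohorts where
only expression data exist?*

## Method

1. **Preprocess** each omics block: drop features then samples missing
   more than 20% of entries, impute the rest with feature medians,
   average copy-number variations per gene, and min–max scale every
   feature to [−1, 1]. Blocks are aligned by sample ID and concatenated
   into one matrix *x*.
2. **Integrate** with a denoising autoencoder: a symmetric tanh network
   (hidden widths 200–50–2–50–200) trained with Adam to reconstruct the
   clean *x* from a corrupted version *x̃* (masking noise, rate 0.2,
   resampled every batch), minimizing
   ‖x − f_d(f_e(x̃))‖₂². The 2-D bottleneck *z* = f_e(x) is the
   integrated representation. Setting the corruption rate to 0 recovers
   the plain autoencoder exactly. PCA, kernel-PCA and plain-AE reductions
   are provided as baselines.
3. **Cluster** *z* with k-means (k-means++, 10 restarts), choosing
   k ∈ {2, …, 8} by the highest mean silhouette width; the
   Davies–Bouldin index is reported alongside.
4. **Evaluate survival**: clusters are mapped to Low/High risk by
   Kaplan–Meier median survival and compared with the two-group log-rank
   test.
5. **Classify**: an L1-penalized logistic regression
   (maximizing Σᵢ{yᵢ ln pᵢ + (1−yᵢ) ln(1−pᵢ)} − λ‖β‖₁, intercept
   unpenalized, λ by stratified cross-validation) compresses the subtype
   call into a sparse expression signature that can be applied to
   external mRNA-only cohorts and evaluated there by the log-rank test.

A seeded synthetic generator (`simulate_multiomics()`) produces
multi-block Gaussian cohorts with a planted two-group structure, MCAR
missingness and subtype-dependent exponential survival, so the whole
pipeline is testable with known ground truth.

## Worked example

```r
library(subtypeDAE)

sim    <- simulate_multiomics(sim_config(seed = 1))     # 300 samples, 3 blocks
blocks <- lapply(sim$dataset$blocks, preprocess_block)
ds     <- assemble(blocks, sim$dataset$clinical)

model <- fit_dae(ds, dae_config(seed = 1))
emb   <- embed_samples(model, ds)
sel   <- select_k(emb, 2, 8, seed = 1)
sel$metrics
#>   k silhouette       dbi tot_withinss
#> 1 2  0.8184735 0.2604890     7.425918
#> 2 3  0.6370241 0.5933326     5.180699
#> 3 4  0.4411535 0.8131764     3.428316
#> ...
sel$best_k
#> [1] 2

cl <- sel$results[["2"]]
mclust::adjustedRandIndex(cl$labels, sim$truth$labels[ds$sample_ids])
#> [1] 1

risk <- assign_risk_groups(cl, ds$clinical)
logrank_test(ds$clinical$time, ds$clinical$event,
             risk$risk_group[ds$sample_ids])$p_value
#> [1] 2.271984e-16
```

The silhouette column says how well separated the k-means clusters are in
the bottleneck space (0.82 at k = 2 — strong separation; raw k-means on
the same concatenated 380-feature matrix reaches only ~0.09). The adjusted
Rand index of 1 means the two recovered clusters match the generator's
planted subtypes exactly, and the log-rank p-value shows the recovered
risk groups differ sharply in survival (the generator's hazard ratio
was 3).

The same run, plus the classifier and a benchmark of six clustering
strategies, is available as one call (`run_pipeline()`) or from the
shell via the thin CLI at `inst/cli/subtype-dae.R`.

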