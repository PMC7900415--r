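# snfimc

Prediction of candidate miRNA–disease associations by **similarity network
fusion** (SNF) and **nonnegative inductive matrix completion** (IMC).

Most human diseases are associated with dysregulated microRNAs, but testing
candidate miRNA–disease pairs experimentally is slow and expensive.
Computational ranking of the untested pairs of a verified association
catalogue lets bench scientists prioritize candidates. This package
implements a complete pipeline for that task, together with the
cross-validation protocols used to evaluate it and a synthetic-data
generator with planted structure, so every stage can be exercised and
tested without access to any external database.

## The model

The inputs are a binary association matrix `A ∈ {0,1}^(nd×nm)`
(`A[i,j] = 1` iff disease *i* has a verified link to miRNA *j*), a
precomputed miRNA functional similarity matrix `MF`, and a disease term DAG
(MeSH-descriptor style).

1. **Disease semantic similarity.** Each ancestor `d` of disease `D`
   contributes `DD_D(d)`: 1 for `D` itself, otherwise
   `Δ · max{DD_D(d′) : d′ a child of d on a path to D}` with Δ = 0.5.
   With `DV(D) = Σ_{d∈T(D)} DD_D(d)`,

   `DS(d_i, d_j) = Σ_{t ∈ T(d_i)∩T(d_j)} (DD_i(t) + DD_j(t)) / (DV(d_i) + DV(d_j))`.

2. **Gaussian interaction-profile (GIP) kernel.**
   `GKD(d_i, d_j) = exp(−ρ_d ‖K(d_i) − K(d_j)‖²)` on the rows of `A`
   (columns for miRNAs), with `ρ_d = ρ′_d / mean_i ‖K(d_i)‖²` and
   `ρ′_d = 1`.

3. **Similarity network fusion.** For each entity class the two views are
   fused by cross-diffusion: full kernels `P` (row-stochastic, diagonal ½)
   are repeatedly propagated through the KNN kernels `S` of the *other*
   view, `P₁ ← S₁ P₂ S₁ᵀ`, `P₂ ← S₂ P₁ S₂ᵀ`, and averaged after `T = 20`
   steps, giving fused similarities `S_d` and `S_m`.

4. **Inductive matrix completion.** The fused similarities act as feature
   matrices in

   `min_{U,V ≥ 0} ½‖A − S_d U Vᵀ S_mᵀ‖²_F + λ₁/2 ‖U‖²_F + λ₂/2 ‖V‖²_F`,

   solved by NMF-style multiplicative updates (monotone in the objective,
   stopped at relative change < 1e-6). Predicted scores are
   `Ŝ = S_d U Vᵀ S_mᵀ`; a disease absent from training is scored from its
   feature vector alone.

Evaluation follows the standard protocols for this problem: **global
LOOCV** (each verified pair held out in turn and ranked against all
unverified pairs) and **repeated five-fold CV**, both with leak-free
per-fold recomputation of the association-dependent kernels, and
tie-aware ROC/AUC.

## Worked example

```r
library(snfimc)

dataset <- generate_dataset(nd = 60, nm = 80, rank = 3, density = 0.06,
                            noise = 0.1, seed = 42)
dataset
#> <mda_dataset> 60 diseases x 80 miRNAs, 313 associations, seed 42

pred <- mda_predict(dataset, mda_config(seed = 1))
glance(pred$fit)
#> # A tibble: 1 × 7
#>    rank lambda1 lambda2 n_iterations objective_initial objective_final converged
#>   <int>   <dbl>   <dbl>        <int>             <dbl>           <dbl> <lgl>
#> 1    50       1       1           69           378647.            144. TRUE

head(rank_scores(pred$scores, top_k = 3), 3)
#> # A tibble: 3 × 4
#>   disease_id mirna_id score  rank
#>   <chr>      <chr>    <dbl> <int>
#> 1 D001       M060     0.217     1
#> 2 D001       M003     0.199     2
#> 3 D001       M005     0.184     3

cv <- five_fold_cv(dataset, mda_config(seed = 1), n_repeats = 5, seed = 42)
cv
#> <cv_result> five_fold_cv: AUC = 0.7370 (5 repeats, sd 0.0060)
autoplot(cv)   # ROC curve
```

The solver converges in 69 iterations and drives the objective from 3.8e5
to 144; the ranked table lists, per disease, the strongest miRNA
candidates. The cross-validated AUC of 0.74 sits below this benchmark's
Bayes ceiling of 0.85 (the AUC the true planted sampling probabilities
achieve — computed by `scripts/acceptance.R`): held-out links are ranked
far above chance, while the degree-preserving null collapses to ≈ 0.5.
See the methods vignette for what the synthetic benchmark does and does
not show.

A command-line front end for file-driven runs lives at
`inst/cli/snfimc.R` (`simulate`, `predict`, `evaluate` subcommands).

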