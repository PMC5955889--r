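# ssdu

Stochastic global optimization for the **refinement stage of rigid-body
protein–protein docking**. The input is the kind of ensemble a global
FFT-based docking search produces: hundreds to thousands of low-energy
receptor–ligand placements, each a 6-vector
ψ = (r, a, b, y₁, y₂, y₃) — center-to-center distance, exponential
coordinates of the translation direction, and an axis-angle rotation
vector — with an energy. The package is for structural-bioinformatics
developers who want a fully reproducible, certifiably convex refinement
loop to study, extend, or plug their own energy model into.

## The method

The binding-energy landscape near the native complex is funnel-shaped but
rugged, and strongly anisotropic: a low-energy cluster spreads widely along
a smooth 3-dimensional *permissive* subspace and is confined along steep
*restrictive* directions. The refinement loop exploits this:

1. **DBSCAN** (ε, N_min) on the 5 reduced coordinates x = (a, b, y₁, y₂, y₃)
   separates energy funnels and discards outliers.
2. Per cluster, **PCA** identifies the permissive subspace (the 3 leading
   principal coordinates, > 75% of the variance by construction on funnel
   ensembles).
3. The η lowest-energy members are locally minimized, and a degree-2d
   polynomial **underestimator** U is fitted to their permissive
   coordinates φ and energies f by the semidefinite program

       min Σᵢ [fᵢ − U(φᵢ)]   s.t.   U(φᵢ) ≤ fᵢ ∀i,   U SOS-convex,

   where *SOS-convexity* — the Hessian biform yᵀ∇²U(φ)y has a
   sum-of-squares representation with a PSD Gram matrix — is a tractable
   certificate of convexity. The package ships its own small dense
   interior-point solver for this program family; every fit returns a
   feasible underestimator with its Gram certificate.
4. Sampling is **biased toward the underestimator's global minimum**:
   z* = (φ*, z̄₄, z̄₅) is perturbed uniformly within (−0.5βσᵢ, 0.5βσᵢ) per
   principal coordinate, mapped back, completed with the cluster mean r̄,
   and locally minimized.
5. New conformations are **merged** with the ensemble and the K lowest
   energies are retained; iterate (3 iterations by default).

A post-processing stage reproduces cluster discrimination: greedy
neighbour-count clustering of pairwise placement RMSDs (9 Å threshold, ≤ 30
clusters, ≥ 10 members), 9 per-cluster features, quality labels, and a
random-forest ranker trained with grouped 60/40 splits, positive-class
oversampling, and 15-repeat mean out-of-sample AUC.

A synthetic multi-funnel landscape generator with exact ground truth, a
PIPER-like decoy-ensemble simulator, and a toy Lennard-Jones/Coulomb
rigid-body energy provide controlled study conditions; any deterministic
function of ψ can serve as the energy model.

## Worked example

```r
library(ssdu)

fl     <- funnel_landscape(funnel(center = c(0.5, -0.3, 0.2, 0, 0.1),
                                  depth = -50),
                           ruggedness = 0.3, seed = 11)
truth  <- ground_truth(fl)            # planted global minimum: -50.3824
decoys <- simulate_decoys(fl, 300, temperature = 1, seed = 7)
decoys
#> # A tibble: 300 x 7
#>       r      a      b    y1      y2     y3 energy
#>   <dbl>  <dbl>  <dbl> <dbl>   <dbl>  <dbl>  <dbl>
#> 1  9.86  0.356  0.426 1.24  -0.0362 0.262   -40.2
#> 2 10.3  -0.399 -0.700 0.530  0.0107 0.0154  -45.9
#> 3 10.3   0.216 -0.250 1.49   0.0313 0.0509  -44.6
#> # i 297 more rows

refined <- ssdu_refine(decoys, fl, ssdu_params(n_min = 30, k_bar = 300,
                                               seed = 7))
glance(refined)
#> # A tibble: 1 x 6
#>       K iterations best_input best_refined median_input median_refined
#>   <int>      <int>      <dbl>        <dbl>        <dbl>          <dbl>
#> 1   300          2      -49.5        -50.4        -44.6          -50.4
```

The best input decoy sits at −49.5; after two iterations (the loop stopped
early once the best energy stalled) the refined ensemble reaches −50.4 —
the planted ground-truth minimum — and the *median* moves from −44.6 to
−50.4, i.e. the whole retained ensemble has been concentrated into the
planted funnel bottom. `tidy(refined)` gives the per-iteration trace
(clusters found, outliers removed, best energy), `autoplot(refined)` the
input-vs-refined energy CDFs, and `postprocess_ensemble()` +
`train_ranker()` + `rank_and_enrich()` the cluster-ranking stage.

A thin command-line driver wraps the same functions:

```sh
Rscript inst/cli/ssdu.R simulate --model model.yaml --K 300 --seed 7 --output ens.tsv
Rscript inst/cli/ssdu.R refine   --model model.yaml --input ens.tsv --output refined.tsv
```

Identical seeds reproduce every output table byte-for-byte; each run writes
a provenance record (`<output>.run.yaml`) with the resolved configuration.

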