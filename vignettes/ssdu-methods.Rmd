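---
title: "Refining docking ensembles by subspace convex underestimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining docking ensembles by subspace convex underestimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssdu)
```

## The problem and the model

Rigid-body protein-protein docking pipelines produce, at their global-search
stage, thousands of low-energy receptor-ligand placements ("decoys"). Each
placement is a point on a 6-dimensional manifold, parameterized here as
$\psi = (r, a, b, y_1, y_2, y_3)$: the center-to-center distance $r$ (Å),
exponential coordinates $(a, b)$ of the direction of the translation vector
on the unit sphere, and an axis-angle rotation vector $y$ for the ligand
orientation. The binding-energy landscape over $\psi$ is funnel-shaped but
rugged: within a funnel there is an overall gradient toward the basin
bottom, overlaid with many local minima.

The refinement strategy implemented by this package exploits two structural
observations about such landscapes:

1. Within a well-packed low-energy cluster, $r$ barely varies, so the search
   can drop to the five coordinates $x = (a, b, y_1, y_2, y_3)$.
2. The cluster's variability concentrates in a low-dimensional *permissive*
   subspace — typically the 3 leading principal directions, carrying more
   than 75% of the variance — along which the energy varies smoothly, while
   the orthogonal *restrictive* directions are steep and confining.

The loop (`ssdu_refine()`) iterates:

1. **Clustering and outlier elimination.** DBSCAN on the reduced
   coordinates (Euclidean metric) with radius `eps` and minimum
   neighbourhood size `n_min`. Outliers are discarded; each dense cluster is
   processed separately, which keeps multi-funnel inputs from being averaged
   into a meaningless single model.
2. **Per-cluster subspace.** PCA of the cluster's reduced coordinates
   (`fit_pca()`); the permissive coordinates are the 3 (configurably 2)
   leading principal coordinates.
3. **Local minimization.** The `eta` lowest-energy members (ceiling rule)
   are locally minimized in the full 6D parameterization
   (`local_minimize()`, quasi-Newton with finite differences). The
   underestimator is fitted to local minima, since it approximates the
   envelope of minima rather than the raw energy surface.
4. **SOS-convex underestimation.** `fit_underestimator()` finds the
   polynomial $U$ of even degree $2d$ minimizing
   $\sum_i \left[f_i - U(\phi_i)\right]$ subject to $U(\phi_i) \le f_i$ for
   every sample and to *SOS-convexity*: the Hessian biform
   $y^\top \nabla^2 U(\phi)\, y$ must admit a sum-of-squares representation
   with a positive semidefinite Gram matrix. SOS-convexity is a tractable
   sufficient condition for convexity (exact convexity checking is
   intractable from degree 4 up), verified here by semidefinite programming.
5. **Biased resampling.** The underestimator's global minimum $\phi^\ast$
   (`minimize_convex()`) is completed to
   $z^\ast = (\phi^\ast, \bar z_4, \bar z_5)$ using the cluster means of the
   restrictive coordinates, then perturbed `k_bar` times with independent
   uniform noise in $(-0.5\,\beta\sigma_i,\, 0.5\,\beta\sigma_i)$ per
   principal coordinate — ranges proportional to the cluster's spread, so
   coverage follows the sample distribution. Samples are mapped back with
   $x = W(z^\ast + s) + \bar x$, completed with the cluster mean $\bar r$,
   and locally minimized.
6. **Merge and filter.** All new conformations are merged with the current
   ensemble, and the $K$ lowest-energy conformations are retained. Best and
   $k$-th best energies are therefore non-increasing across iterations.

The loop stops after `max_iter` iterations (default 3, the published
protocol) or when the best energy improves by less than `rel_tol`
(default $10^{-4}$, relative); the published account leaves the stopping
rule open beyond the iteration cap, so the relative-improvement cut is this
package's choice.

## The semidefinite program and its solver

For $n = 3$ variables and degree $2d$, $U$ has $\binom{n + 2d}{2d}$
coefficients and the Gram matrix lives on the basis
$\{\text{monomials of degree} \le d - 1\} \otimes \{y_1, y_2, y_3\}$
(a $12 \times 12$ matrix at the default degree 4). The linear identity
between Gram entries and Hessian-form coefficients is imposed exactly by
parameterizing the Gram matrix as a particular solution plus an orthonormal
null-space basis, computed once per $(n, 2d)$ and cached.

No semidefinite-programming library is involved: the package ships a small
dense primal interior-point solver (`R/sdp.R`) specialized to this problem
family — a log-det barrier on the Gram matrix, log barriers on the
underestimation slacks, damped Newton steps on the central path with a
deterministic $\mu$ schedule ($\mu_0 = 1$ down to $10^{-11}$, factor 0.12),
and a strictly feasible start built from
$\delta(\lVert\phi\rVert^2 + \lVert\phi\rVert^4)$, whose positive-definite
Gram matrix is written down in closed form. Problem sizes (around 50 free
variables) make each fit a few hundred milliseconds. Because iterates stay
strictly feasible, every returned fit satisfies all underestimation
constraints and carries a PSD Gram certificate by construction; the
feasibility tolerance ($10^{-6}$ on the preconditioned scale) only describes
the reported gap accuracy.

Numerical choices worth knowing:

* **Preconditioning.** Coordinates are centered and scaled to unit standard
  deviation; energies are shifted to minimum zero and scaled by their
  standard deviation. The optimum is mapped back exactly (binomial
  re-expansion of the affine substitution), so reported coefficients are in
  original coordinates. The transformation leaves the optimization problem
  mathematically unchanged.
* **Ties.** A ridge of $10^{-9}\lVert c\rVert^2$ makes underdetermined fits
  (fewer samples than coefficients — allowed with a warning) deterministic.
* **Degrees.** Default $2d = 4$, selectable in $\{2, 4, 6\}$. The published
  method motivates polynomials beyond quadratics without printing its
  degree; 4 is the smallest degree where SOS-convexity is a genuine
  relaxation and the SDP stays tiny. At degree 2 the program reduces to an
  explicit PSD constraint on the (constant) Hessian. At degree 6 a strictly
  interior Gram start is not structurally available, so the barrier runs on
  $G + \nu I$ with $\nu \downarrow 0$ tied to $\mu$; the final certificate
  is still checked.
* **Degenerate inputs.** Constant energies return the tight constant;
  zero-variance coordinate directions get unit scale; an unbounded-below
  minimization (possible only for degenerate quadratic parts) raises a
  diagnostic error.

`is_sos_convex()` runs the same machinery as a feasibility program: it
maximizes the minimum Gram eigenvalue over the affine slice reproducing a
given polynomial's Hessian biform, returning a certificate or a refusal.

## Conventions on the conformation manifold

The published parameterization delegates its manifold details to a
supplement; this package fixes explicit, testable conventions and uses them
consistently everywhere:

* `exp_coords_to_direction()` is the sphere exponential map anchored at
  $(0, 0, 1)$: rotate the anchor by angle $\lVert(a,b)\rVert$ about
  $(-b, a, 0)/\lVert(a,b)\rVert$.
* `rotation_from_tangent()` is the SO(3) exponential (axis-angle/Rodrigues)
  map of a global rotation vector; vectors are kept in the open ball
  $\lVert y \rVert < \pi$ (`wrap_tangent()`) so PCA on rotation coordinates
  is meaningful.
* `rmsd()` compares two placements of the *same* ligand without
  superposition — appropriate for intra-complex distances, and free of any
  superposition dependency in the clustering metric.

These conventions may differ from the original authors' supplement; all
downstream modules share them, so results are internally consistent.

## The synthetic landscape and what it does (not) emulate

`funnel_landscape()` builds the test bed:
$$f(\psi) = \min_j\left[d_j + (x - c_j)^\top A_j (x - c_j)
  + k_r (r - r_j)^2\right] + \rho \sum_{i=1}^5 \sin(\omega_i x_i + \phi_i),$$
anisotropic quadratic basins with three small "permissive" and two large
"restrictive" curvature eigenvalues, plus deterministic sinusoidal
ruggedness (phases fixed by the seed). `simulate_decoys()` emulates the
statistics of a global-search output: Gaussian clouds about each funnel
center with covariance $T A_j^{-1}$ (wide along permissive, narrow along
restrictive directions), Boltzmann-like per-funnel weights
$\propto e^{-d_j/T}$, and a fraction of uniform outliers. The $r$
coordinate is drawn from the Boltzmann marginal of its quadratic term,
$N(r_j, T/(2 k_r))$, truncated positive — the published account fixes the
5-coordinate law but not $r$'s.

Default study conditions: permissive eigenvalues 2, restrictive 200. The
100:1 ratio makes the permissive spread ten times the restrictive spread
(mirroring the wide-to-narrow pattern of real near-native clusters, and
putting 3-component explained variance far above 0.75), and the absolute
scale makes the cloud dense enough that the published DBSCAN radius
$\varepsilon = 1.0$ finds core points at desk-scale ensembles. Desk-scale
runs in the tests and the acceptance script use $K = 300$ with
`n_min = 30` — the same 10% ratio as the published $N_{\min} = 100$ at
$K = 1000$; ensembles of that published size work unchanged with the
published defaults.

What passing on this generator shows — and what it does not: the synthetic
landscape has smooth basins, stationary sinusoidal ruggedness, exact
rigid-body geometry, and an available ground truth. Real docking energies
add side-chain rearrangement, solvation and knowledge-based terms, and
non-stationary ruggedness; success here demonstrates the machinery
(clustering, subspace recovery, certified underestimation, biased
resampling, merge-and-filter bookkeeping) under controlled conditions, not
docking accuracy on proteins. The companion `toy_rigid_energy()`
(soft-core Lennard-Jones plus screened Coulomb over point sets, weights as
free parameters) exercises the energy-model contract on physically shaped
functions; the knowledge-based terms of production docking potentials
(solvation, hydrogen bonding, statistical reference-state and rotamer
terms) require external parameter databases and are deliberately out of
scope, with the `energy()` contract as the hook.

## Post-processing: cluster discrimination

`postprocess_ensemble()` reproduces the cluster-selection stage used after
refinement: greedy neighbour-count clustering of pairwise placement RMSDs
(neighbours strictly below 9 Å, at most 30 clusters, at least 10 members,
ties to the lower index — self-pairs excluded, all fixed for determinism);
nine per-cluster features (mean energies of the lowest 25/50/75/100%,
cluster size, mean center distances of the nearest 25/50/75/100%, with
ceiling counts so no quantile set is empty); labels from the quality of the
cluster center; and a random-forest ranker (`train_ranker()`) trained with
grouped 60/40 splits (all clusters of a complex stay on one side),
oversampling of the positive class to parity in the training split only,
and 15 repeats whose out-of-sample AUC is averaged.

Two stand-ins are documented rather than hidden. Quality tiers come from a
distance surrogate — placement RMSD of the cluster center's ligand to the
planted truth, binned at 10/5/1 Å for Acceptable/Medium/High — because the
published quality scorer is an external program; the bands are configurable.
And the forest's positive-class probability uses vote fractions, which with
fully grown trees (pure leaves) equal the tree-averaged leaf positive
fraction described in the published protocol. Forest hyperparameters (500
trees, default mtry) are defaults, not asserted claims.

`run_experiment()` wires the whole pipeline at desk scale and reports
before/after counts of quality conformations per tier, aggregated two ways:
*average* (mean of per-replicate percentage changes; cases with zero
"before" are excluded as undefined ratios) and *total* (percentage change
of pooled counts; zero-before cases still contribute). Cases with zeros on
both sides are dropped from both.

## Reproducibility

Every stochastic step takes a seed; per-cluster, per-iteration child seeds
derive from the top-level seed by a fixed integer scheme, so results do not
depend on cluster enumeration order. Ensemble tables serialize with
17-significant-digit floats (round-trip exact); identical seed and
parameters reproduce output tables bit-for-bit, including through the
command-line driver (`inst/cli/ssdu.R`), which writes a provenance record
(`<output>.run.yaml`) with the resolved configuration beside each output.

## Known limitations

* Rigid bodies only: no side-chain repacking or backbone flexibility; the
  local minimizer moves the 6 rigid-body coordinates.
* The permissive dimension is fixed (3, optionally 2) rather than selected
  from an explained-variance threshold.
* The manifold conventions (exponential coordinates, tangent anchor) are
  this package's explicit choices where the published text is not
  self-contained.
* DBSCAN border points are assigned to the earliest-founded eligible
  cluster — one of several defensible conventions, fixed here for
  determinism.
* The interior-point solver is specialized to this problem family; it is
  not a general-purpose SDP code.
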