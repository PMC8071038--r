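---
title: "Structural covariance networks of brain morphometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural covariance networks of brain morphometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis

`brainwcn` compares the *correlation structure* of morphometric brain
features between two subject groups, rather than the feature values
themselves. Each feature (a regional volume, surface area, thickness,
or curvature summary in the FreeSurfer stats-table layout) becomes a
node; the Spearman correlation of two features across the subjects of
one group defines their association; thresholding at a fixed quantile
turns the association matrix into a network; and twelve node-centrality
measures summarize each node's structural role. A case group is then
scored against a null distribution of control networks obtained by
subject subsampling.

The pipeline has five stages, each an exported function group:

1. **Schema and ingestion** (`make_canonical_schema()`,
   `read_freesurfer_tables()`): a canonical 419-feature schema —
   31 bilateral cortical regions × 6 measures (372), 14 bilateral
   subcortical volumes (28), 12 unpaired subcortical volumes, and 7
   global measures — plus the flagged `BrainSegVolNotVent` normalizer
   column. Reduced schemas with the same structure support small
   studies and tests.
2. **Normalization and augmentation** (`normalize_features()`,
   `augment_lr()`): volumes are divided by the global brain volume,
   thicknesses by the mean cortical thickness (the average of the
   left- and right-hemisphere mean-thickness columns), areas by the
   total cortical surface area; then each homologous left/right pair
   contributes a bilateral average `(L + R)/2` and an asymmetry
   `(L − R)/2`.
3. **Network construction** (`build_network()`): Spearman matrix,
   binary adjacency from the 0.85 quantile of the off-diagonal
   correlations (link density fixed at 0.15), and edge weights
   `w = exp(−S²/σ²)` from the chordal distance
   `S = sin(arccos(r)/2)`, with `σ = 1`.
4. **Centrality** (`centrality_profile()`): degree, strength,
   nearest-neighbor degree/strength, topological and weighted
   closeness and betweenness, clustering coefficient, edge-weight
   disparity (inverse participation ratio), and topological/weighted
   spectral centrality from the Fiedler vector of the combinatorial
   Laplacian.
5. **Comparison** (`compare_groups()`): `K` control networks are built
   from subject subsamples of size `M_sub` drawn with replacement; the
   case network's node-averaged (whole-network) and per-node values are
   z-scored against the Box-Cox-regularized control distribution, with
   one-tailed empirical p-values.

Because every association is a rank correlation, the entire analysis is
invariant to strictly monotone per-feature transforms of the input —
unit changes, log scaling, power transforms — a property the test suite
asserts bit-exactly.

# Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `q` | 0.85 | threshold quantile of the signed correlation distribution; fixes link density at `1 − q` = 0.15 |
| `sigma` | 1 | width of the chordal-distance weight kernel; `w(r=1)=1`, `w(0)=e^{−1/2}`, `w(−1)=e^{−1}` |
| `M_sub` | case-group size | subjects per control subsample, matching the case group so both estimates carry comparable sampling noise |
| `K` | 200 (engine default; 5×10⁴ is feasible for a production run) | subsampling repetitions; the empirical p-value floor is `1/K` |
| `node_set` | `"augmented"` | whether derived bilateral average/asymmetry features are nodes |
| `weighted_distance` | `"inverse"` | weighted shortest-path edge length `1/w`; `"chordal"` uses the chordal distance `S` itself |
| `ipr_variant` | `"disparity"` | IPR as edge-weight disparity `Σ_j (W_ij/S_i)²`; `"spectral"` gives the Fiedler-vector localization reading |
| `tail` | `"one"` | empirical p counts null values more extreme in the direction of the case's deviation |

# Numerical and procedural choices

**Fixed-density thresholding and ties.** The point of thresholding at a
quantile is that every network in the study has the same number of
links. We therefore link exactly the canonical strictly-above-the-
quantile count of node pairs; when tied correlation values straddle the
boundary (which happens under resampling with replacement, where
duplicated subjects tie ranks), tied pairs are admitted in a
deterministic order until that count is reached. With distinct boundary
values the rule coincides with a strict inequality. This guarantees the
whole-network degree z-score is exactly 0 "by construction" — its flag
in the output — for any pair of groups.

**Weighted distances.** The similarity weight `w` must be converted to
a length for path-based measures; we default to `ℓ = 1/w` (strong
similarity = short path) and expose the chordal distance `S` as an
alternative, since the choice changes weighted closeness and
betweenness.

**Undefined values.** Clustering is undefined for nodes of degree < 2,
neighbor averages and disparity for isolated nodes. These propagate as
`NA`, are excluded from whole-network averages, and their counts are
reported, never imputed.

**Disconnected networks.** Construction succeeds with a warning and a
component count. Closeness switches to per-component Wasserman–Faust
scaling (flagged). The spectral measures refuse disconnected input —
the "first nontrivial" Laplacian eigenvector does not exist there — so
subsampling repetitions whose network fragments are logged and redrawn,
and `generate_connected_cohort()` regenerates a synthetic cohort (with
consecutive seeds, deterministically) until the full-group networks are
connected. On graphs with a degenerate Fiedler eigenvalue (e.g. highly
symmetric graphs) the eigenvector is fixed by a deterministic sign
convention and a warning is raised; note that on such graphs the value
of spectral centrality depends on the basis chosen within the
eigenspace, so only reproducibility, not symmetry, is guaranteed.

**Box-Cox z-scores.** The transform parameter λ is fitted by profile
maximum likelihood on the control distribution only; the case value is
transformed with the same λ and shift (an automatic `−min + ε` shift is
applied when values are non-positive, with the domain extended to cover
the case value). A constant control distribution yields an identity
transform with a flag. The empirical p-value is computed on the raw
values — it is rank-based and unaffected by the monotone transform.
Because λ is re-fitted per distribution, the z-score is invariant to a
positive rescaling of the values but not to arbitrary affine shifts;
the p-value is invariant to any monotone transform.

**One-tailed p-values.** Null values are counted as "more extreme" in
the direction of the case's deviation from the control mean; a zero
count is reported as the resolution bound `p = 1/K` with a flag. A
two-tailed variant is available.

**IPR.** The inverse participation ratio is implemented as edge-weight
disparity, `Y_i = Σ_j (W_ij/S_i)²` (equal to `1/K_i` for uniform
weights, tending to 1 under single-edge dominance). An eigenvector-
localization variant (fourth powers of the weighted Fiedler vector) is
an equally defensible reading of the name and is available behind
`ipr_variant = "spectral"`; both are interpretations, and the disparity
form is the default.

**Schema accounting.** The base schema has 419 features, an odd number,
so appending two derived features per homologous pair can never produce
an even total equal to twice a round number plus 419; with the
canonical pairing (186 cortical + 14 subcortical + 2 global pairs) the
augmented table has 823 features and the default network 821 nodes
(the three flagged normalizer columns are not nodes). The two
hemisphere mean-thickness columns are deliberately not paired: after
normalization by their own mean, their bilateral average is identically
1, a degenerate feature.

# The synthetic cohort generator

No imaging data ship with the package; `generate_cohort()` produces
two-group cohorts with the statistical structure the analysis assumes,
so every stage is testable. The generator is a Gaussian copula over
per-feature latents built from variance-share factor layers:

* a **global factor** (default share 0.08) — overall brain size,
  giving every pair a correlation floor;
* a **block factor** per anatomical grouping (0.12) — features of one
  region covary;
* a **measure-kind factor** (0.05) — volumes covary with volumes,
  thicknesses with thicknesses;
* a **smooth anatomical gradient** (0.30): features load on a
  two-dimensional ring at an angle that advances region by region, so
  anatomically nearby regions correlate at close to the full gradient
  share and distant ones weakly or negatively;
* an **antisymmetric gradient** (0.18) loaded `+` by left and `−` by
  right features over the same angles — directional asymmetry, which
  survives the left-minus-right difference and gives the derived
  asymmetry features their own correlated family;
* independent feature noise for the remainder.

Latents are mapped to positive morphometric scales by per-feature
strictly increasing maps (lognormal-type for volumes and areas,
scaled-exponential for thicknesses); since the pipeline is rank-based,
these maps cannot affect results. Whole-brain aggregate columns (the
normalizers) get deliberately small marginal spreads: real whole-brain
aggregates vary far less across subjects than single regions, and a
noisy normalizer would inject a spurious common-denominator correlation
into every normalized feature.

The layered-continuum design (rather than isolated correlation blocks)
is what makes the generator emulate the key empirical property the
analysis relies on: at link density 0.15 the thresholded network is
connected, with a smooth unimodal correlation distribution. Group
differences are planted by scaling every structural loading of a chosen
node set by `sqrt(1 − planted_delta)` in the case group, so
`planted_delta = 0` is an exact null and `planted_delta = 1` fully
decorrelates the planted nodes. Ages are drawn as
`min + lognormal` per group, identical by default so the
Kolmogorov–Smirnov balance gate passes, with an option to inject bias
to exercise the gate.

What the generator does **not** emulate: multi-site acquisition
effects, realistic FreeSurfer measurement error, age- or head-size-
dependent covariance, or heavy-tailed marginals. Passing tests on
synthetic cohorts therefore validate the machinery and its statistical
calibration, not any claim about a particular clinical dataset.

# Statistical behaviour worth knowing

**Bootstrap bias of the asymmetric design.** Subsampling `M_sub`
subjects *with replacement* yields fewer distinct subjects than an
independent sample of the same size, hence noisier correlation
estimates, and under fixed-density thresholding noisier estimates
select systematically larger values at the boundary. Strength-like
whole-network averages are therefore slightly higher in the subsampled
null than in the single case network built from distinct subjects. For
measures with a real group effect this bias is negligible; for
near-zero effects it can dominate and even flip the sign relative to
the symmetric design in which both groups are subsampled and the bias
cancels. The package exposes both designs (`mode = "single_case"`,
`mode = "both"`); their effect signs agree for effects above the
subsampling noise floor, which is how the test suite asserts their
consistency.

**Null calibration.** On equal-size null cohorts (no planted effect)
the fraction of whole-network |z| > 2 across the eleven non-degree
measures is under 10% in the frozen test configuration — conservative
rather than exact, partly because the bootstrap null is slightly wider
than the case's sampling distribution.

**Problem sizes.** The shipped tests and the acceptance script run on
reduced schemas (roughly 80–300 nodes), cohorts of 40–200 subjects per
group, and `K` of 100–200 repetitions, chosen so the full statistical
suite completes in a few minutes while leaving every qualitative
behaviour of the full-scale analysis (fixed density, connectedness,
planted-effect recovery, calibration) intact. The analysis scripts
under `analysis/` state their own sizes; all parameters scale to a
production run (419-feature schema, hundreds of subjects, `K = 5×10⁴`)
without code changes.

# Known limitations

* The spectral measures require connected networks; heavily
  fragmented regimes (extreme `q`) are out of the design envelope.
* No multiple-testing correction is applied across the per-node tests;
  the output reports raw z and empirical p, and the ranking tables are
  meant as effect-size orderings, not families of significant calls.
* The empirical p resolution is `1/K`; with small `K` the `p_bound`
  flag should be taken seriously.
* Box-Cox z-scores are not invariant to affine shifts of the
  centrality scale (the transform is nonlinear by design); comparisons
  should always be read on the measure's native scale.
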