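# brainwcn

Structural covariance network analysis of brain morphometry tables.

Morphometric features extracted from structural MRI — regional volumes,
surface areas, cortical thicknesses, curvature summaries in the layout
written by FreeSurfer's `asegstats2table`/`aparcstats2table` scripts —
co-vary across subjects, and the *pattern* of that covariance can differ
between groups even when the feature values themselves do not.
`brainwcn` is for researchers who want to compare that second-order
structure between a case group and a control group.

## The method

For each group, a weighted correlation network (WCN) is built over the
features:

1. the Spearman correlation matrix *r<sub>S</sub>* of the (normalized,
   left/right-augmented) features across subjects;
2. a binary adjacency *A* linking node pairs whose correlation exceeds
   the 0.85 quantile of the off-diagonal distribution, which fixes the
   link density at ρ = 0.15 for every network;
3. edge weights *w<sub>ij</sub>* = exp(−S<sub>ij</sub>²/σ²) with the
   chordal distance *S* = sin(½ arccos *r<sub>S</sub>*) and σ = 1.

Twelve node centralities are computed on (*A*, *W*): degree *K* and
strength *S*, nearest-neighbor degree/strength *K<sup>nn</sup>*,
*S<sup>nn</sup>*, closeness *CC*/*WCC*, betweenness *BC*/*WBC*
(normalized by C(N−1, 2)), clustering coefficient, edge-weight
disparity (inverse participation ratio), and spectral centrality
*SC*/*WSC* = Σ<sub>j</sub> M<sub>ij</sub>(ν<sub>i</sub>−ν<sub>j</sub>)²
from the Fiedler vector ν of the graph Laplacian.

Group comparison handles class imbalance by subsampling: the case group
is summarized by one network built from all its subjects, the control
group by *K* networks built from subsamples of *M*<sub>sub</sub>
subjects drawn with replacement. Whole-network (node-averaged) and
single-node centralities of the case are scored against the Box-Cox
regularized control distribution with
*z* = (*c*<sup>case</sup> − ⟨*c*⟩<sup>ctrl</sup>)/σ<sup>ctrl</sup>
and one-tailed empirical p-values (resolution floor 1/*K*). Because
the construction is rank-based, results are invariant to any strictly
monotone transform of the input features.

A synthetic-cohort generator (`generate_cohort()`) produces two-group
feature tables with realistic covariance structure and plantable group
differences, so the full pipeline is testable without any imaging data.
See the vignette in `vignettes/` for the model, conventions and design
decisions.

## Worked example

A 123-node study on a synthetic cohort (120 cases vs 200 controls) in
which the six cuneus features of the case group were given a weakened
correlation structure (`planted_delta = 0.6`):

```r
library(brainwcn)

schema <- make_canonical_schema(
  cortical_regions = DKT_CORTICAL_REGIONS[1:8],
  cortical_measures = c("volume", "area", "thickness"),
  subcortical_bilateral = SUBCORTICAL_BILATERAL[1:4],
  subcortical_other = SUBCORTICAL_OTHER[1:2])

cfg <- synth_config(
  n_case = 120, n_control = 200, schema = schema,
  planted_nodes = c("lh_cuneus_volume", "rh_cuneus_volume",
                    "lh_cuneus_area", "rh_cuneus_area",
                    "lh_cuneus_thickness", "rh_cuneus_thickness"),
  planted_delta = 0.6, seed = 42)
cohort <- generate_connected_cohort(cfg)

build_network(cohort$control)
#> corr_network: 123 nodes, 1126 links (density 0.1501, q = 0.850, sigma = 1)
#>   threshold rS > 0.3424235 ; components: 1

cmp <- compare_groups(cohort$case, cohort$control, K = 150, seed = 7)
cmp
#> wcn_comparison (single_case mode, one-tailed)
#>   K = 150  M_sub = 120  q = 0.85  sigma = 1
#>   redrawn repetitions: 2
#>        measure      z           p p_bound            flag
#>         degree  0.000 1.000000000   FALSE by_construction
#>       strength -0.457 0.326666667   FALSE
#>      nn_degree  1.619 0.053333333   FALSE
#>    nn_strength  1.130 0.133333333   FALSE
#>      closeness -1.121 0.126666667   FALSE
#>    w_closeness -2.202 0.013333333   FALSE
#>    betweenness  1.491 0.080000000   FALSE
#>  w_betweenness  1.491 0.080000000   FALSE
#>     clustering  0.775 0.213333333   FALSE
#>            ipr  2.991 0.006666667    TRUE
#>       spectral -2.516 0.006666667    TRUE
#>     w_spectral -2.280 0.013333333   FALSE
```

The degree row is 0/1 "by construction": quantile thresholding gives
every network in the study the same number of links, so the
node-averaged degree cannot differ. The `p_bound` flag marks values at
the 1/*K* resolution floor ("p < 1/K"). At the single-node level, the
planted cuneus perturbation dominates the strength ranking:

```r
rank_nodes(cmp, "strength", k = 5)
#>  rank     hemisphere region feature_measure          feature_id         z
#>     1          right cuneus  thickness_mean rh_cuneus_thickness -6.688927
#>     2          right cuneus          volume    rh_cuneus_volume -6.083320
#>     3           left cuneus          volume    lh_cuneus_volume -4.691585
#>     4  bilateral_avg cuneus          volume   avg_cuneus_volume -4.156170
#>     5 bilateral_asym cuneus    surface_area    asym_cuneus_area -3.862150
```

## The analysis workflow

The `analysis/` directory holds the numbered study drivers, each a thin
narrative script over the package functions, writing its tables under
`results/`:

| script | what it does |
|---|---|
| `analysis/01_simulate_cohort.R` | simulate the two-group cohort, write FreeSurfer-dialect tables, KS age-balance check |
| `analysis/02_build_networks.R` | ingest, normalize/augment, build and export both group networks |
| `analysis/03_centrality_profiles.R` | 12-measure centrality profiles and the measure cluster map |
| `analysis/04_compare_groups.R` | subsampled comparison, whole-network table, top-5 node rankings, symmetric-design check |

Run them in order from the repository root with `Rscript`.

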