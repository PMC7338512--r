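# ctshapes

Trajectory-shape analysis of cortical thickness (CT) development for
comparing autism spectrum disorder (ASD) and typically developing (TD)
cohorts — for neuroimaging researchers working with multi-center regional
thickness tables (ages 6–30) who want to test whether *how* the cortex
changes with age, rather than its thickness at any one age, distinguishes
the groups.

## What it computes

For each region of interest (ROI), polynomial age models of CT are fitted
per diagnostic group and summarized by their highest-order coefficients —
the trajectory **shape** parameters:

- slope β₁ of the linear model (mm/yr): constant rate of cortical change;
- curvature β₂ of the quadratic model (mm/yr²): acceleration of that rate;
- aberrancy β₃ of the cubic model (mm/yr³): change of the acceleration.

Around this core the package provides:

- a synthetic cohort/CT generator emulating multi-center structure, planted
  group contrasts, and symptom coupling (`ct_preset()`, `generate_cohort()`,
  `generate_ct()`, `generate_ados()`, `simulate_study()`);
- ABIDE-dialect phenotype/CT CSV readers and writers (`read_phenotypes()`,
  `read_ct()`, …);
- cohort filters and a within-center |z| > 3 outlier screen
  (`filter_age()`, `filter_small_centers()`, `zscore_outlier_filter()`);
- inter-center variance removal by regression with dummy-coded centers while
  preserving age, group, and age×group variance (`remove_center_variance()`);
- trajectory fitting, a χ² deviance test against the constant model,
  Benjamini–Hochberg masking, and the turning-point statistic
  (`fit_trajectory()`, `deviance_test()`, `fdr_mask()`, `turning_point()`);
- entropy-guided subject subsampling to manufacture within-group variability
  of the shape coefficients (`age_entropy()`, `draw_and_select()`,
  `fit_subsamples()`);
- mean-centered and behavioral partial least squares with subject-level
  permutation tests and bootstrap ratios (`mean_centered_pls()`,
  `behavioral_pls()`, `run_group_pls()`, `run_behavioral_pls()`);
- linear-SVM classification of trajectory shapes under a split-then-subsample
  cross-validation (`cross_validate()`, `compare_models()`), and an
  end-to-end orchestrator (`run_all()`) with YAML configuration.

## Worked example

Simulate a 400-subject, four-center study in which 20% of 40 ROIs carry a
planted ASD contrast (slower thinning, negative curvature), harmonize,
subsample, and test the group difference:

```r
library(ctshapes)

sim <- simulate_study("paper-like", n_asd = 200, n_td = 200,
                      n_roi = 40, seed = 1)
adj <- lapply(1:3, function(d) remove_center_variance(sim$ct, sim$cohort, d))

asd <- sim$cohort[sim$cohort$group == "ASD", ]
td  <- sim$cohort[sim$cohort$group == "TD", ]
set_asd <- fit_subsamples(draw_and_select(asd, n = 35, n_candidates = 500,
                                          K = 20, seed = child_seed(1, "asd")),
                          adj, sim$cohort)
set_td  <- fit_subsamples(draw_and_select(td, n = 35, n_candidates = 500,
                                          K = 20, seed = child_seed(1, "td")),
                          adj, sim$cohort)
pls <- run_group_pls(set_asd, set_td, ct = adj, cohort = sim$cohort,
                     n_perm = 500, n_boot = 500, seed = child_seed(1, "pls"))
summary(pls)
#> PLS (mean_centered), LV1
#>   sigma = 0.020347 ; p_perm = 0.001996
#>   corrected p = 0.005988
#>   largest |bootstrap ratios|:
#>     ROI007_slope     ROI003_slope     ROI002_slope     ROI006_slope
#>            19.13            17.56            16.90            15.14
#>     ROI008_slope     ROI005_slope     ROI004_slope     ROI001_slope
#>            13.21            12.39            12.01            11.25
#> ROI002_curvature ROI007_curvature
#>            -9.37            -8.52
```

The group contrast is significant after Bonferroni correction across
parcellations (corrected p ≈ 0.006 from 500 subject-level permutations), and
the most reliable features are exactly the planted ROIs (ROI001–ROI008):
positive slope bootstrap ratios (slower thinning in ASD) and negative
curvature ratios (more negative curvature in ASD), while aberrancy features
stay near zero. Per-ROI fits expose the trajectory itself:

```r
f <- fit_trajectory(asd$age, adj[[2]][asd$subject_id, "ROI001"], degree = 2,
                    roi = "ROI001", group = "ASD")
f
#> Trajectory fit: quadratic (curvature) for ROI001
#>   group: ASD
#>   n = 200 ; shape coefficient = -0.00071199
#>   coefficients:
#>           b0           b1           b2
#>  2.251860000  0.026328500 -0.000711993
turning_point(f)
#> [1] 18
```

The negative-curvature trajectory is furthest from its age-6-to-30 chord at
18 years — the age at which decreased cortical thinning turns into
increased thinning.

A full run from CSV inputs goes through configuration:

```r
cfg <- default_config()      # or read_run_config("run.yaml")
cfg$seeds$master <- 7
res <- run_all(cfg, "phenotypes.csv", "ct.csv", output_dir = "results")
```

A thin command-line wrapper with `simulate`, `run`, and `classify`
subcommands is installed at `inst/cli/ctshapes.R`.

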