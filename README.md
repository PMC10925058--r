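# perfvol

Coupling of regional pulmonary perfusion and blood volume from dynamic PET.

## What this package is for

Regional pulmonary blood volume (the intravascular fraction `F_b` of a lung
region) is often imaged as a surrogate for regional perfusion `Q`. In early
ARDS the vasculature changes, and the surrogacy itself may change with it.
`perfvol` implements the full analysis chain needed to study that question
on dynamic PET data — and, because such animal PET datasets are not
publicly deposited, a seeded synthetic phantom that emulates the study
design (5 animals × 2 conditions × 30 regions of interest) so the entire
chain runs, and is tested, end to end without any download.

The chain:

1. **Kinetics.** Per-ROI blood fraction `F_b` by fitting dynamic ¹⁸F-FDG
   curves to the three-compartment Sokoloff model
   `C_ROI(t) = F_b C_p(t) + C_e(t) + C_m(t)` (bounded weighted nonlinear
   least squares with multistart); regional perfusion `Q_r` from ¹³NN-saline
   breathhold curves as plateau + early-peak excess (shunt).
2. **Regional algebra.** `F_tis = 1 − F_gas − F_b`,
   `F_tis,n = F_tis / mean(F_tis)`, `Q_n = Q_r / mean(Q_r) / F_tis,n`,
   `F_bn = F_b / mean(F_b) / F_tis,n`, per animal-condition over its 30
   ROIs; longitudinal adjustment `Q_a = Q_n · CO_INJ/CO_BL`,
   `F_ba = F_bn · V_B,INJ/V_B,BL` with `V_B = Σ F_b · V_ROI`.
3. **Statistics.** A two-sample multivariate kernel-density test
   (closed-form integrated squared difference of the two KDEs, unconstrained
   plug-in bandwidths, asymptotic or permutation null); a six-model
   least-squares zoo (`y = ax`, `y = a + bx`, `y = ax + bx²`,
   `y = a + bx + cx²`, `y = e^(ax)`, `y = ae^(bx)`) ranked by
   `BIC = n log(RSS/n) + (k+1) log n` in both variable orientations;
   likelihood-ratio tests of nested forms; stratified piecewise-linear fits
   along the vertical gradient.

Everything takes and returns tibbles and composes with the pipe; fitted
objects have `tidy()`/`glance()` methods and `plot_*()` helpers.

## Worked example

Simulate the two conditions' normalized point clouds at the study's size
(150 ROIs each), test whether they differ, and characterize each coupling:

```r
library(perfvol)

cfg      <- phantom_config(seed = 2026)
baseline <- simulate_coupling_cloud(cfg, "baseline")
injury   <- simulate_coupling_cloud(cfg, "injury")

kde_two_sample_test(baseline[, c("q_n", "f_bn")],
                    injury[, c("q_n", "f_bn")])
#> <kde_test> two-sample kernel-density test (asymptotic)
#>   n1 = 150  n2 = 150
#>   T = 0.98751  z = 34.2  p = < 2.2e-16

zoo <- fit_model_zoo(injury)
best_model(zoo)[, c("form", "label", "a", "b")]
#> # A tibble: 1 × 4
#>   form             label             a      b
#>   <chr>            <chr>         <dbl>  <dbl>
#> 1 quadratic_origin y = ax + bx^2  1.68 -0.536

likelihood_ratio_test(zoo[zoo$form == "linear", ],
                      zoo[zoo$form == "quadratic", ])
#> <lrt_result> linear vs quadratic
#>   chi-square = 498.92  df = 1  p = < 2.2e-16

best_model(fit_model_zoo(baseline))[, c("form", "a", "b")]
#> # A tibble: 1 × 3
#>   form       a     b
#>   <chr>  <dbl> <dbl>
#> 1 linear 0.301 0.704
```

Read: the two clouds are emphatically not from the same distribution
(p ≪ 0.001); the baseline coupling is best described by a line
(`F_bn ≈ 0.30 + 0.70 Q_n` here), the injured lung by a through-origin
quadratic (`F_bn ≈ 1.68 Q_n − 0.54 Q_n²`) — blood volume saturates while
perfusion keeps rising, so `F_b` stops being a faithful perfusion
surrogate, and the likelihood-ratio test confirms the curvature is not a
fitting artefact.

The full pipeline (simulate → fit both tracers per ROI → normalize →
adjust → analyze → tabular report) is one call:

```r
report <- run_pipeline(run_config(phantom_config(seed = 1)),
                       out_dir = "report/")
report$profiles       # per-height-level means/sds (vertical profiles)
report$longitudinal   # per-ROI baseline -> injury changes
```

A thin CLI wrapper lives at `inst/scripts/perfvol-pipeline.R`
(`simulate` and `run-all` subcommands with `--seed`, `--out`,
`--config`).

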