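# atrophyfront

Growth-rate metrics for geographic atrophy (GA) — the late atrophic form
of age-related macular degeneration — are the primary anatomic endpoint
of GA clinical trials, yet the popular *length-type* metrics (mm/year)
have mostly been interpreted only for circular lesions growing
isotropically. `atrophyfront` implements the atrophy-front growth model,
in which the lesion margin advances with a local normal speed given by a
nonnegative growth field `v(x)` (mm/year), and uses it to simulate
lesion growth and to quantify the accuracy of the two families of
length-type estimators:

* **effective radius / square-root-of-area**:
  `Λ̂_ER = (√(A_f/π) − √(A_b/π)) / Δt` (the √-area variant is `√π`
  times larger);
* **perimeter-adjusted**:
  `Λ̂_PA = ((A_f − A_b)/Δt) / ((P_b + P_f)/2)`.

Both estimate the ground-truth length-type rate `Λ`, the position-time
average of `v` along the evolving margin. Under the model,
`Λ̂_PA = Λ` exactly for convex lesions under isotropic time-invariant
growth, while `Λ̂_ER/Λ → 1/√circ` for small growths
(`circ = 4πA/P²`), which equals `√n` for `n` equal circular foci — so
the square-root family inflates with noncircularity and multifocality.

The package is aimed at researchers studying GA progression measurement:
it provides the eikonal (second-order fast-marching) front propagator
with an independent level-set cross-check, subpixel contour-based shape
descriptors (area, perimeter, circularity, focality, Gini-weighted
focality), calibrated random growth-field generators, a lesion factory
(eight benchmark configurations plus clinical-like synthetic baselines),
and tidy experiment drivers with `tidy()`/`glance()`/`autoplot()`
methods.

## Worked example

Benchmark configuration 5 — two equal circular foci totalling 6 mm²,
isotropic field calibrated to Λ = 0.1 mm/year — propagated for one year
on a 24-µm grid:

```r
library(atrophyfront)

cfg <- make_config(5, pixel_size_mm = 0.024)
shape_descriptors(cfg$baseline)
#> # A tibble: 1 × 5
#>   area_mm2 perimeter_mm circularity focality gini_focality
#>      <dbl>        <dbl>       <dbl>    <int>         <dbl>
#> 1     6.00         12.3       0.500        2             2

sq <- propagate(cfg$baseline, cfg$field, dt_years = 1, n_steps = 10)
ground_truth_lambda(sq)
#> <ground_truth_rate> Lambda = 0.1 mm/yr (11 margin samples)

lesion_metrics(sq$states[[1]], sq$states[[11]])[
  , c("lambda_hat_er", "lambda_hat_sqrt_area", "lambda_hat_pa")]
#> # A tibble: 1 × 3
#>   lambda_hat_er lambda_hat_sqrt_area lambda_hat_pa
#>           <dbl>                <dbl>         <dbl>
#> 1         0.141                0.251        0.1000
```

The two equal foci have circularity 1/2, so the effective-radius
estimate is inflated by `1/√0.5 = √2` (0.141 instead of 0.1 mm/year;
`predicted_er_bias(0.5)` returns 1.414), while the perimeter-adjusted
estimate recovers the true 0.1 mm/year. `run_config_sweep()` repeats
this over all eight configurations and growth rates 0.05–0.7 mm/year;
`run_semisim()` runs the semisimulated ensemble (synthetic baseline
cohort × random calibrated fields) and `summarize_errors()` reduces it
to the error statistics; `autoplot()` draws the standard figures. The
methods vignette (`vignettes/atrophy-front-model.Rmd`) documents the
model, the numerical choices and the generator design.

A thin command-line wrapper over the same functions is included for
shell use:

```sh
Rscript inst/cli/ga-growth.R make-configs --out configs/
Rscript inst/cli/ga-growth.R sweep --configs 1,2,5 --out sweep.csv
Rscript inst/cli/ga-growth.R metrics --csv pairs.csv --out estimates.csv
```

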