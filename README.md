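# cyclemark

Simulation and image-analysis toolkit for cell-cycle-coupled histone-mark
inheritance.

## The scientific problem

Every histone modification is diluted two-fold when DNA replicates and must
be restored by writer enzymes. Restoration speed varies by orders of
magnitude: activating marks such as H3K4me3 recover within hours, while
repressive marks such as H3K27me3 need roughly a full cell cycle. A cell
that shortens G1 re-enters S phase before slow marks have recovered, so fast
cycling progressively erodes repressive chromatin — a proposed mechanism for
why short-G1 cells reprogram to pluripotency more efficiently.

`cyclemark` makes this mechanism quantitatively testable on one desktop:

* **Kinetics** — exact solution of the dilution–restoration ODE
  `dM/dτ = k (ρ c(τ) − M)` at the periodic steady state imposed by division
  (`steady_state_mark()`).
* **Synthetic microscopy** — unsynchronized populations
  (`simulate_population()`) rendered to multi-channel nucleus images with
  illumination gradients, Poisson–Gaussian noise, and full ground truth
  (`render_image()`).
* **Imaging pipeline** — illumination correction, rolling-ball background
  subtraction (Rcpp), watershed segmentation, integrated-intensity
  measurement, 1-D cell-cycle ordering, six-stage assignment, and
  DNA-normalized stage profiles (`stage_image_pipeline()`).
* **Cycle statistics** — propidium-iodide histogram deconvolution
  (`fit_pi_histogram()`), FUCCI gating, doubling time and phase durations.
* **Expression-side tools** — reprogramming-barrier classification,
  TF-activity scoring along pseudotime, DTW trajectory comparison, and an
  siRNA colony-screen analysis, each with planted-truth simulators.

Everything tabular is a tibble; fitted objects support `tidy()`, `glance()`,
and `autoplot()`.

## Worked example

Solve the steady-state kinetics of a slow mark (k·T ≈ 1) on a 23 h cycle
with a 10 h G1:

```r
library(cyclemark)

cyc <- cycle_params(t_g1 = 10, t_s = 8, t_g2 = 4, t_m = 1)
slow <- mark_kinetics("H3K27me3", 1 / 23)
steady_state_mark(cyc, slow)
#> # A tibble: 512 × 5
#>      tau phase   dna  mark density
#> *  <dbl> <fct> <dbl> <dbl>   <dbl>
#> 1 0      G1        1 0.584   0.584
#> 2 0.0449 G1        1 0.584   0.584
#> 3 0.0898 G1        1 0.585   0.585
#> 4 0.135  G1        1 0.586   0.586
#> # ℹ 508 more rows
```

The density column peaks at the end of G1 and troughs at the end of S —
the dilution–restoration signature. Now simulate a population carrying a
slow and a fast mark, render it, and run the full imaging pipeline:

```r
cells <- simulate_population(cyc, list(slow, mark_kinetics("H3K4me3", 50 / 23)),
                             n = 200, seed = 1)
img <- render_image(cells, cycle = cyc, seed = 2)
res <- stage_image_pipeline(img$channels, min_cells = 10)
tidy(res$profiles$H3K27me3)
#> # A tibble: 6 × 7
#>   stage     n mean_mark mean_dna mean_ratio norm_ratio ok
#>   <fct> <int>     <dbl>    <dbl>      <dbl>      <dbl> <lgl>
#> 1 G1M      28   140554.  204317.      0.688      1.14  TRUE
#> 2 G1L      29   146596.  206806.      0.709      1.18  TRUE
#> 3 SE       35   159355.  259170.      0.621      1.03  TRUE
#> 4 SML      35   181688.  352611.      0.517      0.858 TRUE
#> 5 G2EM     30   212491.  405483.      0.524      0.870 TRUE
#> 6 G2L      15   226349.  407115.      0.556      0.923 TRUE

glance(res$profiles$H3K27me3)
#> # A tibble: 1 × 6
#>   mark     n_stages n_cells   auc auc_raw ratio_range
#>   <chr>       <int>   <int> <dbl>   <dbl>       <dbl>
#> 1 H3K27me3        6     172  4.97    2.99       0.319
```

The recovered profile peaks at late G1 (G1L) and declines through S,
matching the kinetic prediction, entirely from rendered pixels. The
fast-mark profile (`res$profiles$H3K4me3`) is flat. PI-histogram
deconvolution closes the loop on phase fractions:

```r
h <- simulate_pi_histogram(c(0.5, 0.25, 0.25), n = 50000, seed = 1)
fit_pi_histogram(h)
#> PI histogram fit
#>   2N position: 50.02  (cv 0.051)
#>   fractions: G1 0.500  S 0.250  G2/M 0.249
```

`autoplot()` works on trajectories, stage profiles, and PI fits;
`cyclemark_demo(out_dir)` writes a complete, manifest-stamped pipeline run.

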