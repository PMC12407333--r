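---
title: "Methods: cycle-coupled histone-mark restoration and image-based staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cycle-coupled histone-mark restoration and image-based staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclemark)
```

# The scientific question

During DNA replication, nucleosomes are distributed to both daughter strands,
so every histone modification is diluted two-fold per cell cycle and must be
restored by writer enzymes. Marks differ enormously in restoration speed:
activating marks such as H3K4me3 are restored within minutes-to-hours, while
repressive marks such as H3K27me3 take on the order of a full cell cycle.
A cell that shortens G1 therefore re-enters S phase before slow marks have
recovered, progressively eroding repressive chromatin — a mechanism proposed
to explain why fast-cycling, short-G1 cells reprogram to pluripotency more
efficiently.

`cyclemark` provides a self-contained computational test bed for this
mechanism: a kinetic model of mark dilution and restoration, a synthetic
microscopy generator with ground truth, an image-analysis pipeline that
recovers cell-cycle stage and per-stage mark levels from rendered images,
and the companion statistical tools (PI-histogram deconvolution, FUCCI
gating, TF-activity scoring, trajectory comparison, barrier classification,
and an siRNA-screen analysis).

# The dilution–restoration model

For one mark with restoration rate constant $k$ and target density $\rho$,
the total nuclear amount $M(\tau)$ at cycle position $\tau$ obeys

$$\frac{dM}{d\tau} = k\,\big(\rho\, c(\tau) - M\big),$$

where $c(\tau)$ is the DNA content schedule: 1 throughout G1, rising
linearly from 1 to 2 across S, and 2 through G2/M. Cell division halves the
amount, giving the periodic steady-state condition $M(0) = M(T)/2$.

Because $c(\tau)$ is piecewise constant/linear, the ODE is solved *exactly*
segment by segment: on constant-$c$ segments the solution is a single
exponential relaxation, and on the S-phase segment the particular solution
of the linear forcing is $\rho\,c(\tau) - \rho s / k$ with $s$ the slope of
$c$. `steady_state_mark()` iterates the division condition to a fixed point
and returns the trajectory together with the *density*
$r(\tau) = M / (\rho\, c(\tau))$, the quantity a DNA-normalized image
measurement estimates. The test suite checks the analytic propagation
against a dense Runge–Kutta integration at ten-fold finer step.

Two regimes matter:

* **slow mark** ($kT \approx 1$, the H3K27me3 analogue): density climbs
  through G1 (restoration with no dilution), peaks at the end of G1, is
  diluted faster than it is restored through S, and troughs at the end of S;
* **fast mark** ($kT \gg 1$, the H3K4me3 analogue): restoration tracks
  replication almost instantaneously and the density profile is flat.

Shortening G1 removes most of the slow mark's recovery window, so its
cycle-averaged density and its stage-to-stage dynamic range both shrink,
while the fast mark is untouched. When comparing a 10 h-G1 and a 2 h-G1
condition the package keeps the *absolute* rates fixed (1/23 and 50/23 per
hour) in both conditions — the chemistry of the writer enzymes does not know
the cycle length.

# Synthetic populations and image rendering

`simulate_population()` draws unsynchronized cells from either a uniform age
distribution or the exponential-growth distribution (density
$\propto 2^{-\tau/T}$, so young cells are over-represented two-fold), then
evaluates DNA content, each mark's steady-state amount, and FUCCI reporter
intensities (mCherry high in G1 and decaying over early S; mCitrine rising
across S and high in G2/M).

`render_image()` paints one elliptical nucleus per cell on a jittered grid
(guaranteed non-overlap), with integrated intensity in each channel exactly
proportional to the generating quantity and nuclear area growing linearly
with cycle position. The field is then corrupted with an additive low-order
polynomial illumination gradient, Poisson shot noise, Gaussian read noise,
and 16-bit quantization. Ground truth (label mask and per-nucleus table) is
returned alongside, which is what lets the test suite score segmentation IoU
and staging accuracy rather than eyeballing images.

Known simplifications: nuclei never touch (placement is gridded), noise is
pixel-independent, and FUCCI intensities are noise-free at the cell level.
These keep the generator analytically checkable; the watershed splitter is
exercised by a dedicated constructed doublet instead.

# The imaging pipeline

`stage_image_pipeline()` chains, per channel:

1. **Illumination correction** — block minima (64-px blocks) fit with a 2-D
   polynomial (order 2) and subtracted; block minima approximate the
   background because nuclei are sparse and bright.
2. **Rolling-ball background subtraction** — a grayscale opening with a
   non-flat (spherical-cap) structuring element, implemented in Rcpp; for
   large radii the image is block-min downsampled, opened, and the
   background bilinearly upsampled, the standard fast approximation.
3. **Segmentation** on the DNA channel — Otsu threshold, hole filling,
   distance-map watershed (EBImage), and an area filter.
4. **Measurement** — integrated (summed) intensity per channel over each
   mask label plus morphology (area, centroid, eccentricity, perimeter,
   solidity). Integrated — not mean — intensity is what scales with total
   DNA or mark amount.

## Ordering and staging

`order_cells()` min-max scales the selected features (default: integrated
DNA and area), projects onto the leading principal axis, and orients the
axis by its correlation with DNA, yielding a 1-D cycle coordinate in
$[0, 1]$. `assign_stages()` finds the 2N and 4N modes of the DNA intensity
distribution, smooths DNA along the ordering, and locates the S-phase region
between the two plateaus; the flank crossings at 15% of the 2N–4N span are
linearly extrapolated back to the plateau values so the G1/S and S/G2
boundaries are unbiased. Six analysis stages follow: the first G1 tercile is
*excluded* (early-G1 nuclei are small and dim, the usual practice), the
remaining terciles are G1M and G1L; S splits at its midpoint into SE and
SML; G2/M splits at two-thirds into G2EM and G2L. Supplying FUCCI thresholds
lets the reporter gate override the DNA-based region (an mCherry+/mCitrine−
nucleus can never be called G2).

`stage_profile()` reports, per stage, the mean mark/DNA ratio normalized by
its across-stage mean, plus a trapezoidal AUC over the retained stages.
Stages holding fewer than `min_cells` nuclei are flagged and excluded.

## Comparing conditions with different G1 lengths

A 2 h-G1 condition puts only ~9 of 200 nuclei in each G1 tercile, so its
G1 stages fall below the default `min_cells = 20` and the two conditions
retain *different* stage sets — raw AUCs are then incomparable.
`compare_profiles()` restricts both profiles to the stages retained in both,
renormalizes each on that common support, and compares dynamic range and
AUC on equal footing; the packaged comparison protocol uses
`min_cells = 5`. Across 20 seeded replicates, the slow mark's range is
larger in the long-G1 condition in ≥ 18 replicates, while the fast mark's
between-condition AUC difference stays inside the within-condition
replicate noise.

# Statistical companions

* **PI-histogram fit** (`fit_pi_histogram()`): a Gaussian at the 2N
  position, a Gaussian constrained near twice that position, and an S-phase
  plateau modelled as a uniform density between the peaks convolved with
  the measurement width (a difference of normal CDFs). Weights are softmax
  parameterized, so fractions are always a valid composition; fitting is
  least squares via L-BFGS-B.
* **Doubling time / phase durations**: $T_d = \Delta t \ln 2 / \ln(n_1/n_0)$,
  and durations $T_d \times$ fraction, which sum to $T_d$ exactly.
* **Barrier classes** (`classify_barriers()`): four magnitude rules on mean
  log2 expression in MEF, pre-iPSC, iPSC, ESC with threshold `delta`. The
  rules are not mutually exclusive in a corner configuration (a gene can be
  pre-iPSC-high over MEF while both pluripotent states sit even lower), so
  a fixed precedence (over_up, insufficient_up, over_down,
  insufficient_down) makes the output a partition.
* **TF activity** (`activity_score()`): mean over up-targets minus mean over
  down-targets — means, not sums, so target-set size cancels.
  `activity_trajectory()` bins cells into equal-occupancy pseudotime bins
  (single-cell pseudotime density is uneven) and flags bins under 3 cells.
* **Trajectory comparison**: classic unnormalized DTW (validated against
  exhaustive path enumeration), a strict-less-than distance partition,
  Pearson trend correlation with the exact t-based p-value, and a one-sided
  rank-sum comparison of a gene subset's distances against the full set.
* **Screen** (`count_colonies()` etc.): min-max rescale to 8-bit, fixed
  threshold 60/255, 8-connected labelling (Rcpp), particle filter at
  550 px — the classic particle-analysis recipe — followed by
  control-normalized efficiency, the two-class hit rule
  (efficiency < 0.7 with a rising expression trend, or > 1.3 with a falling
  trend), and a stage-restricted consistency matrix.

# Numerical and reproducibility choices

All stochastic generators take explicit seeds and save/restore the global
RNG state, so calling them never perturbs a user's random stream.
`run_pipeline()` writes a JSON manifest (config, config hash, seeds, row
counts, profile AUCs — no timestamps), making reruns byte-identical.
Problem sizes used in the packaged examples (200 nuclei per 512×512 field,
20 replicates, 112-gene screen panel, 50,000-cell PI histograms) were chosen
so the full suite runs on one CPU in minutes.
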