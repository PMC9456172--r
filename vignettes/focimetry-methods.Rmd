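---
title: "Methods: estimators, generators and defaults"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimators, generators and defaults}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focimetry)
```

This vignette records the quantitative reasoning behind `focimetry`'s
estimators, the design and limits of its synthetic generators, and the
rationale for the package defaults. The companion README shows the user-facing
workflow; here we justify the numbers.

## Cell-cycle kinetics from pulse-chase re-appearance

A short EdU pulse (default 20 minutes) labels exactly the cells that were in
S phase during the pulse. At each chase time the cells are classified by DNA
content into 2N / midN / 4N windows (`[0.8, 1.2]`, `(1.2, 1.6)`, `[1.6, 2.4]`
times the G1 peak) crossed with EdU status, giving the six populations
2N±, midN±, 4N±.

The estimator works from one curve: `R(t)`, the fraction of assigned EdU⁺
cells sitting in the 2N window at chase time `t`. A labelled cell can only be
2N after it divides, so `R(t)` is a re-appearance curve with an analytically
simple shape for an asynchronous (uniform-age) cohort:

- **Rising edge onset.** The first labelled mitoses come from cells that had
  just finished synthesis at the pulse; they need only `T_G2M` to divide.
  The linearly interpolated up-crossing of a low level `q_lo` therefore
  estimates `t_up(q_lo) = T_G2M + q_lo * T_S`, because the mitosis wave moves
  through the labelled cohort at rate `1/T_S`.
- **Rising-edge slope.** The same wave argument gives
  `t_up(q2) - t_up(q1) = (q2 - q1) * T_S` for any two levels on the rising
  edge. The defaults `q_s = c(0.25, 0.60)` sit away from the curve's kinks
  (where linear interpolation between hourly samples is exact up to counting
  noise) and below the plateau, which stays under 1 whenever G1 is shorter
  than roughly `0.8 * T_S`. Hence `T_S = (t_up(0.60) - t_up(0.25)) / 0.35`.
- **Falling edge.** After a full cycle the labelled cohort re-enters S and
  leaves the 2N window. A divided cell stays inside the window through G1
  plus the first `(w_hi2n - 1)` of S, where `w_hi2n = 1.2` is the upper 2N
  edge; so the down-crossing satisfies
  `t_dn(q_lo) = T_cycle + (w_hi2n - 1 - q_lo) * T_S` and inverting gives
  `T_cycle = t_dn(q_lo) - 0.15 * T_S` at the defaults
  (`q_lo = 0.05`, `w_hi2n = 1.2`).

Two guards matter in practice. First, the 2N window holds early-S EdU⁺ cells
at `t = 0` (cells pulsed just after G1 exit still sit below the `1.2 ×` edge),
so crossings are only counted after that initial occupancy has cleared below
`q_lo`. Second, every estimate degrades to `NA` — never to a wrong number —
when its crossing does not occur; a G2-arrested cohort, for example, yields
`T_cycle_h = NA` because labelled cells never re-appear at 2N.

`T_G1_exit_h` is deliberately *not* a G1 duration: it is the first time the
midN⁻ fraction of EdU⁻ cells exceeds `g1_exit_level`, i.e. a checkpoint
readout of G1→S progression onset that a G1 block delays. The alternative
`g2m_method = "4n_decay"` (first time the 4N⁻ fraction falls below 10% of its
initial value) is only meaningful when inflow into G2 is blocked, as after
irradiation, and is left off by default.

On the reference simulation (G1 6 h, S 4.5 h, G2/M 3.5 h, 5,000 cells per
hourly time point, 5% measurement CV) the estimator recovers
`T_cycle ≈ 14 h` and `T_S ≈ 4.5–4.9 h`, inside the expected 13–15 h and
4–5 h windows.

## The pulse-chase generator and EdU halving

`simulate_pulse_chase()` draws each cell's cycle position (uniform by
default, optionally exponential-age), computes true DNA content (2 in G1,
linear from 2 to 4 across S, 4 in G2/M) and true EdU content as the overlap
between the pulse interval and the cell's time in S. Chase evolution is
deterministic given the draw: a cell advances by the chase time, wrapping at
division, and its EdU label is divided by exactly 2 at every division —
halving happens at mitosis, not continuously — so with measurement noise off
the relation `edu(t) = edu(0) / 2^n_divisions` holds to the last bit, and the
test suite asserts it with `expect_identical()`. Log-normal multiplicative
noise (default 5% CV) is applied only to the *measured* columns; the `truth`
table stays noise-free. Checkpoint arrest options (G1 block fraction,
G2 block) freeze the affected cells' positions and division counts.

Limits: there is no cell death, no cycle-time variability between cells, and
EdU background is zero by default (tests use a small explicit threshold of
0.02 in place of a negative-control percentile).

## Microscopy scenes, the refined focus threshold and the 8σ rule

`random_scene_spec()` plants elliptical nuclei (semi-axes 3.2–4.2 µm at
0.2 µm/px) with known per-nucleus DNA photon budgets, and Gaussian foci with
known photon counts on a nucleoplasmic pedestal, plus background, an optional
illumination gradient, Poisson noise and read noise. The truth table records
exact per-nucleus focus counts and the planted *photon fraction* — the share
of the channel's nuclear photons sitting in foci.

`segment_foci()` thresholds the white top-hat image at
`mean + k_sigma * SD` of the per-nucleus background. A naive mean/SD over
all nuclear pixels is contaminated by the foci themselves; on bright-focus
nuclei this inflated threshold made dim foci fall under the minimum area and
be lost. The implementation therefore uses the standard fixed-point
refinement: recompute mean and SD over pixels at or below the current
threshold, iterate until the threshold stabilises (at most 20 iterations,
relative tolerance 1e-8). This is not a tuned constant — it restores the
background-only statistics that the `k_sigma` rule assumes.

With the refined (lower, uncontaminated) threshold, two foci planted close
together can merge above threshold. The generator therefore places foci at
least `8 * sigma` apart: at that separation the above-threshold cores of
neighbouring spots are disjoint for any sensible adaptive threshold, so the
planted count is unambiguous *for a resolution-limited detector*. This is an
identifiability requirement on the ground truth, not tuning: no pixel-based
detector can be graded on sub-resolution pairs. Under these conditions the
full chain recovers exact nucleus and focus counts on 100/100 random scenes
and planted photon fractions to within 0.02 (criterion: ±0.05).

`measure_foci()` measures each focus through a 2-pixel dilated collar
(clipped to the parent nucleus, never crossing into another focus), because
the threshold cuts the Gaussian tails off the segmented core; the
nucleoplasm reference is the median outside the *dilated* foci, and the
background-subtracted intensity is `integrated - area * nucleoplasm`,
floored at zero.

## SMLM rendering, ICCS and cluster counting

`render_localizations()` deposits each molecule as a unit-mass
pixel-integrated Gaussian (differences of the normal CDF per pixel, truncated
at 5σ, mass exact to ~1e-6), with the width floored at 1 pixel
(`sigma_min_px`) so precision-scaled rendering cannot alias.

Two rules matter for image cross-correlation spectroscopy (ICCS):

- **Bounds must equal the data domain.** Padding the render adds a shared
  dark frame to both channels; that frame is genuine common structure and
  inflates the colocalized-fraction null from ~0.02 to ~0.1.
- **Render width at least twice the channel jitter.** ICCS fits a
  Gaussian + offset to the circular (FFT) cross-correlation; independent
  localization jitter `j` attenuates the cross amplitude by
  `2*sigma^2 / (2*sigma^2 + j^2)`. At `sigma = 50 nm` and jitter 10 nm the
  attenuation is negligible; at 30 nm jitter, render at `sigma = 80 nm` or
  use the width-based `"volume"` estimator, which is jitter-tolerant by
  construction.

The fitted squared width is bounded by `fit_radius_px^2`: structure wider
than the fit region is unresolvable from a constant and must be absorbed by
the offset (unbounded fits collapse to a huge Gaussian cancelling a negative
offset and report f = 1 on pure noise). A fixed-width linear fallback handles
near-flat correlations. All four estimators (amplitude, volume, M1, M2) are
clipped to [0, 1], and a non-positive cross amplitude reports f = 0.

`count_spots_in_foci()` reuses the adaptive focus segmentation on the
rendered reference channel, treating the whole field as one "nucleus". On a
sparse localization map the refined background is essentially empty space,
so an SD-based threshold alone would mark every isolated molecule as a
cluster; `focus_params(min_threshold = ...)` therefore floors the threshold
at three times the single-emitter peak `1 / (2*pi*sigma_px^2)` — a cluster
must be at least three overlapping emitters dense.

## Proximity association

`associate_spots_to_foci()` assigns each spot to the nearest focus *within
the same cell* and calls it adjacent when the distance is at most the
threshold (inclusive; default 1 µm, the conventional PLA adjacency scale).
The implementation is vectorised but the test suite pins it, scene by scene,
to a deliberately naive double-loop oracle, and checks that the adjacent
count is monotone in the threshold. Cells without foci yield `NA` distances
(not zero), and per-cell summaries keep focus-only and spot-only cells.

## Defaults worth knowing

| Default | Value | Why |
|---|---|---|
| DNA windows | 0.8–1.2, 1.2–1.6, 1.6–2.4 × G1 peak | conventional 2N/4N gates with a CV-wide margin |
| `q_lo`, `q_s` | 0.05, (0.25, 0.60) | away from curve kinks; plateau-safe (see above) |
| pulse | 1/3 h | short against `T_S`, so labelling ≈ instantaneous S snapshot |
| focus `k_sigma` | 3 | false-positive rate ~1e-3 per nucleus area under refined stats |
| adjacency | 1 µm | PLA linkage scale |
| render `sigma_min_px` | 1 px | anti-aliasing floor |
| ICCS `fit_radius_px` | 10 | covers the correlation peak at default render settings |
| collar dilation | 2 px | recovers Gaussian tails cut by the threshold |

All thresholds and windows are configuration, not constants mined from the
test data; the synthetic generators publish their ground truth precisely so
that every default can be audited against it.
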