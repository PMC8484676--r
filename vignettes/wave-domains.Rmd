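---
title: "Modeling and quantifying cortical wave domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and quantifying cortical wave domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Cortical Rho GTPase activity in large embryonic cells can self-organize into
*wave domains*: coexisting sub-regions of the cell cortex in which activity
waves propagate coherently in one direction, different from the neighboring
sub-regions. This package provides (i) a stochastic reaction–diffusion model
that generates such dynamics on arbitrary cell-shaped domains and (ii) an
automated analysis pipeline that detects and quantifies wave domains in any
time-lapse record, simulated or experimental.

## The model

Three fields live on a pixel grid masked by the cell shape: the active,
membrane-bound GTPase `A` (slow diffusion `D_A`), the inactive cytosolic form
`I` (fast diffusion `D_I`), and F-actin `F`, a non-diffusing local inhibitor.
Interconversion follows the mass-conserved activator–substrate (wave-pinning)
motif with Hill-type positive feedback and an F-actin–dependent negative
feedback:

$$f = \left(k_0 + \gamma\,\frac{A^3}{A_0^3 + A^3}\right) I
    - \left(s_1 + s_2\,\frac{F}{F_0 + F}\right) A,$$

$$\partial_t A = f + D_A \nabla^2 A + \alpha_1 \xi_1,\qquad
  \partial_t I = -f + D_I \nabla^2 I - \alpha_1 \xi_1,\qquad
  \partial_t F = k_n A - k_s F + \alpha_2 \xi_2,$$

with per-pixel, per-step standard Gaussian noise $\xi_{1,2}$. The same noise
realization enters `A` and `I` with opposite signs: fluctuations shuffle
molecules between the two forms but never create or destroy them, so the
total `A + I` mass is a conserved quantity — the model describes processes
fast compared to expression-level changes. `model_params()` carries the
reference values (`D_A = 0.001/3`, `D_I = 0.1/3`, `gamma = 1`, `A0 = 0.4`,
`s1 = 0.5`, `F0 = 0.5`, `kn = 0.1`, `ks = 0.025`, all in model units); the
basal activation `k0` (0–0.3), the negative-feedback strength `s2` (0–1.3)
and the noise magnitudes (1e-15–3) are the knobs that select the dynamic
regime.

### Discretization

`run_simulation()` integrates with forward Euler (`dt = 0.001` au) on a
square grid (`h = 0.02` au) using a mask-weighted five-point Laplacian: each
neighbor flux is multiplied by the neighbor's mask value, so nothing leaks
across the cell boundary regardless of its shape, and the fluxes cancel
pairwise (zero net flux, verified exactly in the tests). The explicit scheme
requires `max(D_A, D_I) * dt / h^2 < 1/2`; the defaults give 0.083 and
`run_simulation()` refuses to start otherwise. Snapshots are saved every
1000 iterations (1 au of time) by default, and every saved state is audited
for total mass and per-field min/max, so conservation (relative deviation
within 1e-11) and positivity are checkable on every run.

The noise term is applied as `dt * alpha * xi`, i.e. the Euler update is
applied to the full right-hand side including the noise, matching the
discrete scheme the model is defined by (not the `sqrt(dt)`
Euler–Maruyama convention — the noise magnitudes are calibrated for this
scheme). The noise-free reaction terms are quasi-positive (`f >= 0` at
`A = 0`, etc.), which guarantees a nonnegative continuum solution, but a
noise increment can overshoot zero. Where it does, the value is clamped to
zero and the overshoot is transferred to the conserved partner (`A` to `I`
or vice versa), leaving `A + I` unchanged per pixel; `F`, which has no
conservation partner, is simply clamped.

One numerical subtlety deserves mention: at the minimal noise level
(`alpha = 1e-15`) a single increment `alpha * xi * dt` is around 1e-18 —
below one ulp of a concentration of order one, so naive addition would
round it away entirely and the homogeneous state could stay *exactly*
uniform forever, never seeding the instability it is unstable to. The core
therefore accumulates the noise increments with Kahan compensation
(per-pixel residual buffers), letting sub-ulp noise build up until it
commits; the residuals are part of the integrator state, so resumed runs
remain bit-identical to uninterrupted ones.

The update loop is compiled (Rcpp). It draws its noise from a dedicated
xoshiro256++ generator with a ziggurat normal sampler seeded by the `seed`
argument, which makes whole trajectories bit-reproducible independent of R's
global RNG state; `extend_simulation()` carries the generator state across
calls, so a run continued in pieces is bit-identical to one long run. Model
units convert to physical units only in reports, via `scaling_factors()`
(0.83 s/au for the starfish calibration, 1.56 s/au for frog, 15.93 µm per
au of distance; one pixel is 0.3186 µm).

### Initial conditions and masks

Three standard initializations (`make_initial_state()`), all with mean
`A + I = 1` over the mask: homogeneous (`A = 0, I = 1`; patterns then
nucleate from noise), a central 10×10 activation spike with `I` lowered
uniformly to keep total mass, and per-pixel random perturbations
`A = eps|xi|, I = 1 - A` (used for the scheme-refinement check).
`make_mask()` builds square, disk or image-derived masks, always with a
one-pixel background ring.

## Stage analysis

From a homogeneous start, the pattern amplitude `max(A) - min(A)` grows
exponentially over orders of magnitude (*low-activity stage*) before
saturating (*high-activity stage*). `detect_stages()` thresholds the slope
of the log-amplitude at 1e-3 per au. Because both the pre-growth noise
floor and the saturated plateau produce short spurious crossings of so small
a threshold, the slope series (central differences) is smoothed with a
5-frame moving average and the growth stage is taken as the *longest*
sustained above-threshold run; its end time is the stage duration `T_g`.
On clean piecewise-exponential traces this reduces exactly to the kink
location.

The low-activity pattern is either *quasi-static* (a fixed spatial pattern
whose amplitude grows) or *oscillatory* (activator and inhibitor peaks swap
periodically). `classify_regime()` separates them with the temporal Pearson
autocorrelation of `A` evaluated at `t = 0.5 T_g` over lags up to
`0.4 T_g` (so the window ends before the high-activity stage): the regime
is oscillatory when the swing (max − min) of the autocorrelation exceeds 1.
With the reference parameters on a 100×100 grid, `s2 = 0.8` yields a swing
of a few hundredths (quasi-static) and `s2 = 1.1` a swing near 2
(oscillatory). `oscillation_period()` reports the mean spacing of
autocorrelation peaks, using a 0.05 minimum prominence so numerical ripple
is not counted as a peak.

## Wave vectors and wave domains

```{r}
library(cortexwaves)
sim <- run_simulation(model_params(k0 = 0.2, s2 = 0.8),
                      grid_spec(make_mask("square", 102)),
                      duration = 900, seed = 11)
stg <- detect_stages(pattern_amplitude(sim))
wd <- detect_wave_domains(sim$A[, , sim$times >= stg$T_g],
                          mask = sim$grid$mask,
                          wf_params = wave_params(tau_c = 8, T_av = 60),
                          label_every = 15)
```

`wave_vector_field()` estimates the local propagation direction by comparing
each pixel at time `t` with the pixels of a `w_c`-sized window at time
`t + tau_c`: offsets to similar pixels (similar in intensity *and* in Sobel
gradient magnitude) dominate a weighted vector sum, whose angle is the wave
direction. The weight is `(1 + |dA| + |d grad A|)^-n` with `n = 5`; larger
`n` sharpens the weighting but the final segmentation is insensitive over
`n` in 3–7 (a property the tests enforce). The raw offsets are summed
unnormalized; pixels outside the mask are excluded, and pixels whose vector
sum is numerically zero (below `1e-12 * w_c^2`, e.g. deep inside a uniform
region) are flagged invalid rather than given an arbitrary angle.
Directions are then averaged over a running window of `T_av` frames with
the circular mean, restricted — when the cell edge moves — to the
intersection of the window's masks. Angles use image coordinates (x along
columns, y along rows pointing down) and live in `[0, 2*pi)`.

`coherence_distance_map()` assigns each pixel the largest disk radius
within which the circular standard deviation `sqrt(-2 log Rbar)` of the
averaged directions stays below `C_cr = 0.4`. Radii are searched as
integers from 1 outward with running vector sums and early exit, so the
reported distance is the last radius actually verified; the search is
capped at `r_max = 40` px (the statistic saturates long before that on
100-px grids) and the standard deviation itself is capped at 10 where the
resultant length collapses to rounding noise. The compiled implementation
is tested for exact equality against a brute-force per-pixel, per-radius
scan.

The coherence map is segmented by `watershed_flat_merge()`, a watershed of
the negated map in which plateau pixels never seed catchment basins of
their own: levels are flooded in decreasing order, each level's pixels that
touch an existing basin are absorbed into it breadth-first (ties resolved
deterministically toward the smaller label), and only the left-over plateau
components found new basins. This suppresses the over-segmentation a
textbook watershed produces on the large flat regions typical of coherence
maps, and an all-flat map yields a single region. Adjacent segments whose
circular-mean directions differ by less than `theta_m = 0.5` rad across an
interface longer than 10% of the square root of the smaller segment's area
are then merged (`merge_similar_domains()`), smallest angular difference
first, recomputing after every merge until a fixed point. An optional
minimum-area filter absorbs regions smaller than a threshold into their
longest-interface neighbor; when asked for (`min_area = "auto"`) the
threshold is the square of the pattern wavelength, estimated as the lag of
the first minimum of the spatial autocorrelation of `A` along the mean
propagation direction — wave domains are by definition larger than the
wavelength of the waves inside them. `domain_statistics()` reports
per-frame counts, pixel and µm² areas, and mean directions.

## Texture descriptors

For regime mapping and simulation-to-experiment comparison, frames are
z-scored over the analysis window and summarized by the Shannon entropy of
the 256-bin intensity histogram (in bits, after min–max scaling, hence
invariant to affine intensity changes) and by gray-level co-occurrence
features (contrast, correlation, energy, homogeneity) computed from an
8-level quantization at the single-pixel horizontal offset, unsymmetrized
by default — these are the conventions of the standard MATLAB-lineage
texture routines, and both are configurable. The excitation measure — the
fraction of the cell area where `A` exceeds its spatial mean — tracks the
ratio of activation front to refractory area. `preprocess_experimental()`
crops a 100×100 µm window, resamples it to 100×100 px (bilinear, via
EBImage) and z-scores it, putting microscopy movies and simulations on a
common footing.

## Synthetic ground truth

The generators in this package exist so every analysis stage can be scored
against known truth without any external data. `plane_wave_movie()` emits a
traveling sinusoidal wave train with a prescribed direction;
`multidomain_movie()` tiles the frame with independent wave trains, one
direction per region, returning the planted label map and angles;
`spiral_movie()` produces a rotating Archimedean spiral — the classic
excitable-media pattern whose wave vectors point in *all* directions away
from the core, serving as a negative control that must not come out as one
coherent domain. All are deterministic given their seed, emit nominal
intensities in [0, 1] (plus optional additive Gaussian noise), and refuse
aliasing specifications (`speed >= wavelength/2`). A moving-edge mask
sequence (`moving_edge_masks()`) exercises the mask-intersection rule of
the circular averaging. What these fixtures deliberately do *not* emulate:
microscope point-spread functions, shot noise, photobleaching, or curved
wave fronts — passing on them validates the estimator and segmentation
logic, not robustness to every optical artifact of real recordings.

## Numerical choices and problem sizes

Default analysis settings: convolution window 5 px, frame lag 8 au
(simulation) or 1 frame (experiment), averaging window 300 au or 15 frames,
`C_cr = 0.4`, `theta_m = 0.5` rad, interface fraction 0.10. The package's
own test and acceptance runs use a 100×100 active grid (2×2 au of model
space) — large enough to hold several pattern wavelengths, so the
quasi-static/oscillatory boundary and the wave-domain phenomenology match
the larger reference geometry, while a full growth stage (`T_g` of a few
hundred au, seed- and regime-dependent) simulates in a few minutes.
The domain-count trend check averages directions over 60 frames rather than
300 so that several independent segmentation epochs fit into the
high-activity window analyzed.

Degenerate inputs are handled explicitly rather than silently: zero-variance
frames make the Pearson autocorrelation undefined (returned as `NA` with a
warning), constant frames have zero entropy and undefined co-occurrence
correlation, empty angle sets are an error for the circular statistics, and
`zscore_frames()` refuses a flat window.

## Limitations

The model omits actin mesh transport (`F` does not diffuse), bulk–surface
exchange in 3-D geometry, and any cell-cycle coupling; it reproduces the
growth and competition of wave domains but not the abrupt reversal observed
late in oocyte recordings, which is thought to be driven by processes
outside this signaling motif. The wave-vector estimator assumes
frame-to-frame displacements within the convolution window; waves faster
than `(w_c - 1)/2` pixels per lag alias. Domain identity is not tracked
across frames — counts and areas are per-frame statistics, not lineages.
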