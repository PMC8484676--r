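# cortexwaves

Cortical Rho GTPase activity in starfish oocytes and frog embryos organizes
into traveling waves, and — under the right balance of activation and
inhibition — into **wave domains**: coexisting regions of the cell cortex in
which waves propagate coherently in one direction, differing from region to
region. `cortexwaves` is an R package for scientists studying this kind of
spatiotemporal pattern. It provides:

- a stochastic 2-D **mass-conserved activator–substrate (wave-pinning)
  model** of GTPase cycling with F-actin negative feedback, solved on
  arbitrary masked cell shapes;
- the **analysis toolkit** to quantify the resulting dynamics in simulated
  or experimental movies: growth-stage detection, quasi-static vs
  oscillatory regime classification, per-pixel wave-vector fields,
  automated wave-domain segmentation, and texture descriptors;
- **synthetic movie generators** with planted ground truth for validating
  every analysis step.

## The model

Active membrane-bound GTPase `A`, inactive cytosolic form `I` and F-actin
`F` evolve as

```
dA/dt =  f(A,I,F) + D_A ∇²A + α₁ξ₁        f(A,I,F) = (k₀ + γ A³/(A₀³+A³)) I
dI/dt = -f(A,I,F) + D_I ∇²I − α₁ξ₁                  − (s₁ + s₂ F/(F₀+F)) A
dF/dt =  k_n A − k_s F + α₂ξ₂
```

with `D_I ≫ D_A` (cytosol vs membrane), autocatalytic activation saturating
at `A₀`, F-actin feedback saturating at `F₀`, and per-pixel Gaussian noise
entering `A` and `I` with opposite signs so that the total GTPase mass is
conserved exactly. Integration is forward-Euler with a mask-weighted
five-point Laplacian (zero flux across the cell outline), noise-overshoot
repair that preserves both nonnegativity and the `A+I` mass, and a
per-snapshot audit of mass and positivity. Depending on the basal
activation `k₀` and feedback strength `s₂` the model produces spiral waves,
wave domains, or noise-dominated flicker.

## Worked example

Simulate the oscillatory low-activity regime on a 100×100 cell, detect the
growth stage, and classify the regime from the temporal autocorrelation:

```r
library(cortexwaves)

grid <- grid_spec(make_mask("square", 102))        # 100x100 active pixels
params <- model_params(k0 = 0.2, s2 = 1.1)         # oscillatory regime
sim <- run_simulation(params, grid, duration = 500, seed = 11)

stg <- detect_stages(pattern_amplitude(sim))
stg
#> Low-activity stage: T_g = 221 au (183.4 s); 222 low / 279 high frames

classify_regime(sim, stg$T_g)
#> Low-activity regime: oscillatory (autocorrelation swing 1.966)
```

The amplitude of the activator pattern grows exponentially until `t ≈ 220`
au (the low-activity stage) and then saturates. At the reference
quasi-static parameters (`s2 = 0.8`) the same analysis yields a swing of
a few hundredths — the autocorrelation stays pinned near 1 because the
pattern barely moves — whereas here the activator and inhibitor peaks swap
periodically, driving the autocorrelation between roughly +1 and −1
(swing ≈ 2).

Segmenting the high-activity stage into wave domains:

```r
wd <- detect_wave_domains(sim$A[, , sim$times >= stg$T_g],
                          mask = grid$mask,
                          wf_params = wave_params(tau_c = 8, T_av = 60),
                          label_every = 15)
attr(wd$stats, "counts")    # domains per analyzed frame, decreasing as
                            # domains grow and compete
```

Synthetic validation data with known truth:

```r
mv <- multidomain_movie(size = 60, n_frames = 14, wavelength = 12,
                        speed = 2, directions = c(0, 2*pi/3, 4*pi/3),
                        noise_sigma = 0.1, seed = 1)
wd <- detect_wave_domains(mv$movie,
                          wf_params = wave_params(tau_c = 1, T_av = 10),
                          dom_params = domain_params(min_area = 144))
tail(attr(wd$stats, "counts"), 1)
#> [1] 3           # the three planted direction regions are recovered
```

A command-line front end over the same functions ships in
`inst/cli/cortexwaves-cli.R` (`simulate`, `synth`, `analyze-stages`,
`analyze-domains`, `analyze-texture`).

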