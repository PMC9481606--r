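# aquaopes

Enhanced sampling, unbinding kinetics and trapped-water analysis at desk
scale.

Ligand-protein unbinding happens on millisecond timescales that plain
molecular dynamics cannot reach, and the water network inside a binding
pocket is often what gates the release.  The modern toolchain for this
problem combines four ingredients: **on-the-fly probability enhanced
sampling** (OPES) to converge binding free energies, an **OPES-flooding**
variant that leaves the transition state unbiased so physical residence
times can be recovered by hyperdynamics time rescaling, **machine-learned
collective variables** (Deep-LDA, Deep-TICA) built from water-coordination
descriptors, and a **geometric pipeline** that locates the long-lived
"reservoir" waters whose coordination numbers feed those descriptors.

`aquaopes` implements this entire stack in R (with an Rcpp propagation
core) so that every stage can be exercised, understood and validated on
analytic toy systems and seeded synthetic data — no microsecond MD
required.  It is aimed at method developers and students of enhanced
sampling: the algorithms are the real ones, the systems are deliberately
small.

## The methods in brief

OPES estimates the CV density on the fly from weighted Gaussian kernels,

```
P_n(s) = sum_k w_k G(s, s_k) / sum_k w_k,     w_k = exp(beta V_{k-1}(s_k))
```

and biases with the well-tempered form
`V_n(s) = (1 - 1/gamma) (1/beta) log(P_n(s)/Z_n + epsilon)`, where
`epsilon = exp(-beta dE/(1 - 1/gamma))` caps the deposited bias at `dE`.
For kinetics, the cap is set below the barrier and an excluded region
blocks deposition near the transition state; the physical time is then
`t = <exp(beta V)>_V * t_MD`, and residence-time samples are fitted to
`(1/tau) exp(-t/tau)` with a bootstrap-calibrated KS test.  Hydration
spots come from a convex hull over anchor atoms, a 100 ps residence
filter, and k-means with a 2–3 Å spacing rule; binding free energies use
the funnel correction
`dF = (1/beta) log(C0 pi R_cyl^2 int_B exp(-beta (W(z) - W_U)) dz)` with
`C0 = 1/1660 A^-3`, and `dF(T) = dU - T dS` across temperatures splits
enthalpy from entropy.  The methods vignette
(`vignettes/methods.Rmd`) derives all conventions and defaults.

## Worked example

Free-energy recovery on the 5 kT double well, then unbinding rates on the
7 kT well:

```r
library(aquaopes)

pot  <- make_potential("double_well_1d", c(h = 5))
spec <- langevin_spec(pot, n_steps = 2e6, seed = 42, friction = 100)
res  <- run_opes(spec, opes_config(barrier = 6, gamma = 10))
fes  <- reweighted_fes(res$series, discard = 0.2)
fes[findInterval(c(-1, 0, 1), fes$s), ]
#>         s free_energy error
#> 19 -1.013       0.289 0.727
#> 50 -0.013       4.595 0.309
#> 81  0.987       0.029 0.058
```

The reweighted profile reproduces the analytic double well: ~0 kT at the
two minima (±1), ~5 kT at the barrier (the residual is block-average
noise, largest in the rarely-visited left well at this short length).

```r
pot7 <- make_potential("double_well_1d", c(h = 7))
stp  <- cv_stop(above = 0.8, dwell = 10)           # committed escape
smp  <- residence_time_sample(
  langevin_spec(pot7, n_steps = 2e6, seed = 1),
  opes_config(barrier = 5, gamma = 10, deposit_period = 100,
              excluded_region = cv_region(min = -0.5)),
  stp, n_runs = 50, seed = 11)
fit_exponential(smp$times, seed = 2)
#> <rate_fit> exponential residence-time model
#>   tau = 295.8, k_off = 0.003381, p-value = 0.0649 (bootstrap)
#>   mu = 295.8, sigma = 230.9, n = 50 events
```

Fifty flooding runs (each a few thousand steps) give a mean physical
escape time of ~296 time units against ~148 from fifty unbiased
brute-force events that each need ~150,000 steps — rate recovery within
a factor of two at a fraction of the cost, with the exponentiality of
the sample retained (p > 0.05).  `split_and_fit()` resolves two-mechanism
samples into separate `tau` estimates, mirroring how fast and slow
unbinding paths are analysed.

The hydration-spot pipeline on a synthetic scene:

```r
ws  <- synth_water_scene(water_scene_spec(seed = 3))
res <- track_residences(ws$frames, ws$hull, frame_interval = 10,
                        lifetime_threshold = 100)
cluster_spots(res$pooled, k = "auto", seed = 4)
#> <hydration_spots> k = 5, min pair distance = 4.962 A,
#>   max nearest-neighbour = 5.521 A
```

All five planted reservoir positions are recovered (centre RMSE ~0.1 Å);
no transient bulk water survives the 100 ps filter.

## Command line

A thin CLI wraps the same functions:

```sh
aqua-opes synth --what scene --seed 3 --out scene/
aqua-opes spots --traj scene/scene.xyz --top scene/anchors.pdb \
          --lifetime 100 --interval 10 --k auto --seed 2 --out spots
aqua-opes rates --times times.txt --out rates.tsv
```

Exit codes: 0 success, 1 runtime failure, 2 usage error.  Any flag can
come from a YAML config (`--config file`, flags override).

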