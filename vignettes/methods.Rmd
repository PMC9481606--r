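---
title: "Methods: enhanced sampling, unbinding kinetics and trapped-water analysis"
author: "aquaopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enhanced sampling, unbinding kinetics and trapped-water analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquaopes)
```

`aquaopes` packages, at desk scale, the computational machinery used in
modern studies of ligand-protein unbinding: on-the-fly probability
enhanced sampling (OPES) for free energies, its flooding variant for
physical residence times, machine-learned collective variables, a
geometric pipeline for locating long-lived ("reservoir") water molecules,
and funnel-corrected binding thermodynamics.  Everything runs on analytic
toy systems and seeded synthetic data, so each stage can be validated
against an independent oracle without microsecond all-atom MD.  This
vignette describes the models, the tunable parameters, the numerical
choices, and what the toy-scale validations do and do not demonstrate.

## The OPES bias

A collective variable (CV) $s(R)$ is a scalar function of configuration
describing a slow mode.  OPES estimates the CV probability density on the
fly from weighted Gaussian kernels deposited along the trajectory,

$$P_n(s) = \frac{\sum_k^n w_k\, G(s, s_k)}{\sum_k^n w_k},
  \qquad w_k = e^{\beta V_{k-1}(s_k)},$$

and converts it into the well-tempered bias

$$V_n(s) = \left(1 - \tfrac{1}{\gamma}\right)\frac{1}{\beta}
  \log\!\left(\frac{P_n(s)}{Z_n} + \epsilon\right),$$

which steers sampling toward the broadened target
$P^{tg}(s) \propto P(s)^{1/\gamma}$.  Before any deposit $V_0 \equiv 0$
(the weight definition forces $w_1 = 1$).  Key parameters:

* **`gamma`** (bias factor, default 10): $\gamma = 1$ makes the prefactor
  vanish, recovering unbiased dynamics exactly; $\gamma \to \infty$
  targets a flat distribution.
* **`barrier`** ($\Delta E$, energy): sets
  $\epsilon = e^{-\beta \Delta E / (1 - 1/\gamma)}$, which caps the
  deposited bias at $\Delta E$; the bias in never-visited regions is the
  *floor* $(1-1/\gamma)\beta^{-1}\log\epsilon = -\Delta E$.
* **`sigma`** (kernel bandwidth): when not given it is estimated from a
  short unbiased segment.  We use the median absolute deviation of lagged
  CV differences (divided by $\sqrt 2$) rather than a standard deviation:
  the quantity of interest is the fluctuation width of the *starting
  basin*, and a rare barrier crossing inside the estimation segment would
  inflate a standard deviation to the inter-basin distance while leaving
  the MAD of short-time differences untouched.
* **`deposit_period`** (default 500 integrator steps) and `Z_n`, computed
  as the mean of $P_n$ over the deposited centres - the standard
  reference convention for "configuration space explored so far".  No
  kernel merging or adaptive bandwidths are used; at desk scale the plain
  kernel table is affordable and simpler to reason about.

Between deposits the bias is constant in time, so the propagation engine
evaluates it through a lattice (501 nodes per CV by default, multilinear
interpolation with finite-difference nodal gradients) that is refreshed
at each deposit; the exported `evaluate_bias()` always performs the exact
kernel sum, and the lattice is only an internal device of the integrator.
Its resolution is a tunable of `opes_config()`.

Free-energy surfaces are recovered by reweighting: frames carry weights
$\propto e^{\beta V}$, are histogrammed (or kernel-smoothed), and
$F = -\beta^{-1}\log P$ is min-zeroed.  Errors are standard errors over
`n_blocks` contiguous blocks.  The first 20% of frames are discarded as
the default equilibration in the package's own studies, since early
frames are generated while the bias is still filling the well.

## Dynamics and toy systems

The integrator is overdamped Euler-Maruyama,
$x_{t+1} = x_t - \nabla(U + V)\,\Delta t/\gamma_f + \sqrt{2 k_B T \Delta t/\gamma_f}\,\eta$,
in reduced units ($k_BT = 1$, friction $\gamma_f = 1$, $\Delta t = 10^{-3}$
by default), with a bitwise-reproducible private RNG (mt19937-64 +
Box-Muller) so identical spec + seed gives identical trajectories.  Full
molecular dynamics is deliberately out of scope: overdamped dynamics is
sufficient to exercise bias construction, time rescaling and rate
statistics.

Shipped potentials: `double_well_1d` ($U = h(x^2-1)^2$; barrier $h$,
minima at $\pm 1$), `double_well_2d` (adds a harmonic transverse mode),
and `binding_funnel_2d`, where escape along an exit coordinate $z$ is
gated by a solvation-like coordinate $w$: the exit barrier
$H(1 + c(w-1)^2)$ is cheapest when $w$ pays a harmonic price to open.
All parameters of these potentials are package choices with no
experimental meaning; their closed forms are the oracles of the test
suite (a Dijkstra grid-minimax saddle search cross-checks the funnel
barrier).

For the FES-recovery study we run the $h = 5\,k_BT$ double well with
friction 100 for $10^7$ steps ($\gamma = 10$, cap $6\,k_BT$).  The
friction is chosen from the Kramers estimate so that the unbiased control
run shows essentially no interwell transitions on the same budget while
the biased run shows dozens; with friction 1 the unbiased crossing time
would be only ~$3\times 10^4$ steps and the contrast would vanish.

## OPES flooding and residence times

To compute rates the bias must vanish where the transition happens.  Two
controls achieve this: the cap $\Delta E$ is set *below* the barrier, and
an **excluded region** covering the transition state refuses kernel
deposits.  The physical residence time then follows the hyperdynamics
relation

$$t = \langle e^{\beta V(s)}\rangle_V\, t_{\mathrm{MD}},$$

with the average accumulated along the trajectory at the output stride.
Two operational choices deserve explanation:

* **Gauge.**  The Eq.-form bias above is $\approx 0$ at well-sampled
  points and equals the negative floor $-\Delta E$ in unexplored regions
  - including the excluded transition region.  A bias is defined up to a
  constant; the hyperdynamics relation presumes the gauge in which the
  bias vanishes *at the transition state*.  The boost is therefore
  accumulated as $e^{\beta(V - V_{\text{floor}})}$, with floor 0 before
  the first deposit.  With the bias disabled the acceleration is exactly
  1 and $t = t_{\mathrm{MD}}$; a constant bias $V_0$ gives exactly
  $e^{\beta V_0}$.
* **Exclusion margin.**  Kernels deposited right at the exclusion
  boundary leak bias across it: the logarithm turns a Gaussian tail into
  a slowly decaying bias shoulder that reaches $\approx 0$ only ~4-5
  bandwidths past the last kernel.  The excluded region must therefore
  begin a few bandwidths *before* the barrier top.  The package's
  double-well studies use `cv_region(min = -0.5)` for the saddle at 0
  (about $5\sigma$).  With the boundary at the saddle itself, the
  transition state acquires several $k_BT$ of bias and the boost is
  overcounted by an order of magnitude - this failure mode is easy to
  reproduce and is why the margin rule is part of the method.

On the $h = 7\,k_BT$ well (cap $5\,k_BT$), 500 flooding runs recover the
mean escape time of unbiased brute force within a factor of about 1.9 and
pass the exponentiality test in every replicate batch.  The residual
overestimate is systematic and grows with the cap (~1.2x at cap 3, ~1.8x
at cap 5 against a 200-event brute-force reference); it reflects the
approximations of time rescaling under a nearly-full well, not sampling
noise.  A cap-independence check (two caps, same protocol) is part of the
test suite.

Escape is committed by a dwell criterion: the stop predicate must hold
for 10 consecutive output frames (one frame for the brute-force oracle's
finer stride), so transient recrossings do not count as events.

Residence-time samples are fitted to the homogeneous model
$p(t) = \tau^{-1} e^{-t/\tau}$ by maximum likelihood ($\hat\tau$ is the
sample mean; censored runs add survival mass:
$\hat\tau = (\sum t_i + \sum c_j)/n_{\text{events}}$).  Because
$\hat\tau$ is estimated from the same sample, the Kolmogorov-Smirnov
p-value is calibrated by a parametric bootstrap (1000 resamples by
default; the plain asymptotic KS, which is anti-conservative here, is
available for comparison).  The summary table carries
$\tau$, $k_{\mathrm{off}} = 1/\tau$, the p-value, $\mu$, $\sigma$ and the
event count; `split_and_fit()` fits two user-labelled mechanism
populations separately and reports the $\tau$ ratio.  Mechanism
*classification* is intentionally user input - the package does not
decide which events were fast or slow.

## Machine-learned collective variables

**LDA / Deep-LDA.**  For two labelled states B and U with descriptor
means $\mu_B, \mu_U$ and within-state covariance sum
$S_w = S_B + S_U$, Fisher's ratio
$w^\top S_b w / w^\top S_w w$ with $S_b = (\mu_B-\mu_U)(\mu_B-\mu_U)^\top$
is maximised by $w \propto (S_w + \lambda I)^{-1}(\mu_B - \mu_U)$.
Deep-LDA feeds the descriptors through a small MLP and applies this
criterion to the last hidden layer $h$; the CV is $s = w^\top h$ with the
cubic transform $s_w = s + s^3$ applied by default to widen the sharp
distributions this construction tends to produce.  The trainers are
written in plain matrix algebra (no NN library): the gradient of the
closed-form Fisher objective with respect to each hidden activation is
derived analytically
($\partial J/\partial h_i = \pm\tfrac{2}{n_s}A^{-1}\delta
+ \tfrac{2}{n_s-1}M(h_i - \mu_s)$ with $A = S_w + \lambda I$,
$M = -A^{-1}\delta\delta^\top A^{-1}$ - the centring terms cancel) and
backpropagated; optimisation is full-batch Adam with a 20% validation
split and patience-20 early stopping.  Defaults: hidden widths
[32, 16, 8] with tanh, $\lambda = 0.05\,\mathrm{tr}(S_w)/N_h$.  With
linear activations and $N_h \ge N_d$ the construction provably collapses
onto closed-form LDA, which the tests assert at cosine $\ge 0.99$.

**TICA / Deep-TICA.**  The slowest decorrelating modes solve the
generalized eigenproblem $C(\tau)v = \lambda C(0)v$.  Covariances are
mean-free and symmetrised over the pair $(t, t+\tau)$ (the reversible
estimator, which keeps $\lambda \le 1$ up to numerical tolerance), and
frames from biased runs are reweighted by $e^{\beta V}$ as an
approximation to rescaled time; plain-time weighting is the zero-bias
special case.  Implied timescales are $-\tau/\log\lambda_i$.  Deep-TICA
trains an MLP whose `n_out` outputs form a basis maximising
$\sum_i \lambda_i^2$; the gradient treats the weighted means as constants
(a stop-gradient, standard for this objective since the centring
correction is an edge effect) and the returned CV is the leading
eigenfunction.  The lag time is expressed in the series' own time unit -
the package takes no position on the absolute unit.

## Trapped-water hydration spots

The four-step method for locating long-lived water molecules:

1. select anchor atoms (alpha-carbons) enclosing the region of interest;
2. build their **convex hull** - implemented by exhaustive enumeration of
   supporting planes (every point triple whose plane has all remaining
   points on one side), exact and fast for the tens of anchors the method
   uses; containment is a closed half-space test (boundary counts as
   inside) and the volume comes from the facet polygons;
3. track per-water **residences**: contiguous intervals of frames inside
   the hull; intervals longer than the lifetime threshold (default
   100 ps, exclusive) are retained, and a single-frame exit splits an
   interval in two;
4. **cluster** the pooled retained positions with k-means (10 restarts,
   fixed seed).  With `k = "auto"` the count is swept upward from 1 and
   the largest k is kept whose minimum inter-centre distance stays at or
   above the lower edge of the 2-3 Angstrom spacing band; both the
   minimum pairwise and the maximum nearest-neighbour spacing are
   reported, since "relative distance" can reasonably mean either.

Around the spot centres (and a ligand / binding-site anchor pair) the
package evaluates smooth coordination numbers
$\sum_j (1-(r_j/r_0)^n)/(1-(r_j/r_0)^m)$ with the removable singularity
at $r_j = r_0$ taking its limit $n/m$.  The switching form and its
parameters $(n, m, r_0) = (6, 12, 3.5\,\text{\AA})$ are the standard
rational switching of enhanced-sampling engines; they are configurable
because no single choice is canonical.  A frame's descriptor vector
$(G, H, V_1 \ldots V_k)$ has length $2 + k$ - 18 in a 16-spot
configuration.

The synthetic water scenes plant occupants that jitter
($\sigma = 0.5\,$Å) around interior spots for a stated lifetime and then
swap identity with a bulk water (teleport exchange - only the residence
bookkeeping matters downstream, not diffusion pathways), plus bulk
waters random-walking outside the hull with scripted incursions kept
strictly below the filter threshold.  The default scene (5 spots $\ge$
4 Å apart, 500 ps lifetimes, 50 frames at 10 ps) is constructed so the
planted truth is recoverable exactly: 5 waters pass the 100 ps filter,
none passes a 600 ps filter, and no bulk water ever qualifies.  What
these scenes do *not* emulate: periodic boundaries, realistic water
exchange kinetics, hull deformation over time, or correlated
protein-water motion - so passing them shows the bookkeeping and
clustering are correct, not that the method's thresholds are optimal for
real trajectories.

## Funnel-corrected binding thermodynamics

A funnel restraint (cone of slope `cone_slope` meeting a cylinder of
radius $R_{\mathrm{cyl}}$ at `z_switch`) confines the unbound ligand;
the wall is half-harmonic, zero inside, continuous and once
differentiable across the surface (the cone/cylinder junction line is
only $C^0$, a measure-zero set excluded from gradient tests).  The
standard-state binding free energy follows from the axial profile
$W(z)$:

$$\Delta F = \frac{1}{\beta}\log\!\left(C^0 \pi R_{\mathrm{cyl}}^2
  \int_B dz\, e^{-\beta (W(z) - W_U)}\right),
  \qquad C^0 = \tfrac{1}{1660}\,\text{\AA}^{-3},$$

integrated by the trapezoid rule (second-order convergent, verified).
$W_U$ is the *mean* of $W$ over the unbound plateau interval rather than
a single grid value, for noise robustness.  **Sign convention:** the
package reports the unbinding work, positive for a stable binder - the
scale on which such numbers are usually quoted.  Under this convention
$\Delta F$ is invariant under constant shifts of $W$ (the $W_U$
subtraction cancels them) and monotone *increasing* in
$R_{\mathrm{cyl}}$ at fixed $W$: a wider cylinder means more unbound
volume to integrate the standard concentration against, hence more work
to reach it.

The enthalpy/entropy split fits
$\Delta F(T) = \Delta U - T\Delta S$ across temperatures by generalized
least squares with the user-supplied per-point uncertainties taken as
known (the parameter covariance is $(X^\top W X)^{-1}$ without residual
rescaling, which is what makes the reported 1-sigma intervals calibrated
- the test suite checks ~68% coverage over 500 noisy repeats).  The
temperature grid is user input.

## Problem sizes, determinism, limitations

The package's own validation studies (test suite and
`scripts/acceptance.R`) use: $10^7$ steps for FES recovery; 10 batches of
50 flooding runs against 50 brute-force events for rate recovery; 100
Monte-Carlo repeats of $n = 200$ exponential fits; $10^6$ frames for the
TICA timescale; $2\times 10^4$ frames for Deep-TICA; 500 repeats for the
coverage calibration.  These sizes make every check decisive at its
stated tolerance while the whole suite stays fast on one CPU.

All randomness flows from one master seed through `derive_seed()`; the
C++ integrator uses its own mt19937-64 + Box-Muller stream, so results
are reproducible bit for bit across runs on one thread, independent of
R's global RNG state.

Known limitations: single-walker only (the kernel-table serialisation is
versioned so shared-bias walkers can merge tables later); CV dimension
at most 2 in the propagation engine; no periodic-boundary chemistry; the
flooding estimate carries the cap-dependent systematic documented above;
and the hydration-spot auto-k rule guarantees the lower spacing bound
only - the upper bound is reported, not enforced, because both cannot be
guaranteed simultaneously for arbitrary data.
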