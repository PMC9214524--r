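---
title: "Modelling chemorepulsive autochemotaxis with cappsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling chemorepulsive autochemotaxis with cappsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(cappsim)
```

## The system and the model

Self-propelled oil droplets in a surfactant solution consume fuel as they
swim and shed a long-lived trail of oil-filled micelles in their wake.  The
trail acts as a *chemorepellent* for other droplets (and, later, for the
droplet itself): an approaching swimmer is both turned away from and pushed
down the concentration gradient.  At the collective level these delayed,
trail-mediated "collisions" can transiently arrest the whole emulsion —
*chemotactic self-caging* — at area fractions far below anything that could
jam sterically.

`cappsim` implements the chemically active polar particle (CAPP) description
of this system.  A droplet is a point at position $\mathbf r$ with a unit
orientation $\mathbf n$ obeying the Langevin equations

$$\dot{\mathbf r} = V_0 \mathbf n - \alpha \nabla c + \sqrt{2D_t}\,\xi_t,
\qquad
\dot{\mathbf n} = \Omega\, \mathbf n \times (\mathbf n \times \nabla c)
 + \sqrt{2D_r}\,\mathbf n \times \xi_r .$$

The torque coupling $\Omega > 0$ rotates $\mathbf n$ away from the gradient
(using $\mathbf n \times (\mathbf n \times \nabla c) =
(\mathbf n\!\cdot\!\nabla c)\,\mathbf n - \nabla c$, which is how the
integrator evaluates it in any dimension); the force coupling $\alpha > 0$
adds a direct drift down-gradient, which is what makes the swimming speed dip
before the turning point of a reflection.  In 2D the deterministic turn rate
reduces to $\dot\theta = -\Omega\,(\nabla c \cdot \mathbf n_\perp)$.

## The trail field

The concentration field is built from Gaussian diffusion kernels.  Each
element $\mathrm ds$ of a trail emitted at time $t'$ contributes, at query
time $t$,

$$\frac{q\,\mathrm ds}{4\pi D\,(t - t' + t_\mathrm{off})}
  \exp\!\left(-\frac{|\mathbf r-\mathbf r'|^2}
  {4D\,(t - t' + t_\mathrm{off})}\right),$$

and the fields of all trails simply superimpose (the couplings are linear in
$\nabla c$).  Two conventions matter:

* **Deposition scale.** `q` is the emission per unit trail length (default
  1), so the concentration carries units of inverse length and the couplings
  are used as the lumped products `omega_c0` ($\Omega c_0$, µm²/s) and
  `alpha_c0` ($\alpha c_0$, µm³/s).  This is the unique convention in which
  those lumped units are dimensionally consistent with a turn rate in rad/s
  and a drift in µm/s, and with the defaults
  (`omega_c0 = 7e3`, `alpha_c0 = 3e4` — the medians of the single-event
  fits) it yields maximum turn rates of ~0.1–0.4 rad/s during encounters,
  the experimentally observed scale.
* **Finite-source offset.** A 50 µm droplet is not a point source; every
  kernel age is shifted by `t_off = 20` s, so even a freshly laid trail has
  a cross-section standard deviation of $\sqrt{2 D t_\mathrm{off}} \approx
  46$ µm.  The offset is configurable in `field_params()` and enters *all*
  kernels (single-event profiles, the fluorescence model and the collective
  field).

For a single delayed collision the 2D field reduces to the 1D cross-section
`trail_cross_section()`: a Gaussian of variance $2D(\Delta t + t_\mathrm{off})$
frozen for the duration of the encounter (`trail_mode = "static"`; an
`"aging"` mode, in which the variance keeps growing in real time, is provided
as a sensitivity check — at the lags of interest it moves the separatrix by
little).  A unit test verifies that the resampled 2D kernel quadrature of a
long straight trail reproduces this closed form to ~1%.

## Numerical choices

* **Integrator.** Euler–Maruyama with the orientation updated on the angle
  (2D) or renormalised after an infinitesimal rotation (3D); `|n| = 1` is
  conserved to 1e-9 by construction.  Default `dt = 0.02` s, i.e.
  $V_0\,\mathrm dt = 0.5$ µm, far below the ≥ 46 µm kernel width; halving
  `dt` moves a reflection turning point by well under 0.5 µm.  The collective
  driver and the single-event integrator are C++ hot loops; an R-level
  `capp_step()`/`capp_simulate()` with arbitrary field closures is the
  reference implementation, and a test pins the two paths to each other.
* **Trail discretisation.** Trails are resampled to at most
  `ds_max = 25 µm` (half a droplet diameter) and summed by the midpoint
  rule; in collective runs droplets deposit every 0.5 s (12.5 µm at
  $V_0 = 25$ µm/s).
* **Cutoffs.** Segments older than `T_mem = 600` s or farther than
  `R_max = 5\sqrt{4 D T_\mathrm{mem}}` are skipped; truncated contributions
  are below 1e-6 of a fresh peak.
* **Degenerate inputs.** An empty trail set gives a zero field, not an
  error; a droplet that stalls inside a trail (speed < 5% of $V_0$ for
  > 60 s) is flagged `"trapped-in-trail"`; a trajectory that never exits the
  interaction band is `"unresolved"`; a turning point within 1e-3 µm of the
  trail centre is classified as a reflection (the separatrix convention).

## Single events, the separatrix, and coupling fits

`simulate_event()` launches a droplet at incidence angle $\theta_\mathrm{inc}$
toward a trail of lag $\Delta t$ and classifies the outcome by the side on
which it leaves the band $|d| \le d_\mathrm{max} = 220$ µm.  Integration
continues 10 s beyond band exit (`t_beyond`): the outgoing leg is what makes
the initial heading and the force coupling separately identifiable when
fitting (the kinematic series the event carries is still band-limited).
`separatrix()` bisects $\Delta t^*(\theta_\mathrm{inc})$ to 0.5 s between
1 and 600 s, reporting angles whose switch falls outside the bracket as
absent, and attaches the rotational-noise band
$\delta\theta = \sqrt{2 D_r T}$ with approach time
$T = d_\mathrm{max}/(V_0 \sin\theta_\mathrm{inc})$ — the square root is
required for dimensional consistency.

`fit_event()` recovers `(omega_c0, alpha_c0)` per event by a Nelder–Mead
simplex on $\log_{10}$ couplings plus the initial heading as a bounded
nuisance parameter, minimising the mean squared position residual at the
observed sample times with ≥ 5 log-spaced multistarts (the forward model is
non-smooth at the crossing–reflection boundary).  Position-only residuals
are the documented objective; the speed and turn-rate series serve as
posterior checks.  Two identifiability facts are worth knowing:

* the trajectory shape is overwhelmingly sensitive to `omega_c0`, which is
  recovered to ~1% under 1 µm tracking noise across two decades of ground
  truth;
* `alpha_c0` leaves only a small positional footprint (a speed dip of
  $\alpha |\nabla c| \lesssim 2$ µm/s over tens of seconds).  The *median*
  over a set of events at a common ground truth is recovered within 10% at
  1 µm noise, but per-event estimates scatter widely, and in regimes where
  the torque dominates (`omega_c0` large, `alpha_c0` small) the force
  coupling is genuinely below the noise floor — the fit flags events with a
  flat loss surface (`identifiable = FALSE`) rather than inventing a value.

## Collective simulations and caging analysis

`simulate_collective()` integrates $N$ trail-depositing droplets in a
periodic box with minimum-image field queries, each droplet interacting with
every trail including its own (self-interaction is what eventually pushes a
droplet out of its cage), excluding only its own segments younger than
`tau_self = 4` s to avoid artifacts of the discretised fresh wake.
Trajectories are returned unwrapped.  `ensemble_msd()` implements the
ensemble MSD from the common start time, with no averaging over time
origins because the chemical landscape ages.  `detect_caging()` resamples
the curve onto a log-spaced lag grid (25 points/decade), estimates the local
log–log slope over a 5-point window, and reports the first crossing below
exponent 0.5 (caging), the subsequent crossing above it (escape), and the
median MSD between them (plateau height); 0.5 separates a plateau
(exponent ≈ 0) from diffusive growth (≈ 1), and absence of either regime is
a result, not an error.

Study conditions follow the quasi-2D experiments: densities 0.025–8.6 mm⁻²,
$V_0 = 25$ µm/s, $D_t = 0$ (translational diffusion is negligible for a
50 µm droplet), $D_r$ either 0 or its measured upper bound 0.01 rad²/s, and
a 2 mm periodic box by default (the walled experimental cell is deliberately
not reproduced, isolating trail-mediated caging from wall rectification).
The acceptance analysis uses $n = 7.4$ mm⁻² in a 2.85 mm box ($N = 60$,
300 s at `dt = 0.02`); the test suite uses the same densities in 1.5–2 mm
boxes with `dt = 0.05` to keep runtimes in seconds.

With the median couplings the model reproduces the qualitative collective
phenomenology: uncoupled or dilute systems stay ballistic, dense coupled
systems develop a subdiffusive interval whose onset moves earlier and whose
displacement scale shrinks as density grows, and individual trajectories
alternate persistent runs with localized episodes.  Quantitatively, the
arrest is *weaker* than in the quasi-2D experiments: the MSD level of the
arrested regime comes out of order $10^6\,\mu\mathrm m^2$ rather than
$10^5\,\mu\mathrm m^2$.  The mechanism is visible in the simulations: with
the finite-source offset applied to every kernel, even fresh trail walls are
≥ 65 µm wide and soft, and in well-trafficked regions overlapping walls
flatten the gradient, so droplets tend to ride along trail corridors instead
of being trapped in closed pockets.  Sharper deposition kernels, confining
walls, or a developed pre-existing chemical landscape would all strengthen
caging, but none of these is constrained by the available observations, so
the package keeps the documented kernel and reports what it produces.

## Trail-fluorescence diffusivity

`fit_profile_series()` recovers the chemorepellent (filled-micelle)
diffusivity from time-resolved trail cross-section intensity profiles.  Each
slice is fitted with a Gaussian plus a constant background
(Levenberg–Marquardt on the residuals; moment-based starts), and the fitted
variances are regressed on time: $\sigma^2(t) = 2D(t + t_\mathrm{off})$, so
the slope gives $2\hat D$ and the intercept $\hat t_\mathrm{off}$.  The
variance regression is the primary estimator because it is exactly invariant
to uniform intensity rescaling and to shifts of the section line; a joint
nonlinear fit of all slices is available as a cross-check, and the
$\log(\mathrm{peak})$ vs $\log(t + \hat t_\mathrm{off})$ slope (expected
$-1/2$) is reported as a diagnostic.  Saturated samples above a configurable
intensity quantile can be masked, mirroring overexposed droplet regions in
real micrographs.

## What the synthetic data do and do not emulate

`gen_profiles()`, `gen_event_pair()` and `gen_collective()` generate every
input the pipeline consumes, each with a ground-truth record and bit-exact
reproducibility under a fixed seed.  They emulate: the Gaussian spreading of
trail profiles with multiplicative intensity noise, delayed-collision
trajectory pairs at a prescribed incidence angle and lag with additive
(σ = 1 µm, sub-pixel tracking scale) position noise applied to the saved
tables only, and multi-droplet trajectory sets at prescribed densities.
They do not emulate: trail widening and curvature in the leader's near wake,
droplet polydispersity, hydrodynamic near-field interactions, fuel
depletion over the experiment, or imaging artifacts beyond saturation.
Passing the round-trip tests therefore demonstrates internal consistency of
the estimators under the model's own assumptions, not robustness to every
feature of real microscopy data.

## Limitations

* The model is "dry": hydrodynamic and chemoadvective effects are absorbed
  into the two couplings, which is justified for lags beyond the ~2 s
  advective timescale but not for near-simultaneous collisions.
* The quasi-2D cell is treated as vertically mixed; diffusion is purely
  in-plane.
* 3D support (field kernel, orientation dynamics, collective driver) reuses
  the 2D-calibrated couplings and is exploratory; no quantitative 3D
  interaction model is attempted.
* The collective caging scale exceeds the experimental one by roughly an
  order of magnitude, as discussed above.
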