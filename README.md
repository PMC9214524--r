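# cappsim

Simulation and analysis of **chemorepulsive autochemotaxis** in active
emulsions: self-propelled microdroplets that shed a diffusing chemical trail
and are repelled by the trails of other droplets (and their own).  The
package is for researchers in active matter and microswimmer physics who
want to simulate this class of system, analyse droplet-tracking data for
trail-mediated interactions, or reproduce the collective "chemotactic
self-caging" phenomenology.

## The model

A droplet is a chemically active polar particle (CAPP): a point at position
**r** with unit orientation **n**, obeying

    dr/dt = V0 n − α ∇c + √(2 Dt) ξt
    dn/dt = Ω n × (n × ∇c) + √(2 Dr) n × ξr

where `c(r, t)` is the chemorepellent concentration, the torque coupling
Ω > 0 turns the swimmer away from the gradient, and the force coupling
α > 0 pushes it down-gradient.  The trail field is a superposition of 2D
Gaussian diffusion kernels laid along each droplet's past path, with every
kernel age shifted by a finite-source offset `t_off = 20 s` (a 50 µm droplet
is not a point source).  Couplings are used as lumped products with the
concentration scale: `omega_c0` (µm²/s) and `alpha_c0` (µm³/s), defaulting
to the median single-event fit values 7·10³ and 3·10⁴.

The package provides, as plain R functions returning classed S3 objects:

| Stage | Functions |
| --- | --- |
| Trail fields | `field_params()`, `trail_cross_section()`, `cross_section_gradient()`, `field_superposition()`, `intensity_profile()` |
| CAPP dynamics | `dynamics_params()`, `particle_state()`, `capp_step()`, `capp_simulate()` |
| Single events | `simulate_event()`, `classify_event()`, `separatrix()`, `detect_interactions()`, `interaction_diagram()` |
| Coupling fits | `fit_event()`, `median_couplings()` |
| Collective | `collective_config()`, `simulate_collective()`, `ensemble_msd()`, `detect_caging()`, `neighborhood_history()` |
| Trail fluorescence | `profile_series()`, `fit_profile_series()` |
| Synthetic data | `gen_profiles()`, `gen_event_pair()`, `gen_collective()`, `derived_timescales()` |
| I/O | `read_trajectories()`, `write_trajectories()`, `write_events()`, `write_msd()`, `read_profiles()`, ... |

## Worked example

Simulate one delayed collision — a droplet hitting, at 45° incidence, the
trail a leader laid 10 s earlier — and map the crossing/reflection boundary:

```r
library(cappsim)

ev <- simulate_event(theta_inc = pi/4, delta_t = 10)
ev
#> Droplet-trail interaction event
#>   theta_inc = 45.0 deg, delta_t = 10.0 s, outcome: reflection
#>   max |dtheta/dt| = 0.274 rad/s, 829 series samples

separatrix(c(30, 45, 60, 75) * pi/180)
#> Crossing-reflection separatrix:
#>  theta_deg delta_t_star delta_theta
#>         30    578.50269       0.593
#>         45    277.24780       0.499
#>         60    135.10229       0.451
#>         75     46.18823       0.427
```

At a fresh trail (small `delta_t`) the gradient is strong and the droplet is
reflected with a peak turn rate of ~0.27 rad/s; beyond the critical lag
`delta_t_star` (here 277 s at 45°) the gradient has decayed enough for it to
cross.  The critical lag shrinks with incidence angle — head-on approaches
need torque the trail cannot supply — and `delta_theta` is the heading
uncertainty accumulated by rotational diffusion during the approach.

Recover the chemorepellent diffusivity from a noisy synthetic
trail-fluorescence series (ground truth D = 52.5 µm²/s, t_off = 20 s, 5%
multiplicative noise):

```r
ps <- gen_profiles(noise_frac = 0.05, seed = 42)
fit_profile_series(ps)
#> Trail diffusivity fit (variance): D = 52.2 um^2/s, t_off = 20.3 s
#>   peak-decay diagnostic slope: -0.505 (model: -0.5)
```

The per-slice Gaussian variances grow linearly in time (slope `2 D`), and
the peak decays as `(t + t_off)^(-1/2)`, as the moving point-source model
predicts.

Collective runs and their MSD analysis follow the same pattern:

```r
cfg <- collective_config(box_size = 2000, number_density = 7.4,
                         duration = 300,
                         dynamics = dynamics_params(dt = 0.05, D_r = 0.01))
sim <- simulate_collective(cfg, seed = 1)
msd <- ensemble_msd(sim)
detect_caging(msd)   # crossover lags and plateau height (NA when absent)
plot(msd)
```

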