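#' Generate a synthetic trail-fluorescence profile series
#'
#' Emulates time-resolved trail cross-section measurements: noise-free
#' intensities from the moving point-source model [intensity_profile()],
#' degraded by multiplicative Gaussian noise and an optional small additive
#' background floor.  The generating parameters and seed are attached as a
#' ground-truth record, so recovery by [fit_profile_series()] can be checked
#' round trip.
#'
#' @param D Generating diffusivity (um^2/s).
#' @param t_off Generating source offset (s).
#' @param times Slice times since droplet passage (s), `> 0`.
#' @param x_grid Section-line positions (um).
#' @param noise_frac Multiplicative noise fraction (0 = exact model).
#' @param I0 Intensity scale (a.u. * um).
#' @param background Additive floor (a.u.).
#' @param seed Integer seed.
#' @return A [profile_series()] with attribute `"ground_truth"`.
#' @export
gen_profiles <- function(D = 52.5, t_off = 20,
                         times = seq(5, 100, length.out = 20),
                         x_grid = seq(-300, 300, by = 1),
                         noise_frac = 0.05, I0 = 1000, background = 0,
                         seed = 1L) {
  if (!length(times) || !length(x_grid)) stop("empty time or position grid")
  stopifnot(all(times > 0))
  set.seed(seed)
  fp <- field_params(D = D, t_off = t_off)
  model <- outer(times, x_grid, function(t, x) intensity_profile(x, t, I0, fp))
  noise <- if (noise_frac > 0) {
    matrix(stats::rnorm(length(model), 0, noise_frac),
           nrow = nrow(model))
  } else 0
  intensity <- model * (1 + noise) + background
  ps <- profile_series(times, x_grid, intensity)
  attr(ps, "ground_truth") <- list(D = D, t_off = t_off, I0 = I0,
                                   noise_frac = noise_frac,
                                   background = background, seed = seed)
  ps
}

#' Generate a synthetic delayed-collision trajectory pair
#'
#' Builds one leader/follower event with known ground truth: the leader
#' moves in a straight line along the x-axis laying its trail; the follower
#' is launched by [simulate_event()] so that it meets the leader's path at
#' incidence angle `theta_inc` with time lag `delta_t`.  Additive Gaussian
#' observation noise is applied to the saved positions only, never to the
#' dynamics.  Times are shifted so both trajectories start at `t >= 0`.
#'
#' @param theta_inc Incidence angle (rad).
#' @param delta_t Time lag (s).
#' @param p,fp Parameter objects for the follower dynamics and the trail
#'   field.
#' @param position_noise SD of additive position noise (um), the sub-pixel
#'   tracking scale.
#' @param dt_sample Observation sampling interval (s).
#' @param d_max Interaction band half-width (um).
#' @param seed Integer seed.
#' @param trail_mode Passed to [simulate_event()].
#' @return A trajectory table (`droplet_id, t, x, y`) for droplets 1
#'   (leader) and 2 (follower), with attribute `"ground_truth"` recording
#'   all generating parameters and the noise-free event.
#' @export
gen_event_pair <- function(theta_inc, delta_t, p = dynamics_params(),
                           fp = field_params(), position_noise = 1,
                           dt_sample = 0.5, d_max = 220, seed = 1L,
                           trail_mode = "static") {
  ev <- simulate_event(theta_inc, delta_t, p, fp, trail_mode = trail_mode,
                       d_max = d_max)
  t_hit <- d_max / (p$V0 * sin(theta_inc))   # follower reaches y = 0 (straight)
  lead_len <- 3 * d_max
  # global shift keeping every sample (incl. the leader pre-history) at t >= 0
  T0 <- max(0, delta_t - t_hit) + lead_len / p$V0
  t_pass_lead <- T0 + t_hit - delta_t        # leader passes the aim point
  # leader path: through the aim point (0, 0) along +x at speed V0
  t_lead <- seq(t_pass_lead - lead_len / p$V0, t_pass_lead + lead_len / p$V0,
                by = dt_sample)
  leader <- data.frame(droplet_id = 1L, t = t_lead,
                       x = (t_lead - t_pass_lead) * p$V0, y = 0)
  # follower: resample the simulated event at the observation cadence
  tr <- ev$trajectory
  t_f <- seq(0, max(tr$t), by = dt_sample)
  follower <- data.frame(
    droplet_id = 2L, t = t_f + T0,
    x = stats::approx(tr$t, tr$x, xout = t_f)$y,
    y = stats::approx(tr$t, tr$y, xout = t_f)$y)
  out <- rbind(leader, follower)
  set.seed(seed)
  if (position_noise > 0) {
    out$x <- out$x + stats::rnorm(nrow(out), 0, position_noise)
    out$y <- out$y + stats::rnorm(nrow(out), 0, position_noise)
  }
  rownames(out) <- NULL
  attr(out, "ground_truth") <- list(
    theta_inc = theta_inc, delta_t = delta_t, V0 = p$V0,
    omega_c0 = p$omega_c0, alpha_c0 = p$alpha_c0, D_t = p$D_t, D_r = p$D_r,
    D = fp$D, t_off = fp$t_off, position_noise = position_noise,
    seed = seed, outcome = ev$outcome, event = ev)
  out
}

#' Generate a synthetic multi-droplet trajectory set
#'
#' Thin wrapper around [simulate_collective()] that attaches the generating
#' configuration and seed as a ground-truth record.
#'
#' @param cfg A [collective_config()].
#' @param seed Integer seed.
#' @return The `"collective_sim"` object with attribute `"ground_truth"`.
#' @export
gen_collective <- function(cfg = collective_config(), seed = 1L) {
  sim <- simulate_collective(cfg, seed = seed)
  attr(sim, "ground_truth") <- list(config = cfg, seed = seed)
  sim
}

#' Derived timescales of the droplet-trail system
#'
#' Characteristic scales combining the measured parameters: the diffusive
#' timescale of trail spreading `a^2 / D`, the advective timescale `a / V0`,
#' the persistence length `V0 / D_r`, and the longest caging lag
#' `l_cage / V0`.
#'
#' @param a_drop Droplet diameter (um).
#' @param D Chemorepellent diffusivity (um^2/s).
#' @param V0 Swimming speed (um/s).
#' @param D_r Rotational diffusivity (rad^2/s).
#' @param l_cage Largest observed cage size (um).
#' @return Named list: `tau_diff` (s), `tau_adv` (s), `persistence_length`
#'   (um), `t_cage` (s).
#' @export
derived_timescales <- function(a_drop = 50, D = 52.5, V0 = 25, D_r = 0.01,
                               l_cage = 500) {
  list(tau_diff = a_drop^2 / D,
       tau_adv = a_drop / V0,
       persistence_length = V0 / D_r,
       t_cage = l_cage / V0)
}
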