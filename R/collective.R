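#' Configuration for a collective simulation
#'
#' Describes an N-droplet Brownian-dynamics run in a periodic box: every
#' droplet obeys the CAPP equations in the superposed field of all deposited
#' trails, including its own past trail (self-interaction is required for
#' cage escape by self-generated chemorepellent buildup), excluding only its
#' own segments younger than `tau_self` to avoid artifacts from the
#' discretised fresh wake directly behind the swimmer.
#'
#' @param dimension 2 or 3.
#' @param box_size Periodic box side (um).  Should be at least 4 kernel
#'   widths at the memory cutoff (checked with a warning).
#' @param number_density Droplets per mm^2 (2D) or per mm^3 (3D).
#' @param duration Simulated time (s).
#' @param dynamics [dynamics_params()].
#' @param field [field_params()].
#' @param dt_deposit Trail deposition cadence (s); at the default speed this
#'   is a 12.5 um segment spacing, finer than the kernel width.
#' @param tau_self Own-trail blind window (s); default `2 * a / V0` for a
#'   50 um droplet.
#' @param save_every Save every `save_every`-th integration step.
#' @return An object of class `"collective_config"` with the droplet count
#'   `N = round(density * box area or volume)`.
#' @export
collective_config <- function(dimension = 2, box_size = 2000,
                              number_density = 3.7, duration = 300,
                              dynamics = dynamics_params(),
                              field = field_params(),
                              dt_deposit = 0.5, tau_self = 4,
                              save_every = 25L) {
  stopifnot(dimension %in% c(2, 3), box_size > 0, duration > 0,
            number_density > 0, dt_deposit > 0, tau_self >= 0)
  vol_mm <- (box_size / 1000)^dimension
  N <- as.integer(max(1, round(number_density * vol_mm)))
  kw <- sqrt(4 * field$D * field$T_mem)
  if (box_size < 4 * kw) {
    warning(sprintf("box_size %g um is below 4 kernel widths at T_mem (%g um)",
                    box_size, 4 * kw))
  }
  structure(list(dimension = as.integer(dimension), box_size = box_size,
                 number_density = number_density, N = N, duration = duration,
                 dynamics = dynamics, field = field,
                 dt_deposit = dt_deposit, tau_self = tau_self,
                 save_every = as.integer(save_every)),
            class = "collective_config")
}

#' @export
print.collective_config <- function(x, ...) {
  cat(sprintf("Collective CAPP configuration: %dD, box %g um, n = %g mm^-%d (N = %d)\n",
              x$dimension, x$box_size, x$number_density, x$dimension, x$N))
  cat(sprintf("  duration %g s, dt %g s, deposit every %g s, tau_self %g s\n",
              x$duration, x$dynamics$dt, x$dt_deposit, x$tau_self))
  invisible(x)
}

#' Simulate a collective of trail-depositing CAPP droplets
#'
#' Brownian dynamics of `cfg$N` droplets in a periodic box with
#' minimum-image field queries.  Droplets start uniformly at random with
#' random orientations, deposit trail segments every `cfg$dt_deposit`, and
#' respond to the superposition of all trails (their own trail included,
#' except its freshest `tau_self` seconds).  Trajectories are returned
#' unwrapped so displacement statistics are meaningful.
#'
#' Deterministic given the seed: the same configuration and seed reproduce
#' the trajectory table bit for bit.
#'
#' @param cfg A [collective_config()].
#' @param seed Integer seed.
#' @return An object of class `"collective_sim"`: list with `trajectories`
#'   (a `capp_trajectory` table for all droplets), `trails` (segment table
#'   `x, y[, z], t, ds, droplet_id`), and `config`.
#' @export
simulate_collective <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "collective_config"))
  set.seed(seed)
  d <- cfg$dimension
  N <- cfg$N
  L <- cfg$box_size
  pos0 <- matrix(stats::runif(N * d, 0, L), ncol = d)
  if (d == 2L) {
    th <- stats::runif(N, 0, 2 * pi)
    n0 <- cbind(cos(th), sin(th))
  } else {
    n0 <- matrix(stats::rnorm(N * 3L), ncol = 3L)
    n0 <- n0 / sqrt(rowSums(n0^2))
  }
  p <- cfg$dynamics
  fp <- cfg$field
  nsteps <- ceiling(cfg$duration / p$dt)
  res <- cpp_collective(pos0, n0, d,
                        V0 = p$V0, alpha = p$alpha_c0, omega = p$omega_c0,
                        Dt = p$D_t, Dr = p$D_r, dt = p$dt, nsteps = nsteps,
                        L = L, q = fp$q, D = fp$D, t_off = fp$t_off,
                        T_mem = fp$T_mem, R_max = fp$R_max,
                        dt_dep = cfg$dt_deposit, tau_self = cfg$tau_self,
                        save_every = cfg$save_every)
  traj <- as.data.frame(res$traj)
  names(traj) <- if (d == 2L) c("droplet_id", "t", "x", "y", "nx", "ny") else
    c("droplet_id", "t", "x", "y", "z", "nx", "ny", "nz")
  traj <- traj[order(traj$droplet_id, traj$t), , drop = FALSE]
  rownames(traj) <- NULL
  class(traj) <- c("capp_trajectory", "data.frame")
  segs <- as.data.frame(res$segments)
  names(segs) <- if (d == 2L) c("x", "y", "t", "ds", "droplet_id") else
    c("x", "y", "z", "t", "ds", "droplet_id")
  structure(list(trajectories = traj, trails = segs, config = cfg,
                 seed = seed),
            class = "collective_sim")
}

#' @export
print.collective_sim <- function(x, ...) {
  print(x$config)
  cat(sprintf("  %d trajectory samples, %d trail segments, seed %d\n",
              nrow(x$trajectories), nrow(x$trails), x$seed))
  invisible(x)
}

#' Ensemble mean squared displacement
#'
#' MSD relative to each droplet's position at the start time `t0`, averaged
#' over droplets: `MSD(t) = (1/N) * sum_i |r_i(t) - r_i(t0)|^2`.  There is
#' deliberately no averaging over time origins: the chemical landscape ages,
#' so the process is not stationary.  Trajectories are linearly resampled
#' onto a common time grid when their grids differ; single-sample
#' trajectories are excluded with a warning.
#'
#' A smoothed local logarithmic slope (the local MSD exponent, ~2 ballistic,
#' ~1 diffusive, ~0 caged) is attached, computed by least squares over a
#' centred window in `log(msd)` vs `log(lag)`.
#'
#' @param trajectories Trajectory table (or a `"collective_sim"`).
#' @param t0 Reference time; defaults to the earliest common time.
#' @param exponent_window Centred window (samples) for the local exponent.
#' @return A data frame of class `"msd_curve"` with columns `lag`, `msd`,
#'   `exponent`, carrying `n_droplets` as an attribute.
#' @export
ensemble_msd <- function(trajectories, t0 = NULL, exponent_window = 5L) {
  if (inherits(trajectories, "collective_sim")) {
    trajectories <- trajectories$trajectories
  }
  has_z <- "z" %in% names(trajectories)
  parts <- split(as.data.frame(trajectories), trajectories$droplet_id)
  parts <- lapply(parts, function(df) df[order(df$t), , drop = FALSE])
  short <- vapply(parts, function(df) nrow(df) < 2L, logical(1L))
  if (any(short)) {
    warning(sprintf("excluding %d single-sample trajectories", sum(short)))
    parts <- parts[!short]
  }
  if (!length(parts)) stop("no usable trajectories")
  grid <- parts[[1L]]$t
  if (is.null(t0)) t0 <- grid[1L]
  grid <- grid[grid >= t0]
  sq <- vapply(parts, function(df) {
    x <- stats::approx(df$t, df$x, xout = grid, rule = 2)$y
    y <- stats::approx(df$t, df$y, xout = grid, rule = 2)$y
    s <- (x - x[1L])^2 + (y - y[1L])^2
    if (has_z) {
      z <- stats::approx(df$t, df$z, xout = grid, rule = 2)$y
      s <- s + (z - z[1L])^2
    }
    s
  }, numeric(length(grid)))
  msd <- rowMeans(sq)
  lag <- grid - t0
  out <- data.frame(lag = lag, msd = msd)
  out$exponent <- local_exponent(lag, msd, exponent_window)
  attr(out, "n_droplets") <- length(parts)
  class(out) <- c("msd_curve", "data.frame")
  out
}

# local log-log slope by least squares over a centred window (clamped at the
# edges); defined only for lag > 0 and msd > 0
local_exponent <- function(lag, msd, window = 5L) {
  ok <- lag > 0 & msd > 0
  ll <- log(lag[ok])
  lm_ <- log(msd[ok])
  n <- length(ll)
  expo <- rep(NA_real_, n)
  h <- window %/% 2L
  for (i in seq_len(n)) {
    j <- max(1L, i - h):min(n, i + h)
    if (length(j) >= 2L && diff(range(ll[j])) > 0) {
      expo[i] <- stats::cov(ll[j], lm_[j]) / stats::var(ll[j])
    }
  }
  out <- rep(NA_real_, length(lag))
  out[ok] <- expo
  out
}

#' Detect caging in an MSD curve
#'
#' Finds the crossover to the caging regime (first lag where the smoothed
#' local MSD exponent drops below `threshold`), the crossover to cage
#' escape (the subsequent lag where it rises back above `threshold`), and
#' the plateau height (median MSD between the two).  The threshold 0.5
#' separates a plateau (exponent near 0) from diffusive growth (near 1).
#' Absent regimes are reported as `NA` -- absence is a valid result, not an
#' error.
#'
#' @param curve An [ensemble_msd()] result, or a data frame with `lag` and
#'   `msd` columns.
#' @param threshold Exponent threshold.
#' @param exponent_window Smoothing window (points of the log-resampled
#'   curve) for the local exponent.
#' @param points_per_decade Resolution of the log-spaced lag grid the curve
#'   is resampled onto before exponent estimation; a regime is a feature of
#'   lag decades, so detection on a fine linear time grid would be
#'   jitter-dominated.
#' @return A list with `crossover_to_caging`, `crossover_to_escape` (s) and
#'   `plateau_height` (um^2).
#' @export
detect_caging <- function(curve, threshold = 0.5, exponent_window = 5L,
                          points_per_decade = 25) {
  absent <- list(crossover_to_caging = NA_real_,
                 crossover_to_escape = NA_real_,
                 plateau_height = NA_real_)
  ok <- curve$lag > 0 & curve$msd > 0 & is.finite(curve$msd)
  if (sum(ok) < 3L) return(absent)
  llag <- log(curve$lag[ok])
  lmsd <- log(curve$msd[ok])
  grid <- seq(min(llag), max(llag), by = log(10) / points_per_decade)
  lm_g <- stats::approx(llag, lmsd, xout = grid, rule = 2)$y
  expo <- local_exponent(exp(grid), exp(lm_g), exponent_window)
  usable <- which(!is.na(expo))
  if (length(usable) < 2L) return(absent)
  below <- expo[usable] < threshold
  cage_i <- which(below)[1L]
  if (is.na(cage_i)) return(absent)
  esc_rel <- which(!below & seq_along(below) > cage_i)
  esc_i <- if (length(esc_rel)) esc_rel[1L] else NA_integer_
  t_cage <- exp(grid[usable[cage_i]])
  t_esc <- if (is.na(esc_i)) NA_real_ else exp(grid[usable[esc_i]])
  pl_win <- if (is.na(esc_i)) usable[cage_i:length(usable)] else
    usable[cage_i:esc_i]
  plateau <- stats::median(exp(lm_g[pl_win]))
  list(crossover_to_caging = t_cage, crossover_to_escape = t_esc,
       plateau_height = plateau)
}

#' @export
print.msd_curve <- function(x, ...) {
  cg <- detect_caging(x)
  cat(sprintf("Ensemble MSD: %d lags up to %g s (%s droplets)\n",
              nrow(x), max(x$lag), attr(x, "n_droplets")))
  if (!is.na(cg$crossover_to_caging)) {
    cat(sprintf("  caging from %g s%s, plateau %.3g um^2\n",
                cg$crossover_to_caging,
                if (is.na(cg$crossover_to_escape)) "" else
                  sprintf(" to %g s", cg$crossover_to_escape),
                cg$plateau_height))
  } else {
    cat("  no caging detected\n")
  }
  invisible(x)
}

#' @export
plot.msd_curve <- function(x, ...) {
  ok <- x$lag > 0 & x$msd > 0
  graphics::plot(x$lag[ok], x$msd[ok], log = "xy", type = "l",
                 xlab = "lag (s)", ylab = expression(MSD ~ (mu * m^2)),
                 main = "Ensemble MSD", ...)
  cg <- detect_caging(x)
  if (!is.na(cg$crossover_to_caging)) {
    graphics::points(cg$crossover_to_caging,
                     x$msd[which.min(abs(x$lag - cg$crossover_to_caging))],
                     pch = 8, col = "black", cex = 1.5)
  }
  if (!is.na(cg$crossover_to_escape)) {
    graphics::points(cg$crossover_to_escape,
                     x$msd[which.min(abs(x$lag - cg$crossover_to_escape))],
                     pch = 8, col = "red", cex = 1.5)
  }
  invisible(x)
}

#' Spatiotemporal neighbourhood history of one droplet
#'
#' For each sample of the focal droplet, collects the positions of other
#' droplets recorded within a spatial radius and a trailing time window --
#' the recent passages whose trails cage the focal droplet.
#'
#' @param trajectories Trajectory table (or `"collective_sim"`).
#' @param focal_id Droplet id of the focal trajectory.
#' @param d_window Spatial radius (um).
#' @param t_window Trailing time window (s): neighbours with
#'   `0 < t_focal - t <= t_window` qualify.
#' @return Data frame `focal_t, droplet_id, t, x, y[, z]` of qualifying
#'   neighbour samples (possibly empty).
#' @export
neighborhood_history <- function(trajectories, focal_id, d_window = 220,
                                 t_window = 50) {
  if (inherits(trajectories, "collective_sim")) {
    trajectories <- trajectories$trajectories
  }
  df <- as.data.frame(trajectories)
  has_z <- "z" %in% names(df)
  focal <- df[df$droplet_id == focal_id, , drop = FALSE]
  if (!nrow(focal)) stop(sprintf("no trajectory with droplet_id '%s'", focal_id))
  others <- df[df$droplet_id != focal_id, , drop = FALSE]
  cols <- c("droplet_id", "t", "x", "y", if (has_z) "z")
  out <- lapply(seq_len(nrow(focal)), function(i) {
    dt <- focal$t[i] - others$t
    d2 <- (others$x - focal$x[i])^2 + (others$y - focal$y[i])^2
    if (has_z) d2 <- d2 + (others$z - focal$z[i])^2
    sel <- dt > 0 & dt <= t_window & d2 < d_window^2
    if (!any(sel)) return(NULL)
    cbind(focal_t = focal$t[i], others[sel, cols, drop = FALSE])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(focal_t = numeric(), droplet_id = df$droplet_id[0],
                      t = numeric(), x = numeric(), y = numeric())
    if (has_z) out$z <- numeric()
  }
  rownames(out) <- NULL
  out
}
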