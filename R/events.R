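#' @useDynLib cappsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# moving-average smoothing with edge clamping
smooth_ma <- function(x, window = 5L) {
  if (window <= 1L || length(x) < window) return(x)
  k <- rep(1 / window, window)
  sm <- stats::filter(x, k, sides = 2L)
  sm <- as.numeric(sm)
  bad <- is.na(sm)
  sm[bad] <- x[bad]
  sm
}

unwrap_angle <- function(th) {
  d <- diff(th)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(th[1L], th[1L] + cumsum(d))
}

# centered finite differences on a (possibly non-uniform) time grid
central_diff <- function(t, x) {
  n <- length(x)
  if (n < 2L) return(rep(NA_real_, n))
  d <- numeric(n)
  d[1L] <- (x[2L] - x[1L]) / (t[2L] - t[1L])
  d[n] <- (x[n] - x[n - 1L]) / (t[n] - t[n - 1L])
  if (n > 2L) {
    i <- 2L:(n - 1L)
    d[i] <- (x[i + 1L] - x[i - 1L]) / (t[i + 1L] - t[i - 1L])
  }
  d
}

# kinematic series (speed, turn rate) from positions, after moving-average
# smoothing; raw finite differences of tracked positions are noise-dominated
event_kinematics <- function(t, x, y, window = 5L) {
  xs <- smooth_ma(x, window)
  ys <- smooth_ma(y, window)
  vx <- central_diff(t, xs)
  vy <- central_diff(t, ys)
  V <- sqrt(vx^2 + vy^2)
  th <- unwrap_angle(atan2(vy, vx))
  dthdt <- central_diff(t, th)
  list(V = V, dthdt = dthdt)
}

new_interaction_event <- function(theta_inc, delta_t, t0, series, outcome,
                                  trajectory = NULL, leader_id = NA,
                                  follower_id = NA, d_max = 220) {
  max_turn <- if (nrow(series)) max(abs(series$dthdt), na.rm = TRUE) else NA_real_
  structure(list(theta_inc = theta_inc, delta_t = delta_t, t0 = t0,
                 series = series, outcome = outcome,
                 max_turn_rate = max_turn, trajectory = trajectory,
                 leader_id = leader_id, follower_id = follower_id,
                 d_max = d_max),
            class = "interaction_event")
}

#' @export
print.interaction_event <- function(x, ...) {
  cat("Droplet-trail interaction event\n")
  cat(sprintf("  theta_inc = %.1f deg, delta_t = %.1f s, outcome: %s\n",
              x$theta_inc * 180 / pi, x$delta_t, x$outcome))
  cat(sprintf("  max |dtheta/dt| = %.3g rad/s, %d series samples\n",
              x$max_turn_rate, nrow(x$series)))
  invisible(x)
}

#' Simulate a single droplet-trail delayed collision
#'
#' Launches one CAPP droplet toward the straight trail of a leader that
#' passed `delta_t` seconds earlier, and integrates until the droplet leaves
#' the interaction band `|d| <= d_max`.  The trail field is the
#' one-dimensional Gaussian cross-section of [trail_cross_section()]: in the
#' default `"static"` mode its width is frozen at the value for lag
#' `delta_t`, while in `"aging"` mode the variance keeps growing as
#' `2*D*(delta_t + t_off + t)` during the encounter.
#'
#' The droplet starts on the incoming (positive-`d`) side at `d = d_max`,
#' heading toward the trail at incidence angle `theta_inc` with respect to
#' the trail line.  Noise is off unless `p` carries positive diffusivities.
#'
#' @param theta_inc Incidence angle (rad), in `(0, pi/2]`.
#' @param delta_t Time lag since leader passage (s), `> 0`.
#' @param p [dynamics_params()].
#' @param fp [field_params()].
#' @param trail_mode `"static"` (frozen profile) or `"aging"`.
#' @param d_max Interaction band half-width (um).
#' @param max_time Give up after this integration time (s); the event is
#'   then `"unresolved"`.
#' @param t_beyond Overshoot window (s): integration continues this long
#'   after the droplet first leaves the band, so the outgoing leg is
#'   recorded (the event series itself stays band-limited).
#' @param smooth Moving-average window (samples) for the kinematic series.
#' @param seed Optional seed for reproducible noisy events.
#' @return An object of class `"interaction_event"`, holding the incidence
#'   geometry, the `(t, d, V, dthdt)` series restricted to the band, the
#'   outcome (`"crossing"`, `"reflection"`, `"trapped-in-trail"` or
#'   `"unresolved"`), and the full trajectory.
#' @export
simulate_event <- function(theta_inc, delta_t, p = dynamics_params(),
                           fp = field_params(),
                           trail_mode = c("static", "aging"),
                           d_max = 220, max_time = 600, smooth = 5L,
                           seed = NULL, t_beyond = 10) {
  trail_mode <- match.arg(trail_mode)
  stopifnot(theta_inc > 0, theta_inc <= pi / 2, delta_t > 0)
  if (!is.null(seed)) set.seed(seed)
  var0 <- 2 * fp$D * (delta_t + fp$t_off)
  C0 <- fp$q / sqrt(2 * pi * var0)
  aging_D <- if (trail_mode == "aging") fp$D else 0
  x0 <- if (theta_inc < pi / 2) -d_max / tan(theta_inc) else 0
  res <- cpp_sim_gauss_trail(
    x0 = x0, y0 = d_max, th0 = -theta_inc,
    V0 = p$V0, alpha = p$alpha_c0, omega = p$omega_c0,
    Dt = p$D_t, Dr = p$D_r, dt = p$dt,
    C0 = C0, var0 = var0, aging_D = aging_D,
    dmax = d_max, max_steps = ceiling(max_time / p$dt), save_every = 1L,
    beyond_steps = as.integer(round(t_beyond / p$dt)))
  path <- res$path
  outcome <- switch(as.character(res$exit_code),
                    "0" = if (path[nrow(path), "y"] < 0) "crossing" else "reflection",
                    "1" = "unresolved",
                    "2" = "trapped-in-trail")
  kin <- event_kinematics(path[, "t"], path[, "x"], path[, "y"], smooth)
  inband <- abs(path[, "y"]) <= d_max
  series <- data.frame(t = path[inband, "t"], d = path[inband, "y"],
                       V = kin$V[inband], dthdt = kin$dthdt[inband])
  traj <- data.frame(droplet_id = 2L, t = path[, "t"], x = path[, "x"],
                     y = path[, "y"], nx = cos(path[, "theta"]),
                     ny = sin(path[, "theta"]))
  class(traj) <- c("capp_trajectory", "data.frame")
  new_interaction_event(theta_inc, delta_t, t0 = 0, series = series,
                        outcome = outcome, trajectory = traj,
                        leader_id = 1L, follower_id = 2L, d_max = d_max)
}

#' Classify a droplet-trail encounter as crossing or reflection
#'
#' Computes the signed distance of a trajectory to a straight trail line and
#' classifies the encounter: `"crossing"` if the droplet exits the band
#' `|d| <= d_max` on the side opposite to its entry, `"reflection"` if it
#' exits on the entry side.  A marginal path whose turning point sits at the
#' trail centre within `tol` is labelled `"reflection"` (the separatrix
#' convention).  A trajectory that never exits the band is `"unresolved"`.
#'
#' @param trajectory Data frame with columns `x, y` (and optionally `t`).
#' @param trail_line List with `origin` (a point on the trail, um) and `dir`
#'   (direction vector); defaults to the x-axis.
#' @param d_max Band half-width (um).
#' @param tol Centre tolerance (um) for the marginal turning point.
#' @return `"crossing"`, `"reflection"`, or `"unresolved"`.
#' @export
classify_event <- function(trajectory,
                           trail_line = list(origin = c(0, 0), dir = c(1, 0)),
                           d_max = 220, tol = 1e-3) {
  u <- trail_line$dir / sqrt(sum(trail_line$dir^2))
  dx <- trajectory$x - trail_line$origin[1L]
  dy <- trajectory$y - trail_line$origin[2L]
  d <- dx * u[2L] * (-1) + dy * u[1L]  # signed perpendicular distance
  inband <- abs(d) <= d_max
  if (!any(inband)) stop("trajectory never enters the interaction band")
  first_in <- which(inband)[1L]
  s0 <- sign(d[first_in])
  if (s0 == 0) s0 <- 1
  after <- seq_along(d) > first_in
  out_idx <- which(after & !inband)
  if (!length(out_idx)) return("unresolved")
  exit <- out_idx[1L]
  window <- first_in:(exit - 1L)
  penetration <- min(s0 * d[window])
  if (sign(d[exit]) == s0) return("reflection")
  if (penetration >= -tol) return("reflection")
  "crossing"
}

#' Crossing-reflection separatrix
#'
#' For each incidence angle, finds by bisection the critical time lag
#' `delta_t_star` at which the deterministic outcome of [simulate_event()]
#' switches from reflection (small lags, strong gradients) to crossing
#' (large lags).  The separatrix is the locus where the turning point of the
#' marginal trajectory sits exactly at the trail centre.  A rotational-noise
#' uncertainty band is attached: the orientation spread accumulated during
#' the approach, `delta_theta = sqrt(2 * D_r * T)` with approach time
#' `T = d_max / (V0 * sin(theta_inc))`.
#'
#' @param theta_grid Incidence angles (rad) in `(0, pi/2]`.
#' @param p,fp Parameter objects; noise in `p` is ignored (the separatrix is
#'   a noise-free construct).
#' @param d_max Band half-width (um).
#' @param bracket Bisection bracket for `delta_t_star` (s); angles whose
#'   switch falls outside are reported as `NA` rather than extrapolated.
#' @param tol Bisection tolerance (s).
#' @param D_r_band Rotational diffusivity (rad^2/s) used for the noise band.
#' @param trail_mode Passed to [simulate_event()].
#' @return A data frame of class `"separatrix_curve"` with columns
#'   `theta_inc`, `delta_t_star`, `delta_theta`.
#' @export
separatrix <- function(theta_grid, p = dynamics_params(), fp = field_params(),
                       d_max = 220, bracket = c(1, 600), tol = 0.5,
                       D_r_band = 0.01, trail_mode = "static") {
  p_det <- p
  p_det$D_t <- 0
  p_det$D_r <- 0
  reflects <- function(theta, lag) {
    ev <- simulate_event(theta, lag, p_det, fp, trail_mode = trail_mode,
                         d_max = d_max)
    ev$outcome %in% c("reflection", "trapped-in-trail")
  }
  star <- vapply(theta_grid, function(th) {
    if (!reflects(th, bracket[1L])) return(NA_real_)
    if (reflects(th, bracket[2L])) return(NA_real_)
    lo <- bracket[1L]
    hi <- bracket[2L]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (reflects(th, mid)) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1L))
  band <- sqrt(2 * D_r_band * d_max / (p$V0 * sin(theta_grid)))
  out <- data.frame(theta_inc = theta_grid, delta_t_star = star,
                    delta_theta = band)
  class(out) <- c("separatrix_curve", "data.frame")
  out
}

#' @export
print.separatrix_curve <- function(x, ...) {
  cat("Crossing-reflection separatrix:\n")
  print(data.frame(theta_deg = round(x$theta_inc * 180 / pi, 1),
                   delta_t_star = x$delta_t_star,
                   delta_theta = signif(x$delta_theta, 3)), row.names = FALSE)
  invisible(x)
}

#' @export
plot.separatrix_curve <- function(x, ...) {
  graphics::plot(x$theta_inc * 180 / pi, x$delta_t_star, type = "b",
                 xlab = "incidence angle (deg)",
                 ylab = expression(Delta * t^"*" ~ "(s)"),
                 main = "Crossing-reflection separatrix", ...)
  invisible(x)
}

# --- event detection from trajectory tables ---------------------------------

# intersection of two polylines; returns list of (x, y, tA, tB, dirA, dirB)
polyline_intersections <- function(A, B) {
  nA <- nrow(A) - 1L
  nB <- nrow(B) - 1L
  if (nA < 1L || nB < 1L) return(list())
  idx <- expand.grid(i = seq_len(nA), j = seq_len(nB))
  p1x <- A$x[idx$i]; p1y <- A$y[idx$i]
  d1x <- A$x[idx$i + 1L] - p1x; d1y <- A$y[idx$i + 1L] - p1y
  p2x <- B$x[idx$j]; p2y <- B$y[idx$j]
  d2x <- B$x[idx$j + 1L] - p2x; d2y <- B$y[idx$j + 1L] - p2y
  den <- d1x * d2y - d1y * d2x
  ok <- abs(den) > 1e-12
  s <- ((p2x - p1x) * d2y - (p2y - p1y) * d2x) / den
  u <- ((p2x - p1x) * d1y - (p2y - p1y) * d1x) / den
  hit <- ok & s >= 0 & s <= 1 & u >= 0 & u <= 1
  hit[is.na(hit)] <- FALSE
  which_hit <- which(hit)
  lapply(which_hit, function(k) {
    i <- idx$i[k]; j <- idx$j[k]
    list(x = p1x[k] + s[k] * d1x[k], y = p1y[k] + s[k] * d1y[k],
         tA = A$t[i] + s[k] * (A$t[i + 1L] - A$t[i]),
         tB = B$t[j] + u[k] * (B$t[j + 1L] - B$t[j]),
         dirA = c(d1x[k], d1y[k]), dirB = c(d2x[k], d2y[k]))
  })
}

# drop near-duplicate meeting points (adjacent-segment endpoint hits)
dedup_points <- function(pts, eps_x = 5, eps_t = 1) {
  keep <- list()
  for (pt in pts) {
    dup <- any(vapply(keep, function(q) {
      (q$x - pt$x)^2 + (q$y - pt$y)^2 < eps_x^2 && abs(q$tB - pt$tB) < eps_t
    }, logical(1L)))
    if (!dup) keep[[length(keep) + 1L]] <- pt
  }
  keep
}

# closest pair of samples between two trajectories
closest_approach <- function(A, B) {
  d2 <- outer(A$x, B$x, "-")^2 + outer(A$y, B$y, "-")^2
  k <- arrayInd(which.min(d2), dim(d2))
  i <- k[1L]; j <- k[2L]
  diri <- if (i < nrow(A)) c(A$x[i + 1L] - A$x[i], A$y[i + 1L] - A$y[i]) else
    c(A$x[i] - A$x[i - 1L], A$y[i] - A$y[i - 1L])
  dirj <- if (j < nrow(B)) c(B$x[j + 1L] - B$x[j], B$y[j + 1L] - B$y[j]) else
    c(B$x[j] - B$x[j - 1L], B$y[j] - B$y[j - 1L])
  list(x = (A$x[i] + B$x[j]) / 2, y = (A$y[i] + B$y[j]) / 2,
       tA = A$t[i], tB = B$t[j], dirA = diri, dirB = dirj,
       dist = sqrt(d2[i, j]))
}

fold_angle <- function(a) {
  a <- abs(a) %% pi
  if (a > pi / 2) a <- pi - a
  if (a == 0) a <- pi / 2 * 1e-12  # degenerate parallel tangents
  a
}

build_event <- function(A, B, pt, d_max, smooth) {
  # trail centre line: leader's path fitted over the interaction window
  near <- which((A$x - pt$x)^2 + (A$y - pt$y)^2 <= d_max^2)
  if (length(near) >= 2L) {
    ax <- A$x[near] - mean(A$x[near])
    ay <- A$y[near] - mean(A$y[near])
    cv <- cbind(ax, ay)
    ev <- eigen(crossprod(cv), symmetric = TRUE)
    u <- ev$vectors[, 1L]
    origin <- c(mean(A$x[near]), mean(A$y[near]))
  } else {
    u <- pt$dirA / sqrt(sum(pt$dirA^2))
    origin <- c(pt$x, pt$y)
  }
  d <- -(B$x - origin[1L]) * u[2L] + (B$y - origin[2L]) * u[1L]
  inband <- abs(d) <= d_max
  if (!any(inband)) return(NULL)
  # contiguous in-band window containing the passage time
  jb <- which.min(abs(B$t - pt$tB))
  if (!inband[jb]) jb <- which(inband)[which.min(abs(B$t[inband] - pt$tB))]
  lo <- jb
  while (lo > 1L && inband[lo - 1L]) lo <- lo - 1L
  hi <- jb
  while (hi < length(d) && inband[hi + 1L]) hi <- hi + 1L
  win <- lo:hi
  s0 <- sign(d[lo])
  if (s0 == 0) s0 <- 1
  kin <- event_kinematics(B$t, B$x, B$y, smooth)
  series <- data.frame(t = B$t[win], d = s0 * d[win],
                       V = kin$V[win], dthdt = kin$dthdt[win])
  tl <- list(origin = origin, dir = u)
  outcome <- tryCatch(
    classify_event(B[win[1L]:min(hi + 1L, nrow(B)), ], tl, d_max),
    error = function(e) "unresolved")
  # incidence angle from the follower heading just before band entry (the
  # tangent at the closest-approach point of a reflection is nearly parallel
  # to the trail, and inside the band the path already curves)
  ke <- max(1L, lo - 4L):min(lo + 4L, hi)
  if (length(ke) >= 2L) {
    ex <- B$x[ke] - mean(B$x[ke])
    ey <- B$y[ke] - mean(B$y[ke])
    ue <- eigen(crossprod(cbind(ex, ey)), symmetric = TRUE)$vectors[, 1L]
  } else {
    ue <- pt$dirB
  }
  th <- fold_angle(atan2(ue[2L], ue[1L]) - atan2(u[2L], u[1L]))
  new_interaction_event(theta_inc = th, delta_t = pt$tB - pt$tA, t0 = pt$tB,
                        series = series, outcome = outcome,
                        trajectory = B,
                        leader_id = A$droplet_id[1L],
                        follower_id = B$droplet_id[1L], d_max = d_max)
}

#' Detect droplet-trail interactions in a trajectory table
#'
#' Scans all ordered droplet pairs for delayed collisions: places where the
#' follower's path meets (or most closely approaches) the earlier path of a
#' leader.  An interaction spans the window where the follower's distance to
#' the leader's trail line is below `d_max`; the time lag `delta_t` is the
#' difference of the two passage times at the meeting point, and the
#' incidence angle is the angle between the local path tangents, folded to
#' `(0, pi/2]`.  Signed distance, speed and turn-rate series are computed by
#' centred finite differences after moving-average smoothing, with the sign
#' convention that the follower's incoming side is positive.
#'
#' @param trajectories Trajectory table (`droplet_id, t, x, y`) with at
#'   least two droplets.
#' @param d_max Interaction band half-width (um).
#' @param smooth Moving-average window (samples) for the kinematic series.
#' @return A list of [simulate_event()]-style `"interaction_event"` objects
#'   (empty if no pair ever comes within `d_max`).
#' @export
detect_interactions <- function(trajectories, d_max = 220, smooth = 5L) {
  parts <- split(as.data.frame(trajectories), trajectories$droplet_id)
  parts <- lapply(parts, function(df) df[order(df$t), , drop = FALSE])
  if (length(parts) < 2L) stop("need at least two trajectories")
  ids <- names(parts)
  events <- list()
  for (a in ids) for (b in ids) {
    if (a == b) next
    A <- parts[[a]]
    B <- parts[[b]]
    pts <- polyline_intersections(A, B)
    pts <- Filter(function(pt) pt$tB > pt$tA, pts)
    pts <- dedup_points(pts)
    if (!length(pts)) {
      ca <- closest_approach(A, B)
      if (ca$dist <= d_max && ca$tB > ca$tA) pts <- list(ca)
    }
    for (pt in pts) {
      ev <- build_event(A, B, pt, d_max, smooth)
      if (!is.null(ev)) events[[length(events) + 1L]] <- ev
    }
  }
  events
}

#' Tabulate interaction events
#'
#' @param events List of `"interaction_event"` objects.
#' @return Data frame with one row per event: leader and follower ids,
#'   `theta_inc` (rad), `delta_t` (s), `outcome`, `max_turn_rate` (rad/s).
#' @export
events_table <- function(events) {
  if (!length(events)) {
    return(data.frame(leader_id = character(), follower_id = character(),
                      theta_inc = numeric(), delta_t = numeric(),
                      outcome = character(), max_turn_rate = numeric()))
  }
  do.call(rbind, lapply(events, function(e) {
    data.frame(leader_id = as.character(e$leader_id),
               follower_id = as.character(e$follower_id),
               theta_inc = e$theta_inc, delta_t = e$delta_t,
               outcome = e$outcome, max_turn_rate = e$max_turn_rate)
  }))
}

#' Interaction diagram from a simulated grid
#'
#' Sweeps a grid of incidence angles and time lags with [simulate_event()]
#' and returns the outcome table mapping the crossing/reflection regions,
#' analogous to plotting all observed delayed collisions in the
#' `(theta_inc, delta_t)` plane.
#'
#' @param theta_grid Incidence angles (rad).
#' @param delta_t_grid Time lags (s).
#' @param p,fp Parameter objects.
#' @param ... Passed to [simulate_event()].
#' @return Data frame with `theta_inc`, `delta_t`, `outcome`,
#'   `max_turn_rate`.
#' @export
interaction_diagram <- function(theta_grid, delta_t_grid,
                                p = dynamics_params(), fp = field_params(),
                                ...) {
  grid <- expand.grid(theta_inc = theta_grid, delta_t = delta_t_grid)
  res <- lapply(seq_len(nrow(grid)), function(k) {
    ev <- simulate_event(grid$theta_inc[k], grid$delta_t[k], p, fp, ...)
    data.frame(theta_inc = grid$theta_inc[k], delta_t = grid$delta_t[k],
               outcome = ev$outcome, max_turn_rate = ev$max_turn_rate)
  })
  do.call(rbind, res)
}
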