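#' CAPP dynamics parameters
#'
#' Parameters of the chemically active polar particle (CAPP) Langevin
#' equations.  A droplet at position `r` with unit orientation `n` obeys
#'
#' \deqn{\dot r = V_0 n - \alpha \nabla c + \sqrt{2 D_t}\,\xi_t}
#' \deqn{\dot n = \Omega\, n \times (n \times \nabla c) + \sqrt{2 D_r}\, n \times \xi_r}
#'
#' so a positive torque coupling `omega_c0` turns the droplet away from the
#' chemorepellent gradient and a positive force coupling `alpha_c0` repels it
#' down-gradient.  The couplings are lumped products of the bare coupling
#' constants with the concentration scale set by the field's deposition
#' strength `q` (see [field_params()]).
#'
#' @param V0 Self-propulsion speed (um/s).
#' @param alpha_c0 Lumped chemotactic force coupling (um^3/s).
#' @param omega_c0 Lumped chemotactic torque coupling (um^2/s).
#' @param D_t Translational diffusivity (um^2/s).  Defaults to 0: Brownian
#'   translational diffusion of a 50 um droplet is negligible.
#' @param D_r Rotational diffusivity (rad^2/s).  Defaults to 0; the
#'   experimental upper bound for these droplets is 0.01 rad^2/s.
#' @param dt Integration time step (s).
#' @return An object of class `"dynamics_params"`.
#' @export
dynamics_params <- function(V0 = 25, alpha_c0 = 3e4, omega_c0 = 7e3,
                            D_t = 0, D_r = 0, dt = 0.02) {
  stopifnot(is.numeric(V0), V0 > 0, is.numeric(dt), dt > 0,
            is.numeric(D_t), D_t >= 0, is.numeric(D_r), D_r >= 0,
            is.numeric(alpha_c0), is.numeric(omega_c0))
  structure(list(V0 = V0, alpha_c0 = alpha_c0, omega_c0 = omega_c0,
                 D_t = D_t, D_r = D_r, dt = dt),
            class = "dynamics_params")
}

#' @export
print.dynamics_params <- function(x, ...) {
  cat("CAPP dynamics parameters:\n")
  cat(sprintf("  V0 = %g um/s, omega_c0 = %g um^2/s, alpha_c0 = %g um^3/s\n",
              x$V0, x$omega_c0, x$alpha_c0))
  cat(sprintf("  D_t = %g um^2/s, D_r = %g rad^2/s, dt = %g s\n",
              x$D_t, x$D_r, x$dt))
  invisible(x)
}

#' Particle state
#'
#' Position, unit orientation, and clock of one droplet.
#'
#' @param r Position (um), length 2 or 3.
#' @param n Orientation, same length as `r`; must be a unit vector to within
#'   1e-6 (it is renormalised exactly on construction).
#' @param t Time (s).
#' @return An object of class `"particle_state"`.
#' @export
particle_state <- function(r, n, t = 0) {
  stopifnot(length(r) %in% c(2L, 3L), length(n) == length(r))
  nn <- sqrt(sum(n^2))
  if (abs(nn - 1) > 1e-6) stop("orientation must be a unit vector (|n| within 1e-6 of 1)")
  structure(list(r = as.numeric(r), n = as.numeric(n) / nn, t = t),
            class = "particle_state")
}

#' One Euler-Maruyama step of the CAPP equations
#'
#' Advances a [particle_state()] by one time step in an arbitrary
#' concentration field.  The position is advanced by
#' `(V0 * n - alpha * grad_c) * dt` plus translational noise; the orientation
#' is rotated by the tangential projection of the torque (in 2D the
#' deterministic turn rate is `-omega * (grad_c . n_perp)` with `n_perp` the
#' +90-degree rotation of `n`) plus rotational noise, then renormalised.
#'
#' @param state A [particle_state()].
#' @param field A function `(r, t)` returning `list(c = , grad = )` as
#'   produced by [field_superposition()], or `NULL` for a field-free step.
#' @param p [dynamics_params()].
#' @return The advanced [particle_state()].
#' @export
capp_step <- function(state, field, p = dynamics_params()) {
  n <- state$n
  if (abs(sqrt(sum(n^2)) - 1) > 1e-6) stop("non-unit orientation")
  d <- length(state$r)
  if (is.null(field)) {
    g <- numeric(d)
  } else {
    f <- field(state$r, state$t)
    g <- f$grad
    if (any(!is.finite(g)) || !is.finite(f$c)) stop("field returned non-finite values")
  }
  gn <- sqrt(sum(g^2))
  if (abs(p$omega_c0) * gn * p$dt > 0.5) {
    warning("|omega * grad c| * dt exceeds 0.5 rad; reduce dt")
  }
  r_new <- state$r + (p$V0 * n - p$alpha_c0 * g) * p$dt
  if (p$D_t > 0) r_new <- r_new + sqrt(2 * p$D_t * p$dt) * stats::rnorm(d)
  if (d == 2L) {
    th <- atan2(n[2L], n[1L])
    th <- th - p$omega_c0 * (g[1L] * (-n[2L]) + g[2L] * n[1L]) * p$dt
    if (p$D_r > 0) th <- th + sqrt(2 * p$D_r * p$dt) * stats::rnorm(1L)
    n_new <- c(cos(th), sin(th))
  } else {
    n_new <- n + p$omega_c0 * p$dt * (sum(n * g) * n - g)
    if (p$D_r > 0) {
      xi <- stats::rnorm(3L)
      xi <- xi - sum(xi * n) * n
      n_new <- n_new + sqrt(2 * p$D_r * p$dt) * xi
    }
    n_new <- n_new / sqrt(sum(n_new^2))
  }
  structure(list(r = r_new, n = n_new, t = state$t + p$dt),
            class = "particle_state")
}

#' Integrate a CAPP trajectory
#'
#' Drives [capp_step()] from an initial state for a given duration and
#' returns the sampled trajectory.  Deterministic given the R random seed.
#'
#' @param state0 Initial [particle_state()].
#' @param field Field query function as in [capp_step()], or `NULL`.
#' @param p [dynamics_params()].
#' @param duration Integration time (s), `> 0`.
#' @param save_every Keep every `save_every`-th step (decimation).
#' @param droplet_id Identifier written into the trajectory table.
#' @param seed Optional integer seed applied via [set.seed()].
#' @return A data frame of class `"capp_trajectory"` with columns
#'   `droplet_id, t, x, y[, z], nx, ny[, nz]`.
#' @export
capp_simulate <- function(state0, field, p = dynamics_params(), duration,
                          save_every = 1L, droplet_id = 1L, seed = NULL) {
  stopifnot(duration > 0)
  if (!is.null(seed)) set.seed(seed)
  nsteps <- ceiling(duration / p$dt)
  d <- length(state0$r)
  keep <- seq(0L, nsteps, by = save_every)
  out <- matrix(NA_real_, nrow = length(keep), ncol = 1L + 2L * d)
  st <- state0
  row <- 1L
  out[row, ] <- c(st$t, st$r, st$n)
  for (k in seq_len(nsteps)) {
    st <- capp_step(st, field, p)
    if (k %% save_every == 0L) {
      row <- row + 1L
      out[row, ] <- c(st$t, st$r, st$n)
    }
  }
  out <- out[seq_len(row), , drop = FALSE]
  cols <- if (d == 2L) c("t", "x", "y", "nx", "ny") else c("t", "x", "y", "z", "nx", "ny", "nz")
  df <- as.data.frame(out)
  names(df) <- cols
  df <- cbind(droplet_id = droplet_id, df)
  class(df) <- c("capp_trajectory", "data.frame")
  df
}

#' @export
print.capp_trajectory <- function(x, ...) {
  d <- if ("z" %in% names(x)) 3L else 2L
  cat(sprintf("CAPP trajectory: %d samples, %dD, t in [%g, %g] s\n",
              nrow(x), d, min(x$t), max(x$t)))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}
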