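#' Fit the CAPP coupling constants to one observed event
#'
#' Estimates the lumped torque and force couplings `(omega_c0, alpha_c0)` by
#' least squares: the CAPP equations are integrated forward (noise-free)
#' through the same frozen Gaussian trail profile the event experienced, and
#' the mean squared distance between observed and simulated positions at the
#' observed sample times is minimised.  The initial position is the first
#' observed sample and the initial orientation the first displacement
#' direction.  Optimisation is a derivative-free simplex on
#' `log10(omega, alpha)` inside box bounds, restarted from several
#' log-spaced initial guesses because the forward model is non-smooth at the
#' crossing-reflection boundary.
#'
#' @param event An `"interaction_event"` whose `trajectory` (or `series`)
#'   holds the observed positions; `event$delta_t` sets the trail profile.
#' @param p_fixed [dynamics_params()]; its couplings are ignored and
#'   replaced by the fit parameters, its noise is switched off in the
#'   forward model.
#' @param fp [field_params()].
#' @param init Optional matrix/vector of starting values
#'   `c(omega_c0, alpha_c0)`; by default 5 log-spaced multistarts.
#' @param bounds List with `omega` and `alpha` ranges (package units).
#' @param trail_mode Trail profile mode, as in [simulate_event()].
#' @return An object of class `"capp_fit"` with components `coefficients`
#'   (`omega_c0`, `alpha_c0`), `loss` (mean squared position residual,
#'   um^2), `converged`, `identifiable`, the observed and fitted
#'   trajectories, and the multistart table.  Methods: `print`, `coef`,
#'   `summary`, `residuals`, `fitted`, `plot`.
#' @export
fit_event <- function(event, p_fixed = dynamics_params(), fp = field_params(),
                      init = NULL,
                      bounds = list(omega = c(1e1, 1e6), alpha = c(1e2, 1e7)),
                      trail_mode = c("static", "aging")) {
  trail_mode <- match.arg(trail_mode)
  obs <- event$trajectory
  if (is.null(obs)) stop("event carries no observed trajectory")
  obs <- obs[order(obs$t), , drop = FALSE]
  if (nrow(obs) < 20L) stop("need at least 20 observed samples to fit")

  var0 <- 2 * fp$D * (event$delta_t + fp$t_off)
  C0 <- fp$q / sqrt(2 * pi * var0)
  aging_D <- if (trail_mode == "aging") fp$D else 0

  t_rel <- obs$t - obs$t[1L]
  duration <- max(t_rel)
  # initial heading from the principal axis of the first few samples --
  # a single noisy displacement would seed the forward model badly
  k0 <- min(7L, nrow(obs))
  hx <- obs$x[seq_len(k0)] - mean(obs$x[seq_len(k0)])
  hy <- obs$y[seq_len(k0)] - mean(obs$y[seq_len(k0)])
  u <- eigen(crossprod(cbind(hx, hy)), symmetric = TRUE)$vectors[, 1L]
  if (sum(u * c(obs$x[k0] - obs$x[1L], obs$y[k0] - obs$y[1L])) < 0) u <- -u
  th0 <- atan2(u[2L], u[1L])
  dt <- p_fixed$dt
  max_steps <- ceiling(duration / dt) + 1L

  forward <- function(omega, alpha, th) {
    res <- cpp_sim_gauss_trail(
      x0 = obs$x[1L], y0 = obs$y[1L], th0 = th,
      V0 = p_fixed$V0, alpha = alpha, omega = omega,
      Dt = 0, Dr = 0, dt = dt, C0 = C0, var0 = var0, aging_D = aging_D,
      dmax = Inf, max_steps = max_steps, save_every = 1L)
    res$path
  }
  # parameters: log10(omega), log10(alpha), plus the initial heading as a
  # nuisance (it is not observed directly and a finite-difference estimate
  # is biased by path curvature and tracking noise)
  objective <- function(lpar) {
    lo <- c(log10(bounds$omega[1L]), log10(bounds$alpha[1L]), th0 - 0.5)
    hi <- c(log10(bounds$omega[2L]), log10(bounds$alpha[2L]), th0 + 0.5)
    pen <- sum(pmax(0, lpar - hi)^2 + pmax(0, lo - lpar)^2)
    lpar <- pmin(pmax(lpar, lo), hi)
    path <- forward(10^lpar[1L], 10^lpar[2L], lpar[3L])
    xs <- stats::approx(path[, "t"], path[, "x"], xout = t_rel, rule = 2)$y
    ys <- stats::approx(path[, "t"], path[, "y"], xout = t_rel, rule = 2)$y
    mean((xs - obs$x)^2 + (ys - obs$y)^2) * (1 + pen)
  }

  if (is.null(init)) {
    init <- cbind(omega = 10^seq(2, 5, length.out = 5L),
                  alpha = 10^seq(3, 6, length.out = 5L))
  } else if (is.null(dim(init))) {
    init <- matrix(init, nrow = 1L, dimnames = list(NULL, c("omega", "alpha")))
  }

  start_loss <- apply(init, 1L, function(s) objective(c(log10(s), th0)))
  # flat loss surface across decades of couplings: no gradient signal.
  # "Flat" is judged against measurement resolution: if sweeping the start
  # grid moves the trajectory by less than 0.01 um RMS, nothing constrains
  # the couplings.
  identifiable <- diff(range(start_loss)) >
    max(1e-4, 1e-8 * (1 + min(start_loss)))

  starts <- vector("list", nrow(init))
  for (k in seq_len(nrow(init))) {
    opt <- stats::optim(c(log10(init[k, ]), th0), objective,
                        method = "Nelder-Mead",
                        control = list(maxit = 600L, reltol = 1e-10))
    om <- min(max(10^opt$par[1L], bounds$omega[1L]), bounds$omega[2L])
    al <- min(max(10^opt$par[2L], bounds$alpha[1L]), bounds$alpha[2L])
    starts[[k]] <- data.frame(omega0 = init[k, 1L], alpha0 = init[k, 2L],
                              omega_hat = om,
                              alpha_hat = al,
                              th0_hat = opt$par[3L],
                              loss = opt$value, conv = opt$convergence == 0L)
  }
  starts <- do.call(rbind, starts)
  best <- which.min(starts$loss)
  coefs <- c(omega_c0 = starts$omega_hat[best], alpha_c0 = starts$alpha_hat[best])
  path <- forward(coefs[1L], coefs[2L], starts$th0_hat[best])
  fitted_traj <- data.frame(
    t = t_rel + obs$t[1L],
    x = stats::approx(path[, "t"], path[, "x"], xout = t_rel, rule = 2)$y,
    y = stats::approx(path[, "t"], path[, "y"], xout = t_rel, rule = 2)$y)

  structure(list(coefficients = coefs, loss = starts$loss[best],
                 converged = starts$conv[best] && identifiable,
                 identifiable = identifiable,
                 starts = starts, observed = obs, fitted = fitted_traj,
                 event_id = paste(event$leader_id, event$follower_id, sep = "-"),
                 bounds = bounds),
            class = "capp_fit")
}

#' @export
coef.capp_fit <- function(object, ...) object$coefficients

#' @export
print.capp_fit <- function(x, ...) {
  cat("CAPP coupling fit", if (!x$converged) "(not converged)", "\n")
  cat(sprintf("  omega_c0 = %.3g um^2/s, alpha_c0 = %.3g um^3/s\n",
              x$coefficients[1L], x$coefficients[2L]))
  cat(sprintf("  mean squared position residual: %.3g um^2 (%d samples)\n",
              x$loss, nrow(x$observed)))
  if (!x$identifiable) cat("  warning: loss is flat in the couplings (no trail signal)\n")
  invisible(x)
}

#' @export
summary.capp_fit <- function(object, ...) {
  cat("Multistart results:\n")
  print(object$starts, row.names = FALSE)
  print(object)
  invisible(object)
}

#' @export
residuals.capp_fit <- function(object, ...) {
  sqrt((object$observed$x - object$fitted$x)^2 +
       (object$observed$y - object$fitted$y)^2)
}

#' @export
fitted.capp_fit <- function(object, ...) object$fitted

#' @export
plot.capp_fit <- function(x, ...) {
  graphics::plot(x$observed$x, x$observed$y, pch = 1, col = "grey40",
                 xlab = "x (um)", ylab = "y (um)", asp = 1,
                 main = "Observed vs fitted trajectory", ...)
  graphics::lines(x$fitted$x, x$fitted$y, col = "red", lwd = 2)
  graphics::legend("topright", c("observed", "CAPP fit"),
                   pch = c(1, NA), lty = c(NA, 1), col = c("grey40", "red"))
  invisible(x)
}

#' Median couplings over a set of event fits
#'
#' Component-wise medians of the fitted couplings over the converged fits,
#' the aggregate the single-event analysis feeds into the collective
#' simulations.
#'
#' @param fits List of [fit_event()] results.
#' @return Named vector `c(omega_c0 = , alpha_c0 = )`.
#' @export
median_couplings <- function(fits) {
  if (!length(fits)) stop("no fits supplied")
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (!length(conv)) stop("no converged fits")
  om <- vapply(conv, function(f) f$coefficients[["omega_c0"]], numeric(1L))
  al <- vapply(conv, function(f) f$coefficients[["alpha_c0"]], numeric(1L))
  c(omega_c0 = stats::median(om), alpha_c0 = stats::median(al))
}
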