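#' Chemorepellent field parameters
#'
#' Bundles the parameters of the diffusing chemorepellent (oil-filled
#' micelle) field shed along droplet trails.  All lengths are in micrometres
#' and times in seconds, the fixed unit system of the package.
#'
#' The trail field is a superposition of Gaussian diffusion kernels.  Because
#' the emitting droplet has a finite radius rather than being a point source,
#' every kernel age is shifted by `t_off`: a cross-section a lag `tau` after
#' droplet passage has variance `2 * D * (tau + t_off)`.
#'
#' @param D Chemorepellent diffusivity (um^2/s).  The default is the filled
#'   micelle diffusivity recovered from trail-fluorescence profiles.
#' @param t_off Finite-source time offset (s) added to every kernel age.
#' @param q Deposition strength: emission per unit trail length.  It sets the
#'   concentration scale; couplings are treated as lumped products with this
#'   scale (see [dynamics_params()]).
#' @param T_mem Memory cutoff (s): trail segments older than this are dropped
#'   from field sums.
#' @param R_max Spatial cutoff (um): segments farther than this from the query
#'   point are dropped.  The default keeps truncated contributions below
#'   1e-6 of a fresh peak.
#' @param ds_max Maximum trail sample spacing (um) used when resampling
#'   trails before kernel quadrature.
#'
#' @return An object of class `"field_params"`.
#' @seealso [trail_cross_section()], [field_superposition()]
#' @export
field_params <- function(D = 52.5, t_off = 20, q = 1,
                         T_mem = 600, R_max = 5 * sqrt(4 * D * T_mem),
                         ds_max = 25) {
  stopifnot(is.numeric(D), length(D) == 1L, D > 0,
            is.numeric(t_off), length(t_off) == 1L, t_off >= 0,
            is.numeric(q), length(q) == 1L, q > 0,
            is.numeric(T_mem), length(T_mem) == 1L, T_mem > 0,
            is.numeric(R_max), length(R_max) == 1L, R_max > 0,
            is.numeric(ds_max), length(ds_max) == 1L, ds_max > 0)
  structure(list(D = D, t_off = t_off, q = q, T_mem = T_mem,
                 R_max = R_max, ds_max = ds_max),
            class = "field_params")
}

#' @export
print.field_params <- function(x, ...) {
  cat("Chemorepellent field parameters (um, s):\n")
  cat(sprintf("  D = %g um^2/s, t_off = %g s, q = %g\n", x$D, x$t_off, x$q))
  cat(sprintf("  cutoffs: T_mem = %g s, R_max = %g um, ds_max = %g um\n",
              x$T_mem, x$R_max, x$ds_max))
  invisible(x)
}

#' Trail record of one droplet
#'
#' The time-stamped emission path of a droplet: the source of its
#' chemorepellent trail.  Emission times must be strictly increasing.
#'
#' @param droplet_id Identifier of the emitting droplet.
#' @param t Emission times (s), strictly increasing.
#' @param x,y Positions (um) at those times; `z` optional for 3D.
#' @param z Optional third coordinate (um).
#' @return A data frame of class `"trail_record"` with columns
#'   `droplet_id, t, x, y[, z]`.
#' @export
trail_record <- function(droplet_id, t, x, y, z = NULL) {
  if (length(t) < 1L) stop("trail must contain at least one sample")
  if (any(diff(t) <= 0)) stop("emission times must be strictly increasing")
  if (length(x) == 1L) x <- rep(x, length(t))
  if (length(y) == 1L) y <- rep(y, length(t))
  stopifnot(length(x) == length(t), length(y) == length(t))
  df <- data.frame(droplet_id = droplet_id, t = t, x = x, y = y)
  if (!is.null(z)) {
    if (length(z) == 1L) z <- rep(z, length(t))
    stopifnot(length(z) == length(t))
    df$z <- z
  }
  class(df) <- c("trail_record", "data.frame")
  df
}

#' Resample a trail to a maximum spatial spacing
#'
#' Linearly interpolates extra samples so that consecutive points are at most
#' `ds_max` apart, ensuring the midpoint-rule kernel quadrature resolves the
#' kernel width (which is at least `sqrt(4*D*t_off)` at birth).
#'
#' @param trail A [trail_record()].
#' @param ds_max Maximum spacing (um).
#' @return A `trail_record` with the same geometry and refined sampling.
#' @export
resample_trail <- function(trail, ds_max = 25) {
  n <- nrow(trail)
  if (n < 2L) return(trail)
  has_z <- "z" %in% names(trail)
  seg_len <- if (has_z) {
    sqrt(diff(trail$x)^2 + diff(trail$y)^2 + diff(trail$z)^2)
  } else {
    sqrt(diff(trail$x)^2 + diff(trail$y)^2)
  }
  pieces <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    m <- max(1L, ceiling(seg_len[k] / ds_max))
    f <- seq(0, 1, length.out = m + 1L)[-(m + 1L)]
    pieces[[k]] <- data.frame(
      t = trail$t[k] + f * (trail$t[k + 1L] - trail$t[k]),
      x = trail$x[k] + f * (trail$x[k + 1L] - trail$x[k]),
      y = trail$y[k] + f * (trail$y[k + 1L] - trail$y[k]))
    if (has_z) pieces[[k]]$z <- trail$z[k] + f * (trail$z[k + 1L] - trail$z[k])
  }
  out <- do.call(rbind, pieces)
  last <- trail[n, setdiff(names(trail), "droplet_id"), drop = FALSE]
  out <- rbind(out, last)
  out <- cbind(droplet_id = trail$droplet_id[1L], out)
  class(out) <- c("trail_record", "data.frame")
  rownames(out) <- NULL
  out
}

kernel_age <- function(lag, fp) {
  if (any(lag < 0)) stop("lag since trail passage must be non-negative")
  lag + fp$t_off
}

#' Trail cross-section concentration
#'
#' Concentration of a straight trail's chemorepellent along a line
#' perpendicular to the trail, a time `lag` after the droplet passed:
#' a Gaussian `q / sqrt(4*pi*D*(lag + t_off)) * exp(-y^2 / (4*D*(lag + t_off)))`
#' whose integral over `y` is independent of the lag (the deposited mass per
#' unit trail length is conserved while it spreads) and whose peak decays as
#' `(lag + t_off)^(-1/2)`.
#'
#' @param y Signed distance from the trail centre line (um); vectorised.
#' @param lag Time since droplet passage (s), `>= 0`; vectorised.
#' @param fp [field_params()].
#' @return Concentration (dimensionless package units).
#' @export
trail_cross_section <- function(y, lag, fp = field_params()) {
  tau <- kernel_age(lag, fp)
  fp$q / sqrt(4 * pi * fp$D * tau) * exp(-y^2 / (4 * fp$D * tau))
}

#' Gradient of the trail cross-section
#'
#' Derivative of [trail_cross_section()] with respect to the signed distance
#' `y`.  Odd in `y`, zero at the trail centre, with extrema at
#' `y = +/- sqrt(2*D*(lag + t_off))`.
#'
#' @inheritParams trail_cross_section
#' @return `d c / d y` (1/um).
#' @export
cross_section_gradient <- function(y, lag, fp = field_params()) {
  tau <- kernel_age(lag, fp)
  -trail_cross_section(y, lag, fp) * y / (2 * fp$D * tau)
}

#' Fluorescence intensity of a trail cross-section
#'
#' Intensity model for the trail of a droplet approximated as a point source
#' moving at constant speed and emitting at a constant rate: along a fixed
#' line perpendicular to the trail the intensity is Gaussian in `x` with
#' variance `2*D*(t + t_off)` and peak height proportional to
#' `(t + t_off)^(-1/2)`.
#'
#' @param x Position along the section line (um), centred on the trail.
#' @param t Time since droplet passage (s), `>= 0`.
#' @param I0 Intensity scale (a.u. * um): the emitted amount per unit trail
#'   length in intensity units.
#' @param fp [field_params()].
#' @return Intensity (a.u.).
#' @export
intensity_profile <- function(x, t, I0 = 1, fp = field_params()) {
  if (any(t < 0)) stop("time since passage must be non-negative")
  tau <- t + fp$t_off
  I0 / sqrt(4 * pi * fp$D * tau) * exp(-x^2 / (4 * fp$D * tau))
}

as_trail_list <- function(trails) {
  if (is.data.frame(trails)) {
    if (nrow(trails) == 0L) return(list())
    return(split(trails, trails$droplet_id))
  }
  trails
}

#' Superposed trail field at a point
#'
#' Concentration and gradient at position `r` and time `t` from a set of
#' trails, assuming the fields of individual trails simply superimpose.
#' Each trail is resampled to spacing `<= fp$ds_max` and summed by the
#' midpoint rule: segment `j` of length `ds` emitted at time `t'` contributes
#' `q*ds / (4*pi*D*(t - t' + t_off)) * exp(-|r - r'|^2 / (4*D*(t - t' + t_off)))`
#' in 2D (3D uses the 3D Gaussian kernel).  Segments older than `fp$T_mem` or
#' farther than `fp$R_max` are skipped.
#'
#' @param r Query position: numeric vector of length 2 or 3 (um).
#' @param t Query time (s).  Only samples emitted strictly before `t`
#'   contribute.
#' @param trails A list of [trail_record()]s, or a single trajectory-style
#'   data frame with a `droplet_id` column (split by droplet).
#' @param fp [field_params()].
#' @return A list with elements `c` (concentration) and `grad`
#'   (its spatial gradient, 1/um per component).
#' @export
field_superposition <- function(r, t, trails, fp = field_params()) {
  dim <- length(r)
  stopifnot(dim %in% c(2L, 3L))
  trails <- as_trail_list(trails)
  ctot <- 0
  gtot <- numeric(dim)
  for (tr in trails) {
    if (nrow(tr) < 2L) next
    tr <- resample_trail(tr, fp$ds_max)
    # midpoint-rule segments
    n <- nrow(tr)
    mx <- (tr$x[-1L] + tr$x[-n]) / 2
    my <- (tr$y[-1L] + tr$y[-n]) / 2
    mt <- (tr$t[-1L] + tr$t[-n]) / 2
    ds <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
    if (dim == 3L) {
      mz <- (tr$z[-1L] + tr$z[-n]) / 2
      ds <- sqrt(diff(tr$x)^2 + diff(tr$y)^2 + diff(tr$z)^2)
    }
    age <- t - mt
    dx <- r[1L] - mx
    dy <- r[2L] - my
    s2 <- dx^2 + dy^2
    if (dim == 3L) {
      dz <- r[3L] - mz
      s2 <- s2 + dz^2
    }
    keep <- age > 0 & age <= fp$T_mem & s2 <= fp$R_max^2 & ds > 0
    if (!any(keep)) next
    inv <- 1 / (4 * fp$D * (age[keep] + fp$t_off))
    pref <- if (dim == 3L) (inv / pi)^1.5 else inv / pi
    w <- fp$q * ds[keep] * pref * exp(-pmin(s2[keep] * inv, 700))
    ctot <- ctot + sum(w)
    gtot[1L] <- gtot[1L] - sum(2 * inv * w * dx[keep])
    gtot[2L] <- gtot[2L] - sum(2 * inv * w * dy[keep])
    if (dim == 3L) gtot[3L] <- gtot[3L] - sum(2 * inv * w * dz[keep])
  }
  list(c = ctot, grad = gtot)
}
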