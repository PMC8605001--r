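## Laser deposition profile and time-profile families.
##
## The volumetric source separates as Q_L(z, t) = f1(z) * f2(t): a
## double-exponential axial deposition profile (diffuse-reflectance fit) times
## a normalized time profile with max f2 = 1.  Discontinuous profiles are
## mollified with linear ramps of half-width eps so dQ_L/dt exists everywhere.

#' Diffuse-reflectance fit constants for the axial fluence profile
#'
#' Double-exponential fluence-rate fit phi/phi0 = O1 exp(-e1 z/delta) -
#' O2 exp(-e2 z/delta) with coefficients that are functions of the diffuse
#' reflectance Rd (Gardner-Jacques-Welch broad-beam fit).
#'
#' @param Rd diffuse reflectance, in [0, 1)
#' @return list with `O1`, `O2`, `e1`, `e2`
#' @export
gardner_fit <- function(Rd) {
  if (Rd < 0 || Rd >= 1) stop("diffuse reflectance Rd must lie in [0, 1)")
  list(
    O1 = 3.09 + 5.44 * Rd - 2.12 * exp(-21.5 * Rd),
    O2 = 2.09 - 1.47 * Rd - 2.12 * exp(-20.7 * Rd),
    e1 = 1 - (1 - 1 / sqrt(3)) * exp(-20.1 * Rd),
    e2 = 1.63 * exp(3.4 * Rd)
  )
}

#' Laser optical parameter set
#'
#' @param intensity incident laser intensity I0 (W/m2)
#' @param absorption absorption coefficient mu_a (1/m)
#' @param scattering scattering coefficient mu_s (1/m)
#' @param anisotropy scattering anisotropy factor g
#' @param diffuse_reflectance diffuse reflectance Rd
#' @param O1,O2,e1,e2 axial-profile fit constants; `NULL` (default) evaluates
#'   the [gardner_fit()] expressions at `diffuse_reflectance`; direct numeric
#'   overrides are always honoured
#' @return object of class `laser_optics`
#' @export
laser_optics <- function(intensity = 3e5, absorption = 18,
                         scattering = 8000, anisotropy = 0.9,
                         diffuse_reflectance = 0.05,
                         O1 = NULL, O2 = NULL, e1 = NULL, e2 = NULL) {
  if (intensity < 0) stop("laser intensity must be >= 0")
  if (absorption <= 0) stop("absorption coefficient mu_a must be > 0")
  if (scattering < 0) stop("scattering coefficient mu_s must be >= 0")
  fit <- gardner_fit(diffuse_reflectance)
  opt <- structure(list(
    intensity = intensity, absorption = absorption,
    scattering = scattering, anisotropy = anisotropy,
    diffuse_reflectance = diffuse_reflectance,
    O1 = if (is.null(O1)) fit$O1 else O1,
    O2 = if (is.null(O2)) fit$O2 else O2,
    e1 = if (is.null(e1)) fit$e1 else e1,
    e2 = if (is.null(e2)) fit$e2 else e2
  ), class = "laser_optics")
  if (opt$e1 <= 0 || opt$e2 <= 0) stop("axial decay constants e1, e2 must be > 0")
  opt
}

#' Axial deposition profile f1(z-hat)
#'
#' f1(z) = I0 mu_a (O1 exp(-e1 z) - O2 exp(-e2 z)), with z in units of the
#' penetration depth delta.
#'
#' @param z nondimensional depth(s), >= 0
#' @param optics a [laser_optics()]
#' @return volumetric deposition (W/m3), same length as `z`
#' @export
axial_profile <- function(z, optics) {
  stopifnot(inherits(optics, "laser_optics"))
  if (any(z < 0)) stop("depth z must be >= 0")
  optics$intensity * optics$absorption *
    (optics$O1 * exp(-optics$e1 * z) - optics$O2 * exp(-optics$e2 * z))
}

## ---- time profiles --------------------------------------------------------

profile_families <- c("single_pulse", "repetitive_pulse", "stairs_cooling",
                      "stairs_heating", "stairs_symmetric", "step",
                      "repetitive_ramp", "harmonic")

#' Laser time profile
#'
#' Builds one of the six supported time-profile families, normalized so that
#' max f2 = 1 and 0 <= f2 <= 1.  All times are nondimensional (units of the
#' characteristic time t*).  Discontinuities are replaced by linear ramps of
#' half-width `epsilon` (centered on the nominal switch time, clipped at 0) so
#' that the time derivative needed by the Cattaneo-Vernotte source term exists
#' everywhere; `epsilon = NULL` defaults to 1e-3 of the shortest protocol
#' feature.
#'
#' Family parameters:
#' \describe{
#'   \item{single_pulse}{`step_time` (pulse duration), optional `onset`}
#'   \item{repetitive_pulse}{`period`, `width`}
#'   \item{stairs_cooling / stairs_heating / stairs_symmetric}{`n_stairs`,
#'     `dwell` (per-stair hold of the staircase leg); the symmetric layout
#'     shortens its holds so all three deliver equal energy}
#'   \item{step}{none (switches on at t = 0)}
#'   \item{repetitive_ramp}{`repeat_time` (sawtooth rise time)}
#'   \item{harmonic}{`omega_r` (frequency ratio); f2 = (1 - cos(omega_r t))/2,
#'     smooth, handled analytically}
#' }
#'
#' @param family one of `r paste(profile_families, collapse=", ")`
#' @param step_time,onset,period,width,n_stairs,dwell,repeat_time,omega_r
#'   family parameters, see Details
#' @param epsilon mollification half-width (nondim time), > 0
#' @param t_max horizon up to which periodic families are compiled
#' @return object of class `time_profile`
#' @export
time_profile <- function(family, step_time = 0.2, onset = 0, period = 0.1,
                         width = 0.05, n_stairs = 3, dwell = 0.05,
                         repeat_time = 0.1, omega_r = 2 * pi,
                         epsilon = NULL, t_max = 2) {
  family <- match.arg(family, profile_families)
  if (family == "harmonic") {
    if (omega_r <= 0) stop("frequency ratio omega_r must be > 0")
    eps <- if (is.null(epsilon)) 1e-3 * 2 * pi / omega_r else epsilon
    return(structure(list(family = family, omega_r = omega_r,
                          epsilon = eps, t_max = t_max, period = 2 * pi / omega_r),
                     class = "time_profile"))
  }
  feature <- switch(family,
    single_pulse = step_time,
    repetitive_pulse = { if (period <= 0 || width <= 0) stop("period and width must be > 0")
                         if (width >= period) stop("pulse width must be smaller than the period")
                         width },
    stairs_cooling = , stairs_heating = , stairs_symmetric = {
      if (n_stairs < 1) stop("need at least one stair")
      dwell * (n_stairs + 1) / (2 * n_stairs) },
    step = 0.05,
    repetitive_ramp = { if (repeat_time <= 0) stop("repeat time must be > 0")
                        repeat_time }
  )
  if (feature <= 0) stop("protocol feature times must be > 0")
  eps <- if (is.null(epsilon)) 1e-3 * feature else epsilon
  if (eps <= 0) stop("mollification half-width epsilon must be > 0")

  knots <- switch(family,
    single_pulse = pl_switches(c(onset, onset + step_time), c(0, 1, 0), eps),
    step = pl_switches(0, c(0, 1), eps),
    repetitive_pulse = {
      n <- max(1L, ceiling(t_max / period) + 1L)
      on <- (seq_len(n) - 1L) * period
      pl_switches(as.vector(rbind(on, on + width)), c(0, rep(c(1, 0), n)), eps)
    },
    stairs_cooling = {
      lv <- c(1, rev(seq_len(n_stairs) - 1) / n_stairs)          # 1, ..., 1/n, 0
      pl_switches(seq(0, by = dwell, length.out = n_stairs + 1), c(0, lv), eps)
    },
    stairs_heating = {
      lv <- c(seq_len(n_stairs) / n_stairs, 0)                   # 1/n, ..., 1, 0
      pl_switches(seq(0, by = dwell, length.out = n_stairs + 1), c(0, lv), eps)
    },
    stairs_symmetric = {
      # equal-energy hold: up and down legs with hold t_u = dwell (n+1)/(2n)
      tu <- dwell * (n_stairs + 1) / (2 * n_stairs)
      lv <- c(seq_len(n_stairs) / n_stairs,
              rev(seq_len(n_stairs - 1)) / n_stairs, 0)
      pl_switches(seq(0, by = tu, length.out = 2 * n_stairs), c(0, lv), eps)
    },
    repetitive_ramp = {
      n <- max(1L, ceiling(t_max / repeat_time) + 1L)
      tt <- 0; vv <- 0
      for (k in seq_len(n)) {
        t0 <- (k - 1) * repeat_time
        # rise to 1 just before the drop, fall back to 0 over 2 eps
        tt <- c(tt, t0 + repeat_time - eps, t0 + repeat_time + eps)
        vv <- c(vv, 1, 0)
      }
      list(t = tt, v = vv)
    }
  )
  structure(list(family = family, epsilon = eps, t_max = t_max,
                 knots_t = knots$t, knots_v = knots$v,
                 period = switch(family, repetitive_pulse = period,
                                 repetitive_ramp = repeat_time, NULL),
                 params = list(step_time = step_time, onset = onset,
                               period = period, width = width,
                               n_stairs = n_stairs, dwell = dwell,
                               repeat_time = repeat_time)),
            class = "time_profile")
}

# Piecewise-linear knot sequence for ideal switches at `times` between
# successive `levels` (length(times) + 1), each switch ramped over
# [t0 - eps, t0 + eps] clipped at zero.  Centered ramps preserve the ideal
# delivered energy exactly away from t = 0.
pl_switches <- function(times, levels, eps) {
  t <- 0; v <- levels[1]
  for (i in seq_along(times)) {
    a <- max(times[i] - eps, if (i == 1) 0 else t[length(t)])
    b <- times[i] + eps
    if (b <= a) stop("mollification ramps overlap; decrease epsilon")
    t <- c(t, a, b); v <- c(v, levels[i], levels[i + 1])
  }
  keep <- !duplicated(t)
  list(t = t[keep], v = v[keep])
}

#' Evaluate a time profile and its derivative
#'
#' @param profile a [time_profile()]
#' @param t nondimensional time(s), >= 0
#' @return list with vectors `f2` and `df2` (derivative w.r.t. nondim time)
#' @export
profile_eval <- function(profile, t) {
  stopifnot(inherits(profile, "time_profile"))
  if (any(t < 0)) stop("time must be >= 0")
  if (profile$family == "harmonic") {
    w <- profile$omega_r
    return(list(f2 = (1 - cos(w * t)) / 2, df2 = w * sin(w * t) / 2))
  }
  kt <- profile$knots_t; kv <- profile$knots_v
  # beyond the last knot the profile holds its final level
  i <- findInterval(t, kt, all.inside = TRUE)
  slope <- (kv[i + 1] - kv[i]) / (kt[i + 1] - kt[i])
  f2 <- kv[i] + slope * (t - kt[i])
  past <- t >= kt[length(kt)]
  f2[past] <- kv[length(kv)]
  slope[past] <- 0
  list(f2 = pmin(pmax(f2, 0), 1), df2 = slope)
}

#' Delivered (time-integrated) profile energy
#'
#' Exact trapezoidal integral of the compiled piecewise-linear profile over
#' `[0, t_end]`; for the harmonic family the closed form is used.
#'
#' @param profile a [time_profile()]
#' @param t_end end of the integration window (nondim time)
#' @return integral of f2 over `[0, t_end]`
#' @export
profile_energy <- function(profile, t_end) {
  if (profile$family == "harmonic") {
    w <- profile$omega_r
    return(t_end / 2 - sin(w * t_end) / (2 * w))
  }
  kt <- profile$knots_t; kv <- profile$knots_v
  tt <- sort(unique(c(kt[kt < t_end], t_end)))
  vv <- profile_eval(profile, tt)$f2
  sum(diff(tt) * (head(vv, -1) + tail(vv, -1)) / 2)
}

#' Volumetric source and its time derivative
#'
#' Q_L(z, t) = f1(z) f2(t); dQ_L/dt = f1(z) df2/dt.
#'
#' @param z nondimensional depth(s)
#' @param t nondimensional time (scalar)
#' @param optics a [laser_optics()]
#' @param profile a [time_profile()]
#' @return list with `QL` and `dQL` (W/m3 and W/m3 per nondim time)
#' @export
source_eval <- function(z, t, optics, profile) {
  f1 <- axial_profile(z, optics)
  f2 <- profile_eval(profile, t)
  list(QL = f1 * f2$f2, dQL = f1 * f2$df2)
}
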