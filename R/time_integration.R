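## Time integration of the reduced system.
##
## The 3-DOF second-order system M x'' + C x' + K x = P(t) is converted to
## first-order form by mass-matrix inversion and integrated with a
## stiff-capable adaptive method (deSolve::lsoda) from homogeneous initial
## conditions.  The elastic wave frequencies exceed the thermal rates by many
## orders of magnitude, so a constant analytic Jacobian is supplied and BDF
## steps damp the (adiabatically unexcited) fast modes; the maximum step is
## capped by the source mollification half-width so ramps are resolved.

#' Integrate the reduced system
#'
#' @param system a [assemble_reduced_system()] result
#' @param t_end nondimensional end time, > 0
#' @param rtol,atol relative/absolute solver tolerances
#' @param max_step maximum nondimensional step within a smooth forcing
#'   segment; `NULL` defaults to `t_end/50`.  Mollification ramps are always
#'   resolved regardless: integration restarts at every profile corner, so
#'   steps never cross a ramp
#' @param n_out number of equally spaced output points (profile knots are
#'   added so plateaus and corners are represented exactly)
#' @param method deSolve integrator; `NULL` picks `"radau"` (L-stable, robust
#'   against the practically undamped megahertz-scale elastic modes) when the
#'   thermoelastic coupling is on and `"lsoda"` otherwise
#' @return object of class `rom_trajectory`: data frame with columns `t`,
#'   `t_seconds`, `q11`, `p11`, `s11`, `dq11`, `dp11`, `ds11` plus solver
#'   metadata attributes
#' @export
integrate_system <- function(system, t_end, rtol = 1e-6, atol = 1e-9,
                             max_step = NULL, n_out = 2001, method = NULL) {
  stopifnot(inherits(system, "reduced_system"))
  if (t_end <= 0) stop("t_end must be > 0")
  if (is.null(method)) method <- if (system$coupling) "radau" else "lsoda"
  # ramps are resolved structurally: every mollification corner bounds a
  # segment below, so inside a ramp the step never exceeds its width
  hmax <- if (is.null(max_step)) t_end / 50 else max_step

  Minv <- solve(system$M)
  A21 <- -Minv %*% system$K
  A22 <- -Minv %*% system$C
  forcing <- system$forcing
  jac <- rbind(cbind(matrix(0, 3, 3), diag(3)), cbind(A21, A22))

  rhs <- function(t, y, parms) {
    x <- y[1:3]; v <- y[4:6]
    list(c(v, A21 %*% x + A22 %*% v + Minv %*% forcing(t)))
  }
  knots <- knot_times(system$profile, t_end)
  times <- sort(unique(c(seq(0, t_end, length.out = n_out), knots, t_end)))
  # integrate segment-by-segment between profile corners: the forcing is
  # smooth (piecewise linear or harmonic) inside a segment, and restarting at
  # each corner resolves the mollification ramps without a global step cap
  bounds <- sort(unique(c(0, knots, t_end)))
  bounds <- bounds[bounds <= t_end]
  sol_rows <- list()
  y0 <- rep(0, 6)
  for (k in seq_len(length(bounds) - 1)) {
    a <- bounds[k]; b <- bounds[k + 1]
    seg_t <- unique(c(a, times[times > a & times < b], b))
    seg_h <- min(hmax, b - a)
    seg <- deSolve::ode(y = y0, times = seg_t, func = rhs, parms = NULL,
                        method = method, rtol = rtol, atol = atol,
                        hmax = seg_h, hini = seg_h / 4, maxsteps = 20000,
                        jacfunc = function(t, y, p) jac, jactype = "fullusr")
    if (any(!is.finite(seg[, -1]))) {
      bad <- seg_t[which(!stats::complete.cases(seg[, -1]))[1]]
      stop("integration failed near t-hat = ", bad,
           "; try tighter tolerances or a larger mollification half-width")
    }
    y0 <- as.numeric(seg[nrow(seg), -1])
    sol_rows[[k]] <- if (k == 1) seg else seg[-1, , drop = FALSE]
  }
  sol <- do.call(rbind, sol_rows)
  attr_diag <- attributes(sol_rows[[length(sol_rows)]])
  out <- data.frame(t = sol[, 1], t_seconds = sol[, 1] * system$groups$tstar,
                    q11 = sol[, 2], p11 = sol[, 3], s11 = sol[, 4],
                    dq11 = sol[, 5], dp11 = sol[, 6], ds11 = sol[, 7])
  structure(out, class = c("rom_trajectory", "data.frame"),
            system = system, rtol = rtol, atol = atol, hmax = hmax,
            method = method, istate = attr_diag$istate)
}

# Profile knot/corner times within [0, t_end] (for output grids).
knot_times <- function(profile, t_end) {
  if (profile$family == "harmonic") {
    k <- seq(0, t_end, by = pi / (2 * profile$omega_r))
  } else {
    k <- profile$knots_t
  }
  k[k <= t_end]
}

#' Interpolate a trajectory at arbitrary times
#'
#' Cubic-spline interpolation of the stored dense output.
#'
#' @param traj a [integrate_system()] trajectory
#' @param t nondimensional time(s) within the trajectory span
#' @param column state column to interpolate (default `"s11"`)
#' @return interpolated values
#' @export
trajectory_at <- function(traj, t, column = "s11") {
  stopifnot(inherits(traj, "rom_trajectory"))
  if (any(t < min(traj$t) - 1e-12) || any(t > max(traj$t) + 1e-12)) {
    stop("requested time outside the integrated span")
  }
  stats::spline(traj$t, traj[[column]], xout = t, method = "natural")$y
}
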