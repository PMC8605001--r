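## Field reconstruction and summary metrics.

#' Reconstruct physical fields from a trajectory
#'
#' Evaluates the one-mode expansions at the requested grid and time:
#' u = Y(r) (F(z) q + d1 F*(z) p), v = R(r) (H(z) p + H*(z) (d2 q + d3 s)),
#' theta = I(r) L(z) s, and converts to dimensional temperature (degrees C)
#' and displacements (m, scaled by the penetration depth).
#'
#' @param traj a [integrate_system()] trajectory
#' @param r,z nondimensional coordinate vectors (a full grid is formed)
#' @param t nondimensional time (scalar, within the trajectory span)
#' @return data frame (long format) with columns `r`, `z`, `theta`, `T_C`,
#'   `u`, `v` (nondim) and `u_m`, `v_m` (m); attribute `t` carries the time
#' @export
reconstruct_fields <- function(traj, r, z, t) {
  stopifnot(inherits(traj, "rom_trajectory"))
  system <- attr(traj, "system")
  bc <- system$bc
  q <- trajectory_at(traj, t, "q11")
  p <- trajectory_at(traj, t, "p11")
  s <- trajectory_at(traj, t, "s11")
  grid <- expand.grid(r = r, z = z)
  Yr <- shape_eval("Y", 1, grid$r)$v
  Rr <- shape_eval("R", 1, grid$r)$v
  Ir <- shape_eval("I", 1, grid$r)$v
  Fz <- shape_eval("F", 1, grid$z)$v
  Fsz <- shape_eval("Fs", 1, grid$z)$v
  Lz <- shape_eval("L", 1, grid$z)$v
  u <- Yr * (Fz * q + bc$d1 * Fsz * p)
  v <- Rr * (Fz * p + Fsz * (bc$d2 * q + bc$d3 * s))
  theta <- Ir * Lz * s
  T0 <- system$groups$T0
  out <- data.frame(grid, theta = theta,
                    T_C = T0 * (1 + theta) - CELSIUS_OFFSET,
                    u = u, v = v,
                    u_m = u * system$groups$delta,
                    v_m = v * system$groups$delta)
  attr(out, "t") <- t
  out
}

#' Probe-point temperature time series
#'
#' Temperature (degrees C) at a fixed probe point, by default the beam axis on
#' the surface (r, z) = (0, 0) where theta = s11.
#'
#' @param traj a [integrate_system()] trajectory
#' @param r,z nondimensional probe coordinates
#' @return data frame with `t`, `t_seconds`, `theta`, `T_C`
#' @export
probe_series <- function(traj, r = 0, z = 0) {
  system <- attr(traj, "system")
  w <- shape_eval("I", 1, r)$v * shape_eval("L", 1, z)$v
  theta <- w * traj$s11
  data.frame(t = traj$t, t_seconds = traj$t_seconds, theta = theta,
             T_C = system$groups$T0 * (1 + theta) - CELSIUS_OFFSET)
}

#' Summary metrics of a run
#'
#' Maximum probe temperature and its time, first-overshoot magnitude relative
#' to the final value, and (for periodic sources with at least three full
#' periods integrated) the steady oscillation amplitude, measured as half the
#' peak-to-trough range over the last three periods.
#'
#' @param traj a [integrate_system()] trajectory
#' @param r,z nondimensional probe coordinates
#' @return list with `max_T_C`, `peak_time`, `peak_time_seconds`,
#'   `overshoot`, `osc_amplitude` (`NA` when unavailable)
#' @export
summarize_run <- function(traj, r = 0, z = 0) {
  ps <- probe_series(traj, r, z)
  imax <- which.max(ps$T_C)
  final <- ps$theta[nrow(ps)]
  overshoot <- max(0, max(ps$theta) - final)
  period <- attr(traj, "system")$profile$period
  osc <- NA_real_
  if (!is.null(period) && max(ps$t) >= 3 * period) {
    tail3 <- ps$theta[ps$t >= max(ps$t) - 3 * period]
    osc <- (max(tail3) - min(tail3)) / 2
  }
  list(max_T_C = ps$T_C[imax], peak_time = ps$t[imax],
       peak_time_seconds = ps$t_seconds[imax],
       overshoot = overshoot, osc_amplitude = osc)
}
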