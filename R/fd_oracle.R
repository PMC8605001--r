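## Independent axisymmetric finite-difference solver for the UNCOUPLED
## hyperbolic bioheat equation, used to verify the Galerkin reduction and the
## tau -> 0 (Pennes) limit.  Deliberately simple: second-order central
## differences, explicit time stepping, no thermoelastic coupling.
##
## Nondimensional equations solved on [0, rmax] x [0, zmax]:
##   hyperbolic: theta_tt + N2 theta_t = N7 Lap(theta) - N4 (theta - theta_b)
##                                        + N5 Q + N6 dQ/dt
##   parabolic (Pennes limit): theta_t = Lap(theta) + w (theta_b - theta) + s5 Q
## with w = N4 tau/t*, s5 = N5 tau/t* (both tau-free products), axis symmetry
## at r = 0, homogeneous Neumann at z = 0 (matching the adiabatic-surface
## condition) and homogeneous Dirichlet at the far truncation boundaries.

#' Finite-difference grid specification
#'
#' @param rmax,zmax truncation radii (nondimensional); the far boundaries
#'   carry homogeneous Dirichlet conditions mirroring the decay at infinity
#' @param nr,nz node counts (including both boundaries)
#' @param dt time step; `NULL` picks a stable default from the CFL bound
#'   (hyperbolic) or the diffusion bound (parabolic)
#' @return object of class `fd_grid`
#' @export
fd_grid <- function(rmax = 12, zmax = 12, nr = 121, nz = 121, dt = NULL) {
  if (rmax <= 0 || zmax <= 0 || nr < 5 || nz < 5) stop("invalid grid")
  structure(list(rmax = rmax, zmax = zmax, nr = nr, nz = nz,
                 hr = rmax / (nr - 1), hz = zmax / (nz - 1), dt = dt),
            class = "fd_grid")
}

#' Finite-difference solution of the uncoupled bioheat equation
#'
#' @param grid a [fd_grid()]
#' @param groups a [nondim_groups()]
#' @param optics a [laser_optics()]
#' @param profile a [time_profile()]
#' @param t_end nondimensional end time
#' @param mode `"hyperbolic"` (Cattaneo-Vernotte) or `"parabolic"` (Pennes
#'   limit: second time derivative and relaxation-scaled terms removed)
#' @param radial_weight optional vectorized function of the nondimensional
#'   radius multiplying the source (default `NULL`: radially uniform
#'   deposition, the form used by the reduced model's projection).  Useful for
#'   apportioning reduced-model error between the axial dynamics and the
#'   fixed radial mode shape (see the methods vignette)
#' @return list with `times`, `surface_theta` (theta at r = z = 0), `field`
#'   (final theta matrix nr x nz), `r`, `z`, `mode`, `dt`
#' @export
fd_solve <- function(grid, groups, optics, profile, t_end,
                     mode = c("hyperbolic", "parabolic"),
                     radial_weight = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "fd_grid"), inherits(groups, "nondim_groups"))
  hr <- grid$hr; hz <- grid$hz
  nr <- grid$nr; nz <- grid$nz
  r <- seq(0, grid$rmax, length.out = nr)
  z <- seq(0, grid$zmax, length.out = nz)
  N2 <- groups$N2; N4 <- groups$N4; N5 <- groups$N5
  N6 <- groups$N6; N7 <- groups$N7
  tb <- groups$theta_b
  ratio <- groups$tau / groups$tstar     # tau-free when multiplied into N4, N5
  w_perf <- N4 * ratio
  s5 <- N5 * ratio
  eps <- profile$epsilon

  dt <- grid$dt
  if (is.null(dt)) {
    dt <- if (mode == "hyperbolic") {
      min(0.4 * min(hr, hz) / sqrt(2 * N7), eps / 2, 1 / (2 * N2))
    } else {
      min(0.2 * min(hr, hz)^2, eps / 2)
    }
  }
  nsteps <- max(2L, ceiling(t_end / dt))
  dt <- t_end / nsteps

  f1 <- axial_profile(z, optics)            # depth profile, uniform in r
  f1row <- matrix(f1, nr, nz, byrow = TRUE)
  if (!is.null(radial_weight)) f1row <- f1row * radial_weight(r)

  # 5-point axisymmetric Laplacian with axis limit and ghost symmetry at z=0
  lap <- function(th) {
    L <- matrix(0, nr, nz)
    ii <- 2:(nr - 1); jj <- 2:(nz - 1)
    L[ii, ] <- (th[ii + 1, ] - 2 * th[ii, ] + th[ii - 1, ]) / hr^2 +
      (th[ii + 1, ] - th[ii - 1, ]) / (2 * hr * r[ii])
    L[1, ] <- 4 * (th[2, ] - th[1, ]) / hr^2          # (1/r) d/dr -> d2/dr2 at axis
    Lz <- matrix(0, nr, nz)
    Lz[, jj] <- (th[, jj + 1] - 2 * th[, jj] + th[, jj - 1]) / hz^2
    Lz[, 1] <- 2 * (th[, 2] - th[, 1]) / hz^2          # Neumann ghost at z = 0
    L <- L + Lz
    L[nr, ] <- 0; L[, nz] <- 0                         # Dirichlet boundaries
    L
  }

  th <- matrix(0, nr, nz)
  times <- (0:nsteps) * dt
  surface <- numeric(nsteps + 1)
  blow <- function(x, t) {
    if (!all(is.finite(x)) || max(abs(x)) > 1e6) {
      stop("finite-difference solution blew up at t-hat = ", signif(t, 4),
           "; reduce dt (CFL bound ~ h/sqrt(2 N7) for the hyperbolic mode, ",
           "h^2/4 for the parabolic mode)")
    }
  }

  if (mode == "parabolic") {
    for (n in seq_len(nsteps)) {
      f2 <- profile_eval(profile, times[n])$f2
      th <- th + dt * (lap(th) + w_perf * (tb - th) + s5 * f1row * f2)
      th[nr, ] <- 0; th[, nz] <- 0
      blow(th, times[n + 1])
      surface[n + 1] <- th[1, 1]
    }
  } else {
    a <- 1 / dt^2 + N2 / (2 * dt)
    thm <- th
    # first step from rest: theta(dt) = dt^2/2 * theta_tt(0)
    s0 <- profile_eval(profile, 0)
    acc0 <- N7 * lap(th) - N4 * (th - tb) + f1row * (N5 * s0$f2 + N6 * s0$df2)
    th1 <- th + dt^2 / 2 * acc0
    th1[nr, ] <- 0; th1[, nz] <- 0
    surface[2] <- th1[1, 1]
    thm <- th; th <- th1
    for (n in 2:nsteps) {
      tn <- times[n]
      s <- profile_eval(profile, tn)
      rhs <- N7 * lap(th) - N4 * (th - tb) + f1row * (N5 * s$f2 + N6 * s$df2)
      thn <- (rhs + (2 * th - thm) / dt^2 + N2 * thm / (2 * dt)) / a
      thn[nr, ] <- 0; thn[, nz] <- 0
      blow(thn, tn)
      thm <- th; th <- thn
      surface[n + 1] <- th[1, 1]
    }
  }
  list(times = times, surface_theta = surface, field = th, r = r, z = z,
       mode = mode, dt = dt)
}
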