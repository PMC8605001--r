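## Galerkin reduced-order model.
##
## The coupled nondimensional PDEs (radial displacement u, depth displacement
## v, temperature theta) are projected onto one-term separable shape functions
##
##   u(r,z,t)     = Y(r) [F(z) q(t) + A F*(z) q(t)]
##   v(r,z,t)     = R(r) [H(z) p(t) + B H*(z) p(t)]
##   theta(r,z,t) = I(r) L(z) s(t)
##
## with Y = J1(r), R = cos(pi r) exp(-r^2), I = exp(-r^2), F = H = L =
## exp(-z^2), F* = H* = z exp(-z).  The time-dependent ratios A and B are
## eliminated heuristically through the projected free-surface traction
## conditions, A q = d1 p and B p = d2 q + d3 s, substituted algebraically
## before time differentiation so the reduced system keeps constant
## coefficients.  Every reduced coefficient is defined operationally as the
## corresponding Galerkin quadrature of the residuals; separability makes each
## one a product of a radial and an axial one-dimensional integral.
##
## The radial integrals involving only Bessel products have no decaying factor
## and are only defined on the truncated domain: all radial quadratures run
## over [0, R_trunc] with R_trunc the J1 zero nearest Rmax (ending at a zero
## minimizes the truncation bias of the oscillatory tail).

#' Evaluate a shape function and its first two derivatives
#'
#' Families: `"Y"` J1(i r); `"R"` cos(i pi r) exp(-i r^2); `"I"` exp(-i r^2);
#' `"F"`, `"H"`, `"L"` exp(-i z^2); `"Fs"`, `"Hs"` z exp(-i z).  Derivatives
#' are analytic (Bessel recurrences, product rules).
#'
#' @param family one of "Y", "R", "I", "F", "Fs", "H", "Hs", "L"
#' @param index mode index i >= 1
#' @param x nondimensional coordinate(s), >= 0
#' @return list with vectors `v`, `d1`, `d2`
#' @export
shape_eval <- function(family, index = 1, x) {
  if (index < 1) stop("shape-function index must be >= 1")
  if (any(x < 0)) stop("shape functions are defined on x >= 0")
  i <- index
  switch(family,
    Y = {
      u <- i * x
      v <- besselJ(u, 1)
      d1 <- i * (besselJ(u, 0) - besselJ(u, 2)) / 2
      # J1''(x) = -J1(x) + J2(x)/x, with series J1'' ~ -3x/8 near 0
      d2 <- i^2 * ifelse(u < 1e-6, -3 * u / 8, -v + besselJ(u, 2) / pmax(u, .Machine$double.xmin))
      list(v = v, d1 = d1, d2 = d2)
    },
    R = {
      a <- i
      e <- exp(-a * x^2); cs <- cos(a * pi * x); sn <- sin(a * pi * x)
      list(v = cs * e,
           d1 = e * (-a * pi * sn - 2 * a * x * cs),
           d2 = e * (4 * a^2 * pi * x * sn + (4 * a^2 * x^2 - a^2 * pi^2 - 2 * a) * cs))
    },
    I = , F = , H = , L = {
      e <- exp(-i * x^2)
      list(v = e, d1 = -2 * i * x * e, d2 = (4 * i^2 * x^2 - 2 * i) * e)
    },
    Fs = , Hs = {
      e <- exp(-i * x)
      list(v = x * e, d1 = (1 - i * x) * e, d2 = (i^2 * x - 2 * i) * e)
    },
    stop("unknown shape-function family: ", family)
  )
}

# Singularity-free radial operator combinations (series limits at r = 0):
#  bessel_op:  Y'' + Y'/r - Y/r^2 = -i^2 J1(i r)   (Bessel equation)
#  div_op Y:   Y' + Y/r = i J0(i r)                (Bessel recurrence)
radial_ops <- list(
  bessel_Y = function(r, i = 1) -i^2 * besselJ(i * r, 1),
  div_Y = function(r, i = 1) i * besselJ(i * r, 0),
  lap_R = function(r, i = 1) {  # R'' + R'/r, finite limit -i^2 pi^2 - 4 i at 0
    s <- shape_eval("R", i, r)
    rp_over_r <- ifelse(r < 1e-6, -i^2 * pi^2 - 2 * i, s$d1 / pmax(r, .Machine$double.xmin))
    s$d2 + rp_over_r
  },
  lap_I = function(r, i = 1) (4 * i^2 * r^2 - 4 * i) * exp(-i * r^2)  # I'' + I'/r
)

# First positive zeros of J1 (bracketing table up to ~ r = 20)
j1_zeros <- c(3.8317059702, 7.0155866698, 10.1734681351, 13.3236919363,
              16.4706300509, 19.6158585105)

#' One-dimensional Galerkin quadrature
#'
#' Adaptive quadrature (QUADPACK through [stats::integrate()]) with an error
#' check: a failed or non-convergent estimate aborts with diagnostics.
#'
#' @param f vectorized integrand
#' @param lower,upper integration limits
#' @param tol relative tolerance
#' @return integral value
#' @export
galerkin_quad <- function(f, lower, upper, tol = 1e-9) {
  res <- stats::integrate(f, lower, upper, rel.tol = tol,
                          abs.tol = tol, subdivisions = 500L, stop.on.error = FALSE)
  if (!res$message %in% "OK") {
    stop("quadrature did not converge on [", lower, ", ", upper, "]: ", res$message)
  }
  scale <- max(abs(res$value), 1)
  if (res$abs.error > 1e3 * tol * scale) {
    stop("quadrature tail estimate ", res$abs.error, " above tolerance for [",
         lower, ", ", upper, "]")
  }
  res$value
}

# Quadrature/truncation settings shared by assembly and the BC solve.
rom_settings <- function(rmax = 12, zmax = 12, tol = 1e-9) {
  r_trunc <- j1_zeros[which.min(abs(j1_zeros - rmax))]
  list(rmax = rmax, zmax = zmax, r_trunc = r_trunc, tol = tol)
}

# All elementary radial and axial integrals of the one-mode basis.
rom_integrals <- function(settings = rom_settings()) {
  tol <- settings$tol; Rt <- settings$r_trunc; Zt <- settings$zmax
  qr <- function(f) galerkin_quad(f, 0, Rt, tol)
  qz <- function(f) galerkin_quad(f, 0, Zt, tol)
  Y <- function(r) shape_eval("Y", 1, r)$v
  Rf <- function(r) shape_eval("R", 1, r)$v
  Rp <- function(r) shape_eval("R", 1, r)$d1
  If <- function(r) shape_eval("I", 1, r)$v
  Ip <- function(r) shape_eval("I", 1, r)$d1
  F0 <- function(z) shape_eval("F", 1, z)$v
  Fpp <- function(z) shape_eval("F", 1, z)$d2
  Fp <- function(z) shape_eval("F", 1, z)$d1
  Fs <- function(z) shape_eval("Fs", 1, z)$v
  Fsp <- function(z) shape_eval("Fs", 1, z)$d1
  Fspp <- function(z) shape_eval("Fs", 1, z)$d2
  # H and L coincide with F, H* with F*, for the one-mode basis, but are kept
  # as distinct entries named by the residual term they come from
  list(
    # radial, weight Y (u-equation)
    YY = qr(function(r) Y(r)^2),
    YbY = qr(function(r) radial_ops$bessel_Y(r) * Y(r)),
    RpY = qr(function(r) Rp(r) * Y(r)),
    IpY = qr(function(r) Ip(r) * Y(r)),
    # radial, weight R (v-equation and normal-traction projection)
    RR = qr(function(r) Rf(r)^2),
    RopR = qr(function(r) radial_ops$lap_R(r) * Rf(r)),
    J0R = qr(function(r) radial_ops$div_Y(r) * Rf(r)),
    IR = qr(function(r) If(r) * Rf(r)),
    # radial, weight I (theta-equation)
    II = qr(function(r) If(r)^2),
    IopI = qr(function(r) radial_ops$lap_I(r) * If(r)),
    J0I = qr(function(r) radial_ops$div_Y(r) * If(r)),
    RI = qr(function(r) Rf(r) * If(r)),
    Ione = qr(If),
    # axial, weight F
    FF = qz(function(z) F0(z)^2),
    FsF = qz(function(z) Fs(z) * F0(z)),
    FppF = qz(function(z) Fpp(z) * F0(z)),
    FsppF = qz(function(z) Fspp(z) * F0(z)),
    HpF = qz(function(z) Fp(z) * F0(z)),
    HspF = qz(function(z) Fsp(z) * F0(z)),
    LF = qz(function(z) F0(z)^2),
    # axial, weight H (= F)
    HH = qz(function(z) F0(z)^2),
    HsH = qz(function(z) Fs(z) * F0(z)),
    HppH = qz(function(z) Fpp(z) * F0(z)),
    HsppH = qz(function(z) Fspp(z) * F0(z)),
    FpH = qz(function(z) Fp(z) * F0(z)),
    FspH = qz(function(z) Fsp(z) * F0(z)),
    LpH = qz(function(z) Fp(z) * F0(z)),
    # axial, weight L (= F)
    LL = qz(function(z) F0(z)^2),
    LppL = qz(function(z) Fpp(z) * F0(z)),
    FL = qz(function(z) F0(z)^2),
    FsL = qz(function(z) Fs(z) * F0(z)),
    HpL = qz(function(z) Fp(z) * F0(z)),
    HspL = qz(function(z) Fsp(z) * F0(z)),
    Lone = qz(F0),
    # boundary traces used by the traction elimination
    F_0 = 1, Fp_0 = 0, Fsp_0 = 1, H_0 = 1, Hp_0 = 0, Hs_0 = 0, Hsp_0 = 1, L_0 = 1
  )
}

#' Traction boundary-condition elimination parameters
#'
#' Projects the free-surface shear and normal stress residuals onto the radial
#' weights and solves for the elimination constants d1, d2, d3 of the
#' time-dependent ratios A = d1 p/q and B = (d2 q + d3 s)/p.  With these, the
#' projected traction residuals vanish identically.
#'
#' @param groups a [nondim_groups()]
#' @param settings quadrature settings from `rom_settings()` (internal)
#' @param integrals optionally precomputed `rom_integrals()`
#' @param coupling logical; `FALSE` removes the thermal-stress term from the
#'   normal traction condition (d3 = 0)
#' @return list with `d1`, `d2`, `d3` and the raw projected coefficients
#' @export
bc_parameters <- function(groups, settings = rom_settings(),
                          integrals = NULL, coupling = TRUE) {
  stopifnot(inherits(groups, "nondim_groups"))
  ig <- if (is.null(integrals)) rom_integrals(settings) else integrals
  M6 <- groups$M6
  M7 <- if (coupling) groups$M7 else 0
  # shear:   K10 (Fp_0 q + Fsp_0 A q) + E10 (H_0 p + Hs_0 B p) = 0
  # normal:  K13 F_0 q + M6 RR (Hp_0 p + Hsp_0 B p) - M7 IR L_0 s = 0
  K10 <- ig$YY; E10 <- ig$RpY; K13 <- ig$J0R
  den1 <- K10 * ig$Fsp_0
  den2 <- M6 * ig$RR * ig$Hsp_0
  if (abs(den1) < .Machine$double.eps) stop("vanishing shear-projection denominator (YY * F*'(0))")
  if (abs(den2) < .Machine$double.eps) stop("vanishing normal-projection denominator (M6 * RR * H*'(0))")
  list(
    d1 = -(E10 * ig$H_0 + K10 * ig$Fp_0) / den1,
    d2 = -(K13 * ig$F_0 + M6 * ig$RR * ig$Hp_0) / den2,
    d3 = M7 * ig$IR * ig$L_0 / den2,
    raw = list(K10 = K10, E10 = E10, K13 = K13,
               E13 = M6 * ig$RR, F9 = M7 * ig$IR)
  )
}

#' Assemble the reduced three degree-of-freedom system
#'
#' Builds the 3x3 mass, damping and stiffness matrices and the forcing vector
#' of the reduced system M x'' + C x' + K x = P(t) for x = (q, p, s), by
#' Galerkin projection of the three volume residuals with the traction
#' elimination constants substituted before time differentiation.  The
#' temperature row carries all the forcing: perfusion offset P1 = N4 theta_b
#' (projection of 1), source P2(t) and source-rate P3(t).
#'
#' @param groups a [nondim_groups()]
#' @param optics a [laser_optics()]
#' @param profile a [time_profile()]
#' @param coupling logical; `FALSE` disables the thermoelastic coupling
#'   (thermal-stress groups M5, M7 and strain-rate feedback groups N1, N3 set
#'   to zero), decoupling the temperature row from the mechanical rows
#' @param settings quadrature settings from `rom_settings()`
#' @return object of class `reduced_system`
#' @export
assemble_reduced_system <- function(groups, optics, profile, coupling = TRUE,
                                    settings = rom_settings()) {
  stopifnot(inherits(groups, "nondim_groups"), inherits(optics, "laser_optics"),
            inherits(profile, "time_profile"))
  ig <- rom_integrals(settings)
  M1 <- groups$M1; M2 <- groups$M2; M3 <- groups$M3; M4 <- groups$M4
  M5 <- if (coupling) groups$M5 else 0
  N1 <- if (coupling) groups$N1 else 0
  N3 <- if (coupling) groups$N3 else 0
  N2 <- groups$N2; N4 <- groups$N4; N5 <- groups$N5; N6 <- groups$N6
  N7 <- groups$N7
  bc <- bc_parameters(groups, settings, integrals = ig, coupling = coupling)
  d1 <- bc$d1; d2 <- bc$d2; d3 <- bc$d3

  # row 1: u-residual, weight Y(r) F(z)
  Mq1 <- ig$YY * ig$FF
  Mp1 <- d1 * ig$YY * ig$FsF
  Cq1 <- -M1 * ig$YY * ig$FF
  Cp1 <- -M1 * d1 * ig$YY * ig$FsF
  Kq1 <- -M2 * ig$YbY * ig$FF - M3 * ig$YY * ig$FppF - M4 * d2 * ig$RpY * ig$HspF
  Kp1 <- -M2 * d1 * ig$YbY * ig$FsF - M3 * d1 * ig$YY * ig$FsppF -
    M4 * ig$RpY * ig$HpF
  Ks1 <- -M4 * d3 * ig$RpY * ig$HspF + M5 * ig$IpY * ig$LF

  # row 2: v-residual, weight R(r) H(z)
  Mq2 <- d2 * ig$RR * ig$HsH
  Mp2 <- ig$RR * ig$HH
  Ms2 <- d3 * ig$RR * ig$HsH
  Cq2 <- -M1 * d2 * ig$RR * ig$HsH
  Cp2 <- -M1 * ig$RR * ig$HH
  Cs2 <- -M1 * d3 * ig$RR * ig$HsH
  Kq2 <- -M2 * d2 * ig$RR * ig$HsppH - M3 * d2 * ig$RopR * ig$HsH -
    M4 * ig$J0R * ig$FpH
  Kp2 <- -M2 * ig$RR * ig$HppH - M3 * ig$RopR * ig$HH -
    M4 * d1 * ig$J0R * ig$FspH
  Ks2 <- -M2 * d3 * ig$RR * ig$HsppH - M3 * d3 * ig$RopR * ig$HsH +
    M5 * ig$IR * ig$LpH

  # row 3: theta-residual, weight I(r) L(z)
  Ms3 <- ig$II * ig$LL + N1 * d3 * ig$RI * ig$HspL
  Mq3 <- N1 * (ig$J0I * ig$FL + d2 * ig$RI * ig$HspL)
  Mp3 <- N1 * (d1 * ig$J0I * ig$FsL + ig$RI * ig$HpL)
  Cs3 <- N2 * ig$II * ig$LL + N3 * d3 * ig$RI * ig$HspL
  Cq3 <- N3 * (ig$J0I * ig$FL + d2 * ig$RI * ig$HspL)
  Cp3 <- N3 * (d1 * ig$J0I * ig$FsL + ig$RI * ig$HpL)
  Ks3 <- -N7 * (ig$IopI * ig$LL + ig$II * ig$LppL) + N4 * ig$II * ig$LL

  M <- rbind(c(Mq1, Mp1, 0),
             c(Mq2, Mp2, Ms2),
             c(Mq3, Mp3, Ms3))
  C <- rbind(c(Cq1, Cp1, 0),
             c(Cq2, Cp2, Cs2),
             c(Cq3, Cp3, Cs3))
  K <- rbind(c(Kq1, Kp1, Ks1),
             c(Kq2, Kp2, Ks2),
             c(0, 0, Ks3))
  dimnames(M) <- dimnames(C) <- dimnames(K) <-
    list(c("q", "p", "s"), c("q", "p", "s"))
  if (abs(det(M)) < .Machine$double.xmin) stop("assembled mass matrix is singular")

  # forcing: source projection is separable, f1L = int f1(z) L(z) dz
  f1L <- galerkin_quad(function(z) axial_profile(z, optics) *
                         shape_eval("L", 1, z)$v, 0, settings$zmax, settings$tol)
  P1 <- N4 * groups$theta_b * ig$Ione * ig$Lone
  amp <- ig$Ione * f1L
  forcing <- function(t) {
    f2 <- profile_eval(profile, t)
    c(0, 0, P1 + N5 * amp * f2$f2 + N6 * amp * f2$df2)
  }

  structure(list(
    M = M, C = C, K = K, forcing = forcing,
    bc = bc, integrals = ig, groups = groups, optics = optics,
    profile = profile, coupling = coupling, settings = settings,
    f1L = f1L, P1 = P1, source_amp = amp
  ), class = "reduced_system")
}
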