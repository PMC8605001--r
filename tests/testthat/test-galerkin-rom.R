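test_that("shape functions and their analytic derivatives are correct", {
  # hand values
  expect_equal(shape_eval("Y", 1, 0)$v, 0)
  expect_equal(shape_eval("R", 1, 0)$d1, 0)
  expect_equal(shape_eval("I", 1, 0)$d1, 0)
  expect_equal(shape_eval("L", 1, 0)$d1, 0)
  fs <- shape_eval("Fs", 1, 1)
  expect_equal(fs$v, exp(-1), tolerance = 1e-14)
  expect_equal(fs$d1, 0, tolerance = 1e-14)      # (1 - z) e^-z at z = 1
  # z-families decay at large argument
  for (fam in c("F", "Fs", "H", "Hs", "L")) {
    expect_lt(abs(shape_eval(fam, 1, 15)$v), 1e-5)
  }
  expect_error(shape_eval("bogus", 1, 1), "unknown")

  # central-difference cross-check of d1 and d2 for every family
  x <- seq(0.05, 4, length.out = 40)
  h <- 1e-5
  for (fam in c("Y", "R", "I", "F", "Fs", "H", "Hs", "L")) {
    for (idx in 1:2) {
      s <- shape_eval(fam, idx, x)
      d1_num <- (shape_eval(fam, idx, x + h)$v - shape_eval(fam, idx, x - h)$v) / (2 * h)
      d2_num <- (shape_eval(fam, idx, x + h)$v - 2 * s$v +
                   shape_eval(fam, idx, x - h)$v) / h^2
      expect_equal(s$d1, d1_num, tolerance = 1e-7)
      expect_equal(s$d2, d2_num, tolerance = 1e-4)
    }
  }
})

test_that("quadrature reproduces closed-form Gaussian integrals", {
  expect_equal(galerkin_quad(function(r) exp(-2 * r^2), 0, 12), gauss_int,
               tolerance = 1e-10)
  expect_equal(galerkin_quad(function(r) r^2 * exp(-2 * r^2), 0, 12),
               gauss_x2_int, tolerance = 1e-10)
  # int_0^inf exp(-k z - z^2) dz against the erfc closed form
  for (k in c(0.5, 1, 2)) {
    expect_equal(galerkin_quad(function(z) exp(-k * z - z^2), 0, 12),
                 exp_gauss_int(k), tolerance = 1e-10)
  }
})

test_that("Gaussian-decay coefficients are insensitive to doubling the truncation radius", {
  g <- default_groups()
  s1 <- thermoskin:::rom_settings(rmax = 12, zmax = 12)
  s2 <- thermoskin:::rom_settings(rmax = 12, zmax = 24)
  i1 <- thermoskin:::rom_integrals(s1)
  i2 <- thermoskin:::rom_integrals(s2)
  for (k in c("RR", "II", "IR", "IopI", "J0I", "FF", "FsF", "LL", "Lone")) {
    expect_equal(i1[[k]], i2[[k]], tolerance = 1e-8, label = k)
  }
})

test_that("assembly is invariant to quadrature refinement beyond the defaults", {
  g <- default_groups()
  op <- laser_optics()
  pr <- time_profile("step")
  s_tight <- assemble_reduced_system(g, op, pr, settings =
                                       thermoskin:::rom_settings(tol = 1e-11))
  s_def <- assemble_reduced_system(g, op, pr)
  for (m in c("M", "C", "K")) {
    drift <- abs(s_tight[[m]] - s_def[[m]]) / pmax(abs(s_def[[m]]), 1e-12)
    expect_lt(max(drift[s_def[[m]] != 0]), 1e-6)
  }
})

test_that("traction elimination makes the projected surface residuals vanish", {
  g <- default_groups()
  bc <- bc_parameters(g)
  set.seed(1)
  Rt <- thermoskin:::rom_settings()$r_trunc
  for (i in 1:5) {
    x <- stats::rnorm(3)  # arbitrary generalized coordinates (q, p, s)
    q <- x[1]; p <- x[2]; s <- x[3]
    # shear residual at z = 0 with A q -> d1 p substituted
    shear <- function(r) {
      (shape_eval("Y", 1, r)$v * bc$d1 * p +           # F'(0)=0, F*'(0)=1
         shape_eval("R", 1, r)$d1 * p) *               # H(0)=1, H*(0)=0
        shape_eval("Y", 1, r)$v
    }
    # normal residual at z = 0 with B p -> d2 q + d3 s substituted
    normal <- function(r) {
      y <- shape_eval("Y", 1, r)
      j0 <- besselJ(r, 0)
      ((j0 * q) +                                      # (Y' + Y/r) F(0) q
         g$M6 * shape_eval("R", 1, r)$v * (bc$d2 * q + bc$d3 * s) -
         g$M7 * shape_eval("I", 1, r)$v * s) *
        shape_eval("R", 1, r)$v
    }
    scale <- max(abs(x))
    expect_lt(abs(galerkin_quad(shear, 0, Rt, tol = 1e-9)), 1e-8 * scale)
    expect_lt(abs(galerkin_quad(normal, 0, Rt, tol = 1e-9)), 1e-8 * scale)
  }
})

test_that("thermal-stress terms drive d3: it vanishes without coupling", {
  g <- default_groups()
  expect_equal(bc_parameters(g, coupling = FALSE)$d3, 0)
  expect_gt(abs(bc_parameters(g, coupling = TRUE)$d3), 0)
})

test_that("assembled coefficients match independent closed-form evaluation", {
  g <- default_groups()
  op <- laser_optics()
  sys <- assemble_reduced_system(g, op, time_profile("step"), coupling = FALSE)
  LL <- gauss_int
  II <- gauss_int
  IopI <- 4 * gauss_x2_int - 4 * gauss_int
  LppL <- 4 * gauss_x2_int - 2 * gauss_int
  expect_equal(sys$M["s", "s"], II * LL, tolerance = 1e-9)
  expect_equal(sys$C["s", "s"], g$N2 * II * LL, tolerance = 1e-9)
  expect_equal(sys$K["s", "s"],
               -g$N7 * (IopI * LL + II * LppL) + g$N4 * II * LL,
               tolerance = 1e-9)
  expect_equal(sys$M["p", "p"],
               sqrt(pi / 8) / 2 * (1 + exp(-pi^2 / 2)) * gauss_int,
               tolerance = 1e-9)
  # source projection against the erfc closed form
  f1L <- op$intensity * op$absorption *
    (op$O1 * exp_gauss_int(op$e1) - op$O2 * exp_gauss_int(op$e2))
  expect_equal(sys$f1L, f1L, tolerance = 1e-9)
})

test_that("disabling the coupling decouples the temperature row", {
  g <- default_groups()
  op <- laser_optics()
  sys <- assemble_reduced_system(g, op, time_profile("step"), coupling = FALSE)
  expect_equal(sys$M["s", c("q", "p")], c(q = 0, p = 0))
  expect_equal(sys$C["s", c("q", "p")], c(q = 0, p = 0))
  expect_equal(sys$K["s", c("q", "p")], c(q = 0, p = 0))
  expect_equal(sys$K[c("q", "p"), "s"], c(q = 0, p = 0))
  # structural layout: no s entries in the q-row mass/damping, forcing only in
  # the temperature row
  sys_c <- assemble_reduced_system(g, op, time_profile("step"), coupling = TRUE)
  expect_equal(sys_c$M["q", "s"], 0)
  expect_equal(sys_c$C["q", "s"], 0)
  expect_equal(sys_c$K["s", c("q", "p")], c(q = 0, p = 0))
  f <- sys_c$forcing(0.05)
  expect_equal(f[1:2], c(0, 0))
  expect_gt(f[3], 0)
})

test_that("zero source and zero arterial offset give identically zero forcing", {
  g <- default_groups()
  op0 <- laser_optics(intensity = 0)
  sys <- assemble_reduced_system(g, op0, time_profile("step"))
  for (t in c(0, 0.01, 0.2)) expect_equal(sys$forcing(t), c(0, 0, 0))
})
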