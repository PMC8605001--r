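test_that("axial profile limits: surface value, deep decay, cancellation", {
  op <- laser_optics()
  expect_equal(axial_profile(0, op),
               op$intensity * op$absorption * (op$O1 - op$O2), tolerance = 1e-12)
  expect_lt(abs(axial_profile(40, op)), 1e-8 * axial_profile(0, op))
  op0 <- laser_optics(O1 = 1.5, O2 = 1.5, e1 = 2, e2 = 2)
  expect_equal(axial_profile(c(0, 0.5, 3), op0), c(0, 0, 0))
  expect_error(axial_profile(-1, op), ">= 0")
})

test_that("every profile family is normalized to [0, 1] with unit maximum", {
  profs <- list(
    time_profile("single_pulse", step_time = 0.2),
    time_profile("repetitive_pulse", period = 0.1, width = 0.05, t_max = 1),
    time_profile("stairs_cooling", n_stairs = 3, dwell = 0.05),
    time_profile("stairs_heating", n_stairs = 3, dwell = 0.05),
    time_profile("stairs_symmetric", n_stairs = 3, dwell = 0.05),
    time_profile("step"),
    time_profile("repetitive_ramp", repeat_time = 0.1, t_max = 1),
    time_profile("harmonic", omega_r = 2 * pi))
  for (p in profs) {
    extremes <- if (p$family == "harmonic") {
      seq(pi / p$omega_r, 0.9, by = 2 * pi / p$omega_r)  # exact peak times
    } else p$knots_t
    grid <- sort(unique(c(seq(0, 0.9, length.out = 4001), extremes)))
    grid <- grid[grid <= 0.9]
    f2 <- profile_eval(p, grid)$f2
    expect_equal(max(f2), 1, tolerance = 1e-12, label = p$family)
    expect_gte(min(f2), 0)
  }
})

test_that("returned derivative matches central differences away from ramp corners", {
  profs <- list(
    time_profile("single_pulse", step_time = 0.2, epsilon = 1e-3),
    time_profile("repetitive_ramp", repeat_time = 0.1, epsilon = 1e-3, t_max = 1),
    time_profile("harmonic", omega_r = 4 * pi))
  set.seed(7)
  for (p in profs) {
    tpts <- runif(200, 0.01, 0.45)
    if (!is.null(p$knots_t)) {
      # stay clear of corners by 3 eps
      keep <- vapply(tpts, function(t) min(abs(t - p$knots_t)) > 3 * p$epsilon, TRUE)
      tpts <- tpts[keep]
    }
    h <- p$epsilon / 10
    num <- (profile_eval(p, tpts + h)$f2 - profile_eval(p, tpts - h)$f2) / (2 * h)
    ana <- profile_eval(p, tpts)$df2
    expect_true(all(abs(num - ana) <= 0.01 * max(1, abs(ana)) + 1e-10),
                label = p$family)
  }
})

test_that("plateau and off-states behave as ideal switches", {
  eps <- 1e-3
  st <- time_profile("step", epsilon = eps)
  v <- profile_eval(st, 10 * eps)
  expect_equal(v$f2, 1)
  expect_equal(v$df2, 0)
  sp <- time_profile("single_pulse", step_time = 0.2, epsilon = eps)
  expect_equal(profile_eval(sp, 0.2 + 10 * eps)$f2, 0)
  expect_equal(profile_eval(sp, 0.1)$df2, 0)  # mid-plateau
})

test_that("stair layouts deliver equal energy and the pulse integral is f1 * width", {
  eps <- 5e-4
  e_heat <- profile_energy(time_profile("stairs_heating", n_stairs = 3,
                                        dwell = 0.05, epsilon = eps), 0.4)
  e_cool <- profile_energy(time_profile("stairs_cooling", n_stairs = 3,
                                        dwell = 0.05, epsilon = eps), 0.4)
  e_symm <- profile_energy(time_profile("stairs_symmetric", n_stairs = 3,
                                        dwell = 0.05, epsilon = eps), 0.4)
  expect_equal(e_heat, e_cool, tolerance = 2 * eps / e_heat)
  expect_equal(e_heat, e_symm, tolerance = 2 * eps / e_heat)
  # one repetitive-pulse period integrates to the pulse width (up to eps terms)
  rp <- time_profile("repetitive_pulse", period = 0.1, width = 0.05,
                     epsilon = eps, t_max = 1)
  expect_equal(profile_energy(rp, 0.1), 0.05, tolerance = 2 * eps / 0.05)
})

test_that("source evaluation is separable and vanishes with the profile", {
  op <- laser_optics()
  pr <- time_profile("single_pulse", step_time = 0.2, epsilon = 1e-3)
  z <- c(0, 0.5, 2)
  s <- source_eval(z, 0.1, op, pr)
  expect_equal(s$QL, axial_profile(z, op) * profile_eval(pr, 0.1)$f2)
  expect_equal(s$dQL, rep(0, 3))          # plateau
  s_off <- source_eval(z, 0.5, op, pr)
  expect_equal(s_off$QL, rep(0, 3))
  op_null <- laser_optics(intensity = 0)
  expect_equal(source_eval(z, 0.1, op_null, pr)$QL, rep(0, 3))
})

test_that("invalid profile parameters are rejected", {
  expect_error(time_profile("no_such_family"))
  expect_error(time_profile("repetitive_pulse", period = 0, width = 0.1), "period")
  expect_error(time_profile("repetitive_pulse", period = 0.1, width = 0.2), "width")
  expect_error(time_profile("harmonic", omega_r = -1), "omega_r")
  expect_error(profile_eval(time_profile("step"), -0.1), ">= 0")
})
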