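test_that("configuration validation reports every offending key at once", {
  expect_error(scenario_config(tissue = list(bogus_key = 1),
                               optics = list(another = 2)),
               "tissue\\$bogus_key.*optics\\$another")
  expect_error(scenario_config(nonblock = list()), "nonblock")
  expect_error(scenario_config(profile = list(time_units = "hours")),
               "time_units")
  cfg <- scenario_config(optics = list(intensity = 1e5))
  expect_s3_class(cfg, "scenario_config")
  expect_equal(cfg$optics$intensity, 1e5)
  expect_equal(cfg$tissue$density, 1000)   # untouched defaults survive
})

test_that("the bundled preset file reproduces the default parameter set", {
  path <- system.file("extdata", "skin_laser_preset.yaml",
                      package = "thermoskin")
  expect_true(nzchar(path))
  cfg <- read_scenario_config(path)
  expect_equal(cfg$tissue$density, 1000)
  expect_equal(cfg$tissue$specific_heat, 4187)
  expect_equal(cfg$tissue$conductivity, 0.628)
  expect_equal(cfg$tissue$youngs_modulus, 100e6)
  expect_equal(cfg$tissue$poisson, 0.4)
  expect_equal(cfg$tissue$relaxation_time, 3)
  expect_equal(cfg$blood$density, 1060)
  expect_equal(cfg$blood$specific_heat, 3860)
  expect_equal(cfg$blood$perfusion_rate, 1.87e-3)
  expect_equal(cfg$optics$intensity, 3e5)
  expect_equal(cfg$optics$diffuse_reflectance, 0.05)
  # recorded fit constants agree with the diffuse-reflectance expressions
  fit <- gardner_fit(0.05)
  expect_equal(cfg$optics$O1, fit$O1, tolerance = 1e-6)
  expect_equal(cfg$optics$O2, fit$O2, tolerance = 1e-6)
  expect_equal(cfg$optics$e1, fit$e1, tolerance = 1e-6)
  expect_equal(cfg$optics$e2, fit$e2, tolerance = 1e-6)
})

test_that("a zero-source run reports body temperature and writes a complete run directory", {
  out <- file.path(tempdir(), "thermoskin-null-run")
  unlink(out, recursive = TRUE)
  res <- run_scenario("null_source", out_dir = out)
  expect_equal(res$metrics$max_T_C, 37)
  for (f in c("trajectory.tsv", "metrics.txt", "log.txt", "config.yaml")) {
    expect_true(file.exists(file.path(out, f)), label = f)
  }
  log <- readLines(file.path(out, "log.txt"))
  for (key in c("lambda_Pa", "mu_Pa", "thermal_modulus_Pa_per_K", "alpha_m2_s",
                "delta_m", "tstar_s", "M2", "N7", "d1", "d2", "d3")) {
    expect_true(any(grepl(paste0("^", key, ":"), log)), label = key)
  }
  unlink(out, recursive = TRUE)
})

test_that("re-running a preset yields byte-identical trajectory files", {
  o1 <- file.path(tempdir(), "thermoskin-det-1")
  o2 <- file.path(tempdir(), "thermoskin-det-2")
  unlink(c(o1, o2), recursive = TRUE)
  cfg <- preset_config("fig8b_stairs")
  cfg$solver$t_end <- 0.25
  run_scenario(cfg, out_dir = o1)
  run_scenario(cfg, out_dir = o2)
  expect_identical(readLines(file.path(o1, "trajectory.tsv")),
                   readLines(file.path(o2, "trajectory.tsv")))
  unlink(c(o1, o2), recursive = TRUE)
})

test_that("snapshot output uses the long delimited format", {
  cfg <- preset_config("fig9_step")
  cfg$solver$t_end <- 0.2
  cfg$output$snapshot_times <- 0.1
  out <- file.path(tempdir(), "thermoskin-snap")
  unlink(out, recursive = TRUE)
  res <- run_scenario(cfg, out_dir = out)
  snap <- utils::read.table(file.path(out, "snapshot_001.tsv"), header = TRUE)
  expect_named(snap, c("r", "z", "theta", "T_C", "u", "v", "u_m", "v_m"))
  expect_equal(nrow(snap), length(cfg$output$grid_r) * length(cfg$output$grid_z))
  unlink(out, recursive = TRUE)
})

test_that("unknown presets are rejected", {
  expect_error(preset_config("fig99"), "unknown preset")
})
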