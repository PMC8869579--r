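# a fast small-grid configuration shared by the synthesis tests
synth_args <- function() {
  list(design = delay_line_design(), stack = reference_stack(),
       f_start = 20e6, f_stop = 40e6, n_points = 801)
}

test_that("noiseless synthesis equals the deterministic model", {
  a <- synth_args()
  sp_model <- delay_line_s21(
    a$design, reference_stack(top = water_material()),
    seq(a$f_start, a$f_stop, length.out = a$n_points))
  sp_synth <- synth_spectrum(a$design, a$stack, water_material(),
                             f_start = a$f_start, f_stop = a$f_stop,
                             n_points = a$n_points, noise_sigma = 0,
                             feedthrough_db = -Inf, r_tt = 0)
  expect_equal(sp_synth$s21, sp_model$s21, tolerance = 1e-12)
})

test_that("synthesis is reproducible under a fixed seed", {
  a <- synth_args()
  s1 <- synth_spectrum(a$design, a$stack, water_material(),
                       f_start = a$f_start, f_stop = a$f_stop,
                       n_points = a$n_points, noise_sigma = 1e-4, seed = 11)
  s2 <- synth_spectrum(a$design, a$stack, water_material(),
                       f_start = a$f_start, f_stop = a$f_stop,
                       n_points = a$n_points, noise_sigma = 1e-4, seed = 11)
  s3 <- synth_spectrum(a$design, a$stack, water_material(),
                       f_start = a$f_start, f_stop = a$f_stop,
                       n_points = a$n_points, noise_sigma = 1e-4, seed = 12)
  expect_identical(s1$s21, s2$s21)
  expect_false(identical(s1$s21, s3$s21))
})

test_that("the synthetic echo lands at three times the transit delay", {
  # air-loaded guide (lowest propagation loss keeps the echo visible)
  a <- synth_args()
  sp0 <- synth_spectrum(a$design, a$stack, vacuum_medium("air"),
                        f_start = 10e6, f_stop = 50e6, n_points = 2001,
                        r_tt = 0)
  sp3 <- synth_spectrum(a$design, a$stack, vacuum_medium("air"),
                        f_start = 10e6, f_stop = 50e6, n_points = 2001,
                        r_tt = 0.3)
  h0 <- impulse_response(sp0, band_taper = 0.5)
  h3 <- impulse_response(sp3, band_taper = 0.5)
  t_main <- h0$time_s[which.max(abs(h0$amplitude))]
  extra <- abs(h3$amplitude) - abs(h0$amplitude)
  t_echo <- h3$time_s[which.max(extra)]
  # the echo travels the path twice more; the guide is dispersive, so the
  # extra delay is 2 L / v_group with v_group inside the guide's velocity
  # bracket (slowest layer to substrate shear velocity)
  extra_delay <- t_echo - t_main
  L <- a$design$delay_path
  expect_gt(extra_delay, 2 * L / sqrt(86.3e9 / 4650))
  expect_lt(extra_delay, 2 * L / sqrt(1.21e9 / 1100))
  # and a gate around the main transit removes the echo energy
  g <- time_gate(sp3, gate_window(0.2e-6, t_main + 1e-6),
                 compensate = FALSE)
  hg <- impulse_response(g, band_taper = 0.5)
  expect_lt(abs(hg$amplitude[which.min(abs(hg$time_s - t_echo))]),
            0.05 * max(abs(extra)))
})

test_that("series follow the liquid schedule", {
  a <- synth_args()
  # single liquid: constant series up to noise
  sched1 <- liquid_schedule(0, list(water_material()))
  ser1 <- synth_series(a$design, a$stack, sched1, duration = 40,
                       sample_interval = 10, f_start = a$f_start,
                       f_stop = a$f_stop, n_points = a$n_points,
                       noise_sigma = 0, seed = 3)
  il1 <- vapply(ser1$spectrum,
                function(s) extract_min_il(s, c(26e6, 34e6))$il_db, numeric(1))
  expect_equal(diff(il1), rep(0, length(il1) - 1), tolerance = 1e-12)

  # air -> water step: both readouts step negative, then recover to air
  sched2 <- liquid_schedule(c(0, 100, 300),
                            list("air", water_material(), "air"))
  ser2 <- synth_series(a$design, a$stack, sched2, duration = 500,
                       sample_interval = 20, tau_mix = 0.1,
                       f_start = a$f_start, f_stop = a$f_stop,
                       n_points = a$n_points, noise_sigma = 0, seed = 3)
  sg <- build_sensorgram(ser2, f0 = 30e6, band = c(26e6, 34e6))
  air1 <- sg$time_s < 100
  wet <- sg$time_s >= 120 & sg$time_s < 300
  air2 <- sg$time_s >= 320
  expect_lt(mean(sg$min_il_db[wet]), mean(sg$min_il_db[air1]))
  expect_lt(mean(sg$phase_deg[wet]), mean(sg$phase_deg[air1]))
  expect_equal(mean(sg$min_il_db[air2]), mean(sg$min_il_db[air1]),
               tolerance = 1e-9)

  # exponential mixing moves monotonically between plateaus
  ser3 <- synth_series(a$design, a$stack,
                       liquid_schedule(c(0, 50), list(
                         water_material(), glycerol_solution(viscosity_cp = 4))),
                       duration = 200, sample_interval = 10, tau_mix = 30,
                       f_start = a$f_start, f_stop = a$f_stop,
                       n_points = a$n_points, noise_sigma = 0, seed = 3)
  il3 <- vapply(ser3$spectrum,
                function(s) extract_min_il(s, c(26e6, 34e6))$il_db, numeric(1))
  expect_true(all(diff(il3[ser3$time_s >= 50]) <= 1e-9))
})

test_that("series survive a directory round trip", {
  a <- synth_args()
  ser <- synth_series(a$design, a$stack,
                      liquid_schedule(0, list(water_material())),
                      duration = 20, sample_interval = 10,
                      f_start = a$f_start, f_stop = a$f_stop,
                      n_points = 101, noise_sigma = 1e-4, seed = 5)
  dir <- withr::local_tempdir()
  write_series(ser, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_series(dir)
  expect_equal(back$time_s, ser$time_s)
  for (i in seq_len(nrow(ser))) {
    expect_lt(max(abs(back$spectrum[[i]]$s21 - ser$spectrum[[i]]$s21)) /
                max(abs(ser$spectrum[[i]]$s21)), 1e-12)
  }
})
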