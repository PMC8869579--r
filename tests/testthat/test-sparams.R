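# a smooth band-limited single-path test spectrum with transit delay tau
single_path_spectrum <- function(n = 1601, f1 = 10e6, f2 = 50e6,
                                 tau = 1.0e-6, level_db = -12,
                                 f0 = 30e6, width = 8e6) {
  f <- seq(f1, f2, length.out = n)
  x <- (f - f0) / width
  env <- undb20(level_db) * (ifelse(abs(x) < 1e-12, 1, sin(pi * x) / (pi * x)))^2
  two_port_spectrum(f, env * exp(-2i * pi * f * tau))
}

test_that("touchstone files round-trip in all three encodings", {
  sp <- single_path_spectrum(n = 31)
  for (fmt in c("RI", "MA", "DB")) {
    path <- withr::local_tempfile(fileext = ".s2p")
    write_touchstone(sp, path, format = fmt)
    back <- read_touchstone(path)
    expect_equal(back$frequency, sp$frequency, tolerance = 1e-12)
    expect_lt(max(abs(back$s21 - sp$s21)) / max(abs(sp$s21)), 1e-12)
  }

  # MA and RI encodings of the same spectrum parse identically
  p1 <- withr::local_tempfile(fileext = ".s2p")
  p2 <- withr::local_tempfile(fileext = ".s2p")
  write_touchstone(sp, p1, format = "MA")
  write_touchstone(sp, p2, format = "RI")
  expect_equal(read_touchstone(p1)$s21, read_touchstone(p2)$s21,
               tolerance = 1e-12)
})

test_that("touchstone parsing honors formats, units and errors", {
  # DB format: -12 dB at 0 degrees decodes to 10^(-12/20)
  path <- withr::local_tempfile(fileext = ".s2p")
  writeLines(c("! one-point fixture", "# MHz S DB R 50",
               "30 -3 0 -12 0 -12 0 -3 0"), path)
  sp <- read_touchstone(path)
  expect_equal(sp$frequency, 30e6)
  expect_equal(sp$s21, complex(real = 10^(-12 / 20)))
  expect_equal(attr(sp, "z0"), 50)

  # frequency-unit keywords are honored
  writeLines(c("# kHz S RI R 75", "1000 0 0 0.5 0 0.5 0 0 0"), path)
  spk <- read_touchstone(path)
  expect_equal(spk$frequency, 1e6)
  expect_equal(attr(spk, "z0"), 75)

  # malformed data section is rejected
  writeLines(c("# MHz S RI R 50", "30 1 2 3"), path)
  expect_error(read_touchstone(path), "9 values")
  writeLines(c("# MHz S RI R 50", "30 a b c d e f g h"), path)
  expect_error(read_touchstone(path), "non-numeric")
})

test_that("gating passes an in-window path and removes an out-of-window echo", {
  tau <- 1.0e-6
  win <- gate_window(0.2e-6, 1.9e-6)
  sp1 <- single_path_spectrum(tau = tau)

  # single path inside the window: mid-band level barely changes
  g1 <- time_gate(sp1, win)
  mid <- abs(sp1$frequency - 30e6) < 2e6
  expect_lt(max(abs(insertion_loss_db(g1)[mid] - insertion_loss_db(sp1)[mid])),
            0.5)

  # two-path response: echo at 3 tau (outside the window) makes ripple with
  # closed-form peak-to-peak 20 log10((1+r2)/(1-r2)); gating removes >= 90%
  r2 <- 0.09
  sp2 <- sp1
  sp2$s21 <- sp1$s21 * (1 + r2 * exp(-2i * pi * sp1$frequency * 2 * tau))
  ripple_pre <- insertion_loss_db(sp2)[mid] - insertion_loss_db(sp1)[mid]
  expect_equal(diff(range(ripple_pre)),
               20 * log10((1 + r2) / (1 - r2)), tolerance = 0.01)
  g2 <- time_gate(sp2, win)
  ripple_post <- insertion_loss_db(g2)[mid] - insertion_loss_db(g1)[mid]
  expect_lt(diff(range(ripple_post)), 0.1 * diff(range(ripple_pre)))

  # the gated two-path spectrum converges to the single-path one mid-band
  expect_lt(max(abs(insertion_loss_db(g2)[mid] - insertion_loss_db(sp1)[mid])),
            0.5)
})

test_that("gating is idempotent, linear, and passive in energy", {
  sp <- single_path_spectrum()
  sp$s21 <- sp$s21 * (1 + 0.09 * exp(-2i * pi * sp$frequency * 2e-6))
  win <- gate_window(0.2e-6, 1.9e-6)
  g1 <- time_gate(sp, win)
  g2 <- time_gate(g1, win)
  mid <- abs(sp$frequency - 30e6) < 2e6
  expect_lt(max(abs(insertion_loss_db(g2)[mid] - insertion_loss_db(g1)[mid])),
            0.1)

  # linearity in the input
  ga <- time_gate({
    spa <- sp; spa$s21 <- 3.7 * sp$s21; spa
  }, win)
  expect_equal(ga$s21, 3.7 * g1$s21, tolerance = 1e-12)

  # time-domain energy of the gated signal never exceeds the original
  e <- function(s) sum(Mod(impulse_response(s, band_taper = 0)$amplitude)^2)
  expect_lte(e(time_gate(sp, win, band_taper = 0, compensate = FALSE)), e(sp))

  # a vanishing window annihilates the signal
  tiny <- time_gate(sp, gate_window(1.0e-6, 1.0001e-6), compensate = FALSE)
  expect_lt(sum(Mod(tiny$s21)^2) / sum(Mod(sp$s21)^2), 1e-3)

  # a window beyond the resolvable span is rejected
  expect_error(time_gate(sp, gate_window(1, 2)), "resolvable")
})

test_that("minimum insertion loss extraction picks the right point", {
  sp <- single_path_spectrum(level_db = -12)
  m <- extract_min_il(sp)
  expect_equal(m$f_min_hz, 30e6, tolerance = 1e-6)
  expect_equal(m$il_db, -12, tolerance = 1e-9)

  # flat spectrum: documented tie-break toward the band start
  flat <- two_port_spectrum(seq(10e6, 50e6, length.out = 101),
                            rep(0.1 + 0i, 101))
  expect_equal(extract_min_il(flat, c(20e6, 40e6))$f_min_hz, 20e6)
  expect_error(extract_min_il(flat, c(60e6, 70e6)), "band")
})

test_that("sensorgrams track series and unwrap phase continuously", {
  sp <- single_path_spectrum()
  # constant series gives a constant sensorgram
  specs <- lapply(0:4, function(i) {
    s <- sp; attr(s, "time_s") <- i * 10; s
  })
  sg <- build_sensorgram(specs, f0 = 30e6)
  expect_equal(nrow(sg), 5)
  expect_equal(diff(sg$min_il_db), rep(0, 4))
  expect_equal(diff(sg$phase_deg), rep(0, 4))
  expect_equal(sg$time_s, seq(0, 40, by = 10))

  # a phase ramp crossing +/-180 degrees unwraps without jumps;
  # oracle: cumulative-difference unwrapping
  phases <- seq(0, -720, by = -40) * pi / 180
  specs2 <- lapply(seq_along(phases), function(i) {
    s <- sp
    s$s21 <- s$s21 * exp(1i * phases[i]) / exp(-2i * pi * s$frequency * 1e-6)
    attr(s, "time_s") <- i
    s
  })
  sg2 <- build_sensorgram(specs2, f0 = 30e6)
  wrapped <- ((phases * 180 / pi + 180) %% 360) - 180
  oracle <- wrapped
  for (i in 2:length(oracle)) {
    d <- oracle[i] - oracle[i - 1]
    oracle[i] <- oracle[i] - round(d / 360) * 360
    if (i < length(oracle)) {
      shift <- oracle[i] - wrapped[i]
      oracle[(i + 1):length(oracle)] <- wrapped[(i + 1):length(oracle)] + shift
    }
  }
  expect_equal(diff(sg2$phase_deg), diff(oracle), tolerance = 1e-6)
  expect_true(all(abs(diff(sg2$phase_deg) + 40) < 1e-6))

  # f0 outside the grid is rejected
  expect_error(build_sensorgram(specs, f0 = 90e6), "outside")
})

test_that("unwrap_phase matches the cumulative-difference oracle", {
  set.seed(7)
  true_phase <- cumsum(rnorm(200, sd = 0.8))
  wrapped <- ((true_phase + pi) %% (2 * pi)) - pi
  un <- unwrap_phase(wrapped)
  expect_equal(diff(un), diff(true_phase), tolerance = 1e-12)
})
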