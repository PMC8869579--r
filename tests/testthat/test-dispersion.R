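test_that("solver agrees with the classical two-layer dispersion relation", {
  # 50 randomized lossless two-layer guides vs the independent bisection
  # oracle for tan(q h) = mu_s s / (mu_l q)
  set.seed(101)
  f <- 30e6
  for (i in 1:50) {
    vl <- runif1(800, 3000)
    vs <- vl * runif1(1.3, 2.5)
    rho_l <- runif1(900, 3000)
    rho_s <- runif1(2000, 8000)
    q1 <- 2 * pi * f * sqrt(1 / vl^2 - 1 / vs^2)
    h <- runif1(0.1, 2.4) / q1
    mu_l <- rho_l * vl^2
    mu_s <- rho_s * vs^2
    v_oracle <- love_oracle_velocity(mu_s, rho_s, mu_l, rho_l, h, f)
    st <- layer_stack(rigid_solid("sub", rho_s, mu_s),
                      list(layer(rigid_solid("guide", rho_l, mu_l), h)))
    sol <- solve_dispersion(st, f)
    expect_equal(sol$phase_velocity, v_oracle, tolerance = 1e-6)
    expect_equal(sol$attenuation_db_per_m, 0, tolerance = 1e-6)
  }
})

test_that("lossy roots match an exact three-media characteristic equation", {
  # independent formulation: substrate half-space / one viscoelastic layer /
  # Newtonian liquid half-space, boundary conditions assembled directly and
  # solved by Newton iteration on the closed-form determinant
  omega <- 2 * pi * 30e6
  mu_s <- 86.3e9; rho_s <- 4650
  mu_l <- 1.21e9; rho_l <- 1100; eta_l <- 0.12
  rho_w <- 997; eta_w <- 0.893e-3
  h <- 8e-6
  mue_l <- mu_l + 1i * omega * eta_l
  mue_w <- 1i * omega * eta_w
  ks2 <- omega^2 * rho_s / mu_s
  kl2 <- omega^2 * rho_l / mue_l
  kw2 <- omega^2 * rho_w / mue_w
  charfn <- function(kx) {
    s_ <- sqrt(kx^2 - ks2); if (Re(s_) < 0) s_ <- -s_
    q <- sqrt(kl2 - kx^2)
    kyw <- sqrt(kw2 - kx^2); if (Im(kyw) > 0) kyw <- -kyw
    zeta <- -1i * kyw * mue_w
    cb <- mu_s * s_ / (mue_l * q)
    mue_l * q * (cb * cos(q * h) - sin(q * h)) -
      zeta * (cos(q * h) + cb * sin(q * h))
  }
  kx <- (omega / 4080) + 0i
  for (i in 1:60) {
    fv <- charfn(kx)
    df <- (charfn(kx + 1e-3) - charfn(kx - 1e-3)) / 2e-3
    kx <- kx - fv / df
  }
  st <- layer_stack(rigid_solid("LiNbO3", rho_s, mu_s),
                    list(layer(viscoelastic_solid("SU8", rho_l, mu_l, eta_l), h)),
                    newtonian_liquid("water", rho_w, eta_w))
  sol <- solve_dispersion(st, 30e6)
  expect_lt(abs(sol$k_x - kx) / abs(kx), 1e-8)
})

test_that("thin-layer limit approaches the substrate shear velocity", {
  st <- reference_stack(h_guiding = 5e-9, include_metal = FALSE,
                        guiding = load_material("SU8_elastic"))
  sol <- solve_dispersion(st, 30e6)
  v_sub <- sqrt(86.3e9 / 4650)
  expect_lt(sol$phase_velocity, v_sub)
  expect_equal(sol$phase_velocity, v_sub, tolerance = 1e-5)
  expect_equal(v_sub, 4307.9, tolerance = 1e-4)
})

test_that("the root is independent of the reference plane", {
  st <- reference_stack(top = water_material())
  sols <- lapply(0:3, function(p) solve_dispersion(st, 30e6, plane = p))
  kx0 <- sols[[1]]$k_x
  for (s in sols[-1]) {
    expect_lt(abs(s$k_x - kx0) / abs(kx0), 1e-8)
  }
})

test_that("passive stacks never show gain", {
  etas <- c(0.5e-3, 2e-3, 4e-3)
  fs <- c(20e6, 30e6, 45e6)
  for (eta in etas) {
    for (f in fs) {
      st <- reference_stack(top = newtonian_liquid("liq", 1050, eta))
      sol <- solve_dispersion(st, f)
      expect_gte(sol$attenuation_db_per_m, 0)
      expect_lt(sol$residual, 1e-8)
    }
  }
})

test_that("liquid loading strictly increases attenuation", {
  sol_vac <- solve_dispersion(reference_stack(), 30e6)
  sol_wat <- solve_dispersion(reference_stack(top = water_material()), 30e6)
  expect_gt(sol_wat$attenuation_db_per_m, sol_vac$attenuation_db_per_m)
})

test_that("sensitivity to layer thickness peaks in the design region", {
  # |dv/dz| around z = 0.05 must exceed the flat start of the curve at
  # z = 0.005 (the design rationale for an 8 um guide at 144 um wavelength)
  lam <- 144e-6
  dv_dz <- function(z, dz = 0.002) {
    vp <- function(zz) solve_dispersion(
      reference_stack(h_guiding = zz * lam), 30e6)$phase_velocity
    (vp(z + dz) - vp(z - dz)) / (2 * dz)
  }
  expect_gt(abs(dv_dz(0.05)), abs(dv_dz(0.005)))
})

test_that("tidiers expose the solution as tibbles", {
  sol <- solve_dispersion(reference_stack(top = water_material()), 30e6)
  td <- tidy(sol)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("substrate", "SU8", "water") %in% td$medium))
  # half-space fields decay away from the guide
  expect_gt(td$decay_length_m[td$medium == "water"], 0)
  gl <- glance(sol)
  expect_equal(nrow(gl), 1)
  expect_lt(gl$residual, 1e-8)
  expect_equal(gl$phase_velocity, 2 * pi * 30e6 / gl$k_x_re)
})

test_that("viscosity sweep is monotone and linear in path length", {
  st <- reference_stack()
  liq <- table3_liquids()
  sw <- viscosity_sweep(st, liq, f = 30e6, delay_path = 37 * 144e-6)
  expect_s3_class(sw, "lw_sweep")
  expect_named(sw, c("eta_cP", "rho_kgm3", "v_phase_mps", "alpha_dB_per_m",
                     "IL_dB", "phase_deg"))
  # loss magnitude non-decreasing with eta * rho; IL negative by convention
  expect_true(all(diff(-sw$IL_dB) > 0))
  expect_true(all(sw$IL_dB < 0))
  # phase shifts negative as viscosity rises
  expect_true(all(diff(sw$phase_deg) < 0))

  # doubling the path doubles propagation loss and phase
  sw2 <- viscosity_sweep(st, liq[1, ], f = 30e6, delay_path = 2 * 37 * 144e-6)
  expect_equal(sw2$IL_dB, 2 * sw$IL_dB[1], tolerance = 1e-10)
  expect_equal(sw2$phase_deg, 2 * sw$phase_deg[1], tolerance = 1e-10)

  # a vacuum "liquid" reproduces the unloaded baseline (zero liquid shift)
  sw_vac <- viscosity_sweep(st, list(vacuum_medium()), f = 30e6,
                            delay_path = 37 * 144e-6)
  sol_vac <- solve_dispersion(reference_stack(), 30e6)
  expect_equal(sw_vac$IL_dB, -sol_vac$attenuation_db_per_m * 37 * 144e-6,
               tolerance = 1e-10)
})

test_that("sweep sensitivity implements central differences", {
  sw <- tibble::tibble(eta_cP = c(1, 2, 3), IL_dB = c(-10, -13, -15),
                       phase_deg = c(0, -4, -6))
  s <- sensitivity(sw)
  expect_equal(s$dIL_dB_per_cP, c(-3, -2.5, -2))
  expect_equal(s$dphase_deg_per_cP, c(-4, -3, -2))
  expect_error(sensitivity(sw[1, ]), "two sweep points")
})

test_that("dispersion curve reports the normalized thickness", {
  dc <- dispersion_curve(z = c(0.04, 0.0556), f = 30e6, wavelength = 144e-6)
  expect_equal(dc$h_m, c(0.04, 0.0556) * 144e-6)
  # velocity falls with thickness in the rising-sensitivity region
  expect_lt(dc$phase_velocity[2], dc$phase_velocity[1])
})
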