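# Shared fixtures: device materials, calibration liquids, and an
# independent classical Love-wave oracle.

table3_liquids <- function() {
  data.frame(
    eta_cP = c(0.893, 1.8, 2.5, 3.3, 4),
    rho_kgm3 = c(997, 1058.2, 1082, 1100, 1111.4)
  )
}

water_material <- function() newtonian_liquid("water", 997, 0.893e-3)

# Independent oracle: classical two-layer Love dispersion relation
# tan(q h) = mu_s s / (mu_l q), q = sqrt(w^2/vl^2 - k^2),
# s = sqrt(k^2 - w^2/vs^2), fundamental branch, solved by bisection.
love_oracle_velocity <- function(mu_s, rho_s, mu_l, rho_l, h, f) {
  vs <- sqrt(mu_s / rho_s)
  vl <- sqrt(mu_l / rho_l)
  stopifnot(vl < vs)
  omega <- 2 * pi * f
  g <- function(v) {
    q <- omega * sqrt(1 / vl^2 - 1 / v^2)
    s <- omega * sqrt(1 / v^2 - 1 / vs^2)
    tan(q * h) - mu_s * s / (mu_l * q)
  }
  # fundamental root lies on the first tan branch, q h in (0, pi/2)
  q1 <- omega * sqrt(1 / vl^2 - 1 / vs^2)
  v_hi <- if (q1 * h < pi / 2 - 1e-9) {
    vs * (1 - 1e-12)
  } else {
    # velocity at which q h = pi/2 (tan pole); root is below it
    1 / sqrt(1 / vl^2 - (pi / (2 * h * omega))^2) * (1 - 1e-12)
  }
  uniroot(g, lower = vl * (1 + 1e-9), upper = v_hi,
          tol = .Machine$double.eps^0.9)$root
}

# small uniform helper for seeded random draws
runif1 <- function(lo, hi) lo + (hi - lo) * runif(1)
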