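# Independent numeric oracles used across the test files. These
# deliberately avoid the package's own solution paths: the radial BVP
# oracle discretizes and solves the ODE directly (Thomas algorithm),
# whereas the package uses the closed-form profile.

# Solve 1/r d/dr(r D dC/dr) = q0 on [Ro, Rk], C(Ro) = C_wall, C'(Rk) = 0,
# by second-order finite differences on n nodes.
bvp_radial_oracle <- function(C_wall, q0, D, Ro, Rk, n = 4001) {
  r <- seq(Ro, Rk, length.out = n)
  h <- r[2] - r[1]
  rp <- r + h / 2
  rm <- r - h / 2
  # tridiagonal: a_i C_{i-1} + b_i C_i + c_i C_{i+1} = d_i
  # last node is a half control volume (width h/2), hence the factor 2
  a <- c(0, rm[2:(n - 1)] / (r[2:(n - 1)] * h^2),
         2 * rm[n] / (r[n] * h^2))
  b <- c(1, -(rm[2:(n - 1)] + rp[2:(n - 1)]) / (r[2:(n - 1)] * h^2),
         -2 * rm[n] / (r[n] * h^2))
  cc <- c(0, rp[2:(n - 1)] / (r[2:(n - 1)] * h^2), 0)
  d <- c(C_wall, rep(q0 / D, n - 1))
  # Thomas algorithm
  for (i in 2:n) {
    w <- a[i] / b[i - 1]
    b[i] <- b[i] - w * cc[i - 1]
    d[i] <- d[i] - w * d[i - 1]
  }
  C <- numeric(n)
  C[n] <- d[n] / b[n]
  for (i in (n - 1):1) C[i] <- (d[i] - cc[i] * C[i + 1]) / b[i]
  list(r = r, C = C)
}

# campaign evaluator over a registry-multiplier map, shared by the robust
# and sensitivity tests on the real model
registry_evaluator <- function(registry = default_registry(),
                               preset = "baseline_gf_model",
                               thresholds = default_thresholds()) {
  function(design, multipliers) {
    p <- realize(registry, multipliers)
    res <- simulate_campaign(design, p, preset, thresholds)
    list(objective = res$cost$cost_per_unit_rbc,
         violations = res$feasibility)
  }
}

# small design grid in the feasible interior of the default model, used
# where the full grid_small fixture would be too slow
mini_robust_grid <- function() {
  design_grid(
    n_fibers_B = c(12L, 16L, 20L, 24L, 28L),
    feed_EPO = c(5, 10),
    base = hd_design(n_fibers_A = 12L,
                     feeds = c(Glc = 25, O2 = 0.4, Lac = 0,
                               EPO = 5, SCF = 50)))
}

# uncertainty rows for a subset of registry parameters at +/- width
unc_rows <- function(ids, width) {
  data.frame(id = ids, lo = 1 - width, hi = 1 + width,
             stringsAsFactors = FALSE)
}
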