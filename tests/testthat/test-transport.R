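test_that("Krogh radius follows the equal-area tiling law", {
  expect_equal(krogh_radius(pi, 1), 1)
  # the bioreactor's fiber-density range: 0.15-0.25 fibers/mm^2
  expect_equal(krogh_radius(1 / 0.15, 1), 1 / sqrt(pi * 0.15),
               tolerance = 1e-12)
  expect_equal(krogh_radius(1 / 0.15, 1), 1.4567312, tolerance = 1e-6)
  expect_equal(krogh_radius(1 / 0.25, 1), 1.1283792, tolerance = 1e-6)
  # doubling the fiber count halves the served area
  expect_equal(krogh_radius(10, 8)^2, krogh_radius(10, 4)^2 / 2)
  expect_error(krogh_radius(10, 0), "invalid design")
})

test_that("zeroth-order annulus profile: uniform limit and no-flux closure", {
  prof <- radial_profile_zeroth_order(0.2, 0, 2e-9, 4e-4, 1.5e-3)
  expect_true(all(prof$profile$C == 0.2))
  expect_false(prof$anoxic)
  # analytic no-flux closure at the Krogh radius, checked numerically
  p <- list(C_wall = 0.2, q0 = 3e-4, D = 2e-9, Ro = 4e-4, Rk = 1.5e-3)
  f <- function(r) p$C_wall + p$q0 / (4 * p$D) * (r^2 - p$Ro^2) -
    p$q0 * p$Rk^2 / (2 * p$D) * log(r / p$Ro)
  eps <- p$Rk * 1e-9
  dCdr <- (f(p$Rk) - f(p$Rk - eps)) / eps
  scale <- abs(f(p$Ro) - f(p$Rk)) / (p$Rk - p$Ro)
  expect_lt(abs(dCdr) / scale, 1e-6)
  expect_error(radial_profile_zeroth_order(0.2, 0, 2e-9, 2e-3, 1.5e-3),
               "invalid geometry")
})

test_that("zeroth-order profile agrees with an independent BVP solve", {
  set.seed(42)
  for (i in 1:10) {
    Ro <- runif(1, 2e-4, 5e-4)
    Rk <- Ro * runif(1, 2, 5)
    D <- 10^runif(1, -9.5, -8.5)
    C_wall <- runif(1, 0.1, 0.5)
    # keep the draw in the non-exhausted regime so the problem is linear
    drop_max <- C_wall * 0.8
    q_lim <- drop_max /
      (Rk^2 / (2 * D) * log(Rk / Ro) - (Rk^2 - Ro^2) / (4 * D))
    q0 <- runif(1, 0.1, 0.9) * q_lim
    prof <- radial_profile_zeroth_order(C_wall, q0, D, Ro, Rk, n_r = 101)
    expect_false(prof$anoxic)
    oracle <- bvp_radial_oracle(C_wall, q0, D, Ro, Rk, n = 4001)
    # compare on the package grid by interpolating the oracle
    Cb <- approx(oracle$r, oracle$C, xout = prof$profile$r)$y
    expect_lt(max(abs(prof$profile$C - Cb)) / max(abs(prof$profile$C)),
              1e-6)
  }
})

test_that("Michaelis-Menten radial solver: limits and monotonicity", {
  # no uptake: uniform profile
  p0 <- radial_profile_mm(0.2, 0, 0.01, 2e-9, 4e-4, 1.5e-3)
  expect_equal(p0$profile$C, rep(0.2, 101), tolerance = 1e-12)
  # saturated (K_m -> 0) limit matches the zeroth-order analytic profile
  # wherever C > 10 K_m
  Km <- 1e-5
  Vrho <- 2e-4
  mm <- radial_profile_mm(0.3, Vrho, Km, 2e-9, 4e-4, 1.2e-3)
  an <- radial_profile_zeroth_order(0.3, Vrho, 2e-9, 4e-4, 1.2e-3)
  sel <- mm$profile$C > 10 * Km
  expect_true(any(sel))
  expect_lt(max(abs(mm$profile$C[sel] - an$profile$C[sel]) /
                  mm$profile$C[sel]), 1e-3)
  # profile is nonincreasing away from the fiber and nonnegative
  expect_true(all(diff(mm$profile$C) <= 1e-12))
  expect_true(all(mm$profile$C >= 0))
  # faster diffusion weakly raises the minimum concentration
  mins <- vapply(c(1, 2, 4, 8) * 1e-9, function(D)
    min(radial_profile_mm(0.2, 3e-4, 0.01, D, 4e-4, 1.4e-3)$profile$C),
    numeric(1))
  expect_true(all(diff(mins) >= -1e-12))
})

test_that("axial lumen profile conserves mass and hits closed forms", {
  Q <- 1e-9; L <- 0.03
  ax0 <- axial_lumen_profile(Q, 0.2, 0, L)
  expect_true(all(ax0$profile$C == 0.2))
  # constant extraction: linear decline with the known outlet value
  e0 <- 1e-9
  ax1 <- axial_lumen_profile(Q, 0.2, e0, L)
  expect_equal(ax1$outlet, 0.2 - e0 * L / Q, tolerance = 1e-12)
  expect_equal(max(abs(diff(ax1$profile$C) - diff(ax1$profile$C)[1])), 0,
               tolerance = 1e-15)
  # conservation identity on random extraction fields
  set.seed(7)
  for (i in 1:5) {
    co <- runif(3, 0, 2e-9)
    efun <- function(z) co[1] + co[2] * sin(200 * z) + co[3] * (z / L)
    ax <- axial_lumen_profile(Q, 0.5, efun, L, n_z = 2001)
    expect_false(ax$starved)
    lhs <- (0.5 - ax$outlet) * Q
    expect_equal(lhs, ax$extracted, tolerance = 1e-8)
    # quadrature oracle for the same integral
    zi <- seq(0, L, length.out = 20001)
    oracle <- sum(diff(zi) * (efun(zi)[-1] + efun(zi)[-length(zi)]) / 2)
    expect_equal(ax$extracted, oracle, tolerance = 1e-6)
  }
  # starvation clamps at zero and reduces the realized extraction
  axs <- axial_lumen_profile(Q, 0.01, 1e-8, L)
  expect_true(axs$starved)
  expect_true(all(axs$profile$C >= 0))
  expect_equal(axs$extracted, 0.01 * Q, tolerance = 1e-12)
})

test_that("limited fraction is a proper volume fraction", {
  prof <- radial_profile_zeroth_order(0.2, 0, 2e-9, 4e-4, 1.5e-3)
  expect_equal(limited_fraction(prof, 0.1), 0)   # everywhere above
  expect_equal(limited_fraction(prof, 0.5), 1)   # everywhere below
  # doubling the wall concentration never increases the limited fraction
  set.seed(11)
  for (i in 1:20) {
    q0 <- runif(1, 1e-4, 1e-3)
    D <- runif(1, 1e-9, 4e-9)
    Cw <- runif(1, 0.1, 0.3)
    Rk <- runif(1, 1e-3, 2e-3)
    p1 <- radial_profile_zeroth_order(Cw, q0, D, 3.5e-4, Rk)
    p2 <- radial_profile_zeroth_order(2 * Cw, q0, D, 3.5e-4, Rk)
    expect_lte(limited_fraction(p2, 0.02), limited_fraction(p1, 0.02))
  }
})

test_that("harvest flux is linear in each factor", {
  expect_equal(harvest_rate(1e7, 5, 0), 0)
  expect_equal(harvest_rate(1e7, 10, 2e5), 2 * harvest_rate(1e7, 5, 2e5))
  expect_equal(harvest_rate(2e7, 5, 2e5), 2 * harvest_rate(1e7, 5, 2e5))
  expect_equal(harvest_rate(1e6, 1, 3e5), 3e5)
})
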