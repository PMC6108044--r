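test_that("Hill proliferation rate has the right anchors and monotonicity", {
  expect_equal(proliferation_rate(G = 2, beta_max = 1, theta = 2), 0.5)
  expect_equal(proliferation_rate(G = 0, beta_max = 1, theta = 2), 0)
  # saturation limit at G >> theta
  expect_equal(proliferation_rate(G = 1e6 * 2, beta_max = 0.7, theta = 2),
               0.7, tolerance = 1e-5)
  G <- seq(0, 50, by = 0.5)
  for (n in c(1, 2, 4)) {
    b <- proliferation_rate(G, 1, 5, n)
    expect_true(all(diff(b) >= 0))
  }
  expect_error(proliferation_rate(1, 1, theta = 0), "theta")
})

test_that("growth-factor decay follows the half-life law", {
  expect_equal(gf_decay(10, t = 3, t_half = 3), 5)
  expect_equal(gf_decay(10, t = 0, t_half = 3), 10)
  expect_equal(gf_decay(10, t = 6, t_half = 3), 2.5)
})

test_that("a zero-rate step leaves the state unchanged", {
  reg <- default_registry()
  zero <- stats::setNames(
    rep(0, 7), c("beta_max_hsc", "beta_max_prog", "kappa_hsc", "kappa_prog",
                 "delta_hsc", "delta_prog", "delta_rbc"))
  k <- kinetic_preset("baseline_gf_model", realize(reg, zero))
  st <- cell_state(c(HSC = 1e5, Prog = 2e5, RBC = 3e5))
  st2 <- kinetics_step(st, c(EPO = 10, SCF = 50), k, dt = 0.01)
  expect_identical(st2$density, st$density)
})

test_that("single-compartment growth matches the exponential closed form", {
  # beta small enough that first-order Euler at dt = 1e-3 stays within
  # 1e-6 of N0 exp(beta t) over the simulated window
  reg <- default_registry()
  mult <- c(beta_max_hsc = 0.1, kappa_hsc = 0, delta_hsc = 0)
  k <- kinetic_preset("baseline_gf_model", realize(reg, mult))
  beta <- 0.05  # = beta_max 0.05/day at saturation
  k$beta_max[["HSC"]] <- beta / (1 - 1e-9)  # cancel the Hill shortfall
  st <- cell_state(c(HSC = 1e6, Prog = 0, RBC = 0))
  G <- c(SCF = 1e9 * k$theta[["HSC"]], EPO = 0)
  out <- simulate_kinetics(st, G, k, t_end = 0.5, dt = 1e-3)
  expect_equal(out$state$density[["HSC"]], 1e6 * exp(beta * 0.5),
               tolerance = 1e-6)
})

test_that("explicit scheme converges at first order in dt", {
  k <- kinetic_preset("baseline_gf_model")
  st <- cell_state(c(HSC = 1e6, Prog = 0, RBC = 0))
  G <- c(EPO = 10, SCF = 50)
  run <- function(dt) simulate_kinetics(st, G, k, t_end = 5,
                                        dt = dt)$state$density[["RBC"]]
  ref <- run(5e-4)
  e1 <- abs(run(0.02) - ref)
  e2 <- abs(run(0.01) - ref)
  expect_gt(e1 / e2, 1.8)
  expect_lt(e1 / e2, 2.2)
})

test_that("with no death and unit amplification cells are conserved", {
  reg <- default_registry()
  mult <- c(delta_hsc = 0, delta_prog = 0, delta_rbc = 0,
            amp_hsc = 1 / 4, amp_prog = 1 / 16)  # amp -> 1
  k <- kinetic_preset("baseline_gf_model", realize(reg, mult))
  expect_equal(unname(k$amp), c(1, 1, 1))
  st <- cell_state(c(HSC = 1e6, Prog = 1e5, RBC = 0))
  G <- c(EPO = 10, SCF = 50)
  tot_prev <- sum(st$density)
  for (i in 1:50) {
    st2 <- kinetics_step(st, G, k, dt = 0.01)
    fl <- attr(st2, "fluxes")
    # differentiation outflow of c equals inflow to c+1 at every step
    expect_equal(unname(fl$inflow[-1]),
                 unname(fl$diff_out[-length(fl$diff_out)]))
    tot <- sum(st2$density)
    expect_gte(tot, tot_prev * (1 - 1e-12))  # nondecreasing
    st <- st2; tot_prev <- tot
  }
  # with beta = 0 as well, the total is conserved exactly
  k0 <- kinetic_preset("baseline_gf_model",
                       realize(reg, c(mult, beta_max_hsc = 0,
                                      beta_max_prog = 0)))
  st <- cell_state(c(HSC = 1e6, Prog = 1e5, RBC = 1e4))
  tot0 <- sum(st$density)
  for (i in 1:100) st <- kinetics_step(st, G, k0, dt = 0.01)
  expect_equal(sum(st$density), tot0)
})

test_that("too-large steps are rejected with a step-size error", {
  k <- kinetic_preset("baseline_gf_model")
  st <- cell_state(c(HSC = 1e6, Prog = 0, RBC = 0))
  expect_error(kinetics_step(st, c(EPO = 10, SCF = 50), k, dt = 2),
               "step size")
})

test_that("presets are valid and the suspension bound is pessimistic", {
  for (nm in c("baseline_gf_model", "suspension_2d_model")) {
    k <- kinetic_preset(nm)
    expect_true(all(k$beta_max >= 0) && all(k$kappa >= 0) &&
                  all(k$delta >= 0) && all(k$amp >= 1) && all(k$theta > 0))
    expect_identical(k$preset_name, nm)
  }
  expect_error(kinetic_preset("foo"), "unknown kinetic preset")
  # identical 30-day inputs: suspension RBC output never above baseline
  st <- cell_state(c(HSC = 1e6, Prog = 0, RBC = 0))
  G <- c(EPO = 10, SCF = 50)
  base <- simulate_kinetics(st, G, kinetic_preset("baseline_gf_model"),
                            t_end = 30)
  susp <- simulate_kinetics(st, G, kinetic_preset("suspension_2d_model"),
                            t_end = 30)
  expect_lte(susp$inflow_rbc, base$inflow_rbc)
  expect_lte(susp$state$density[["RBC"]], base$state$density[["RBC"]])
})
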