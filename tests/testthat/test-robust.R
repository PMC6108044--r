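# toy evaluators over multiplier maps: objective = f(realized p), with
# the toy registries from toy_scenarios()
lin_toy <- toy_scenarios()$linear_toy
mul_toy <- toy_scenarios()$multiplicative_toy

toy_mult_evaluator <- function(toy, cutoff = Inf) {
  function(design, multipliers) {
    obj <- toy$objective(realize(toy$registry, multipliers))
    list(objective = obj,
         violations = if (obj > cutoff) "cutoff" else character(0))
  }
}

toy_grid <- design_grid(feed_EPO = c(5, 10))

test_that("zero-width uncertainty recovers the nominal evaluation", {
  ev <- toy_mult_evaluator(lin_toy)
  u0 <- unc_rows(c("p1", "p2"), 0)
  wc <- worst_case_evaluate(NULL, ev, u0, mode = "vertex_enum")
  expect_equal(wc$objective, 5)  # 2*1 + 3*1
  expect_equal(unname(wc$realization), c(1, 1))
})

test_that("linear worst case puts every parameter at its adverse bound", {
  # f = 2 p1 + 3 p2 with mixed-sign coefficients via a negated variant
  ev <- toy_mult_evaluator(lin_toy)
  u <- unc_rows(c("p1", "p2"), 0.5)
  wc <- worst_case_evaluate(NULL, ev, u, mode = "vertex_enum")
  expect_equal(wc$objective, 2 * 1.5 + 3 * 1.5)
  expect_equal(unname(wc$realization), c(1.5, 1.5))
  # coordinate probing agrees on this monotone objective
  cp <- worst_case_evaluate(NULL, ev, u, mode = "coordinate_probe")
  expect_equal(cp$objective, wc$objective)
  expect_equal(cp$realization, wc$realization)
  # and never reports below the nominal evaluation
  expect_gte(cp$objective, 5)
})

test_that("vertex enumeration rejects oversized uncertainty sets", {
  ids <- paste0("q", 1:13)
  u <- unc_rows(ids, 0.1)
  expect_error(worst_case_evaluate(NULL, function(d, m)
    list(objective = 1, violations = character(0)), u,
    mode = "vertex_enum"), "budget error")
})

test_that("robust optimum with zero width equals the nominal optimum", {
  ev <- function(design, multipliers) {
    p <- realize(lin_toy$registry, multipliers)
    gp <- attr(design, "grid_point")
    list(objective = gp[["feed_EPO"]] * p[["p1"]] + p[["p2"]],
         violations = character(0))
  }
  rb <- robust_optimize(toy_grid, ev, unc_rows(c("p1", "p2"), 0),
                        mode = "vertex_enum")
  expect_identical(rb$grid_point, rb$nominal$grid_point)
  expect_equal(rb$objective, rb$nominal$objective)
  expect_equal(rb$price_of_robustness, 0)
})

test_that("price of robustness is nonnegative and monotone in width", {
  set.seed(31)
  for (rep in 1:20) {
    a <- runif(1, 0.5, 3); b <- runif(1, 0.5, 3)
    ev <- function(design, multipliers) {
      p <- realize(lin_toy$registry, multipliers)
      gp <- attr(design, "grid_point")
      list(objective = a * gp[["feed_EPO"]] * p[["p1"]] + b * p[["p2"]],
           violations = character(0))
    }
    widths <- sort(runif(3, 0, 0.5))
    objs <- vapply(widths, function(w)
      robust_optimize(toy_grid, ev, unc_rows(c("p1", "p2"), w),
                      mode = "vertex_enum")$objective, numeric(1))
    rb <- robust_optimize(toy_grid, ev, unc_rows(c("p1", "p2"),
                                                 widths[2]))
    expect_gte(rb$price_of_robustness, 0)
    expect_gte(rb$objective, rb$nominal$objective)
    # nested uncertainty sets give ordered robust optima
    expect_true(all(diff(objs) >= -1e-12))
  }
})

test_that("single uncertain parameter with monotone objective: robust = nominal at adverse bound", {
  ev <- function(design, multipliers) {
    p <- realize(lin_toy$registry, multipliers)
    gp <- attr(design, "grid_point")
    list(objective = gp[["feed_EPO"]] * p[["p1"]], violations = character(0))
  }
  rb <- robust_optimize(toy_grid, ev, unc_rows("p1", 0.3))
  # closed form: min over designs of (design value) * 1.3
  expect_equal(rb$objective, 5 * 1.3)
  expect_equal(unname(rb$realization[["p1"]]), 1.3)
})

test_that("robust design under binding harvest-flux uncertainty adds ceramic fibers", {
  # real-model fixture: the trans-membrane cell flux J_cells may fall to
  # half its nominal value; harvest area (ceramic set-B fiber count) is
  # the design lever that hedges against it
  ev <- registry_evaluator()
  grid <- mini_robust_grid()
  nominal <- global_optimize(grid, function(d)
    ev(d, stats::setNames(numeric(0), character(0))))
  rb <- robust_optimize(grid, ev, unc_rows("j_cells", 0.5),
                        mode = "vertex_enum")
  expect_gte(rb$design$n_fibers_B, nominal$design$n_fibers_B)
  expect_gte(rb$price_of_robustness, 0)
})
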