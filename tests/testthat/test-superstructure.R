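# cheap synthetic evaluator over grid coordinates: deterministic, fast,
# with optional feasibility constraints
toy_evaluator <- function(coefs, cutoff = Inf) {
  function(design) {
    gp <- attr(design, "grid_point")
    obj <- sum(coefs[names(gp)] * as.numeric(gp))
    list(objective = obj,
         violations = if (obj > cutoff) "cutoff exceeded" else character(0))
  }
}

test_that("enumeration is exhaustive, deterministic, lexicographic", {
  g <- design_grid(feed_EPO = c(5, 10), feed_SCF = c(25, 50, 75))
  expect_equal(length(g), 6L)
  designs <- enumerate_designs(g)
  expect_length(designs, 6L)
  pts <- t(vapply(designs, function(d) attr(d, "grid_point"), numeric(2)))
  # first declared variable most significant
  expect_equal(pts[, "feed_EPO"], c(5, 5, 5, 10, 10, 10))
  expect_equal(pts[, "feed_SCF"], rep(c(25, 50, 75), 2))
  # stable across calls
  pts2 <- t(vapply(enumerate_designs(g), function(d)
    attr(d, "grid_point"), numeric(2)))
  expect_identical(pts, pts2)
  # singleton grid yields exactly that design
  g1 <- design_grid(feed_EPO = 7)
  d1 <- enumerate_designs(g1)
  expect_length(d1, 1L)
  expect_equal(d1[[1]]$feeds[["EPO"]], 7)
  expect_error(design_grid(nonsense_var = 1:3) |> enumerate_designs(),
               "unknown design variable")
})

test_that("a dominating design is found and certified", {
  g <- design_grid(feed_EPO = c(5, 10), feed_SCF = c(25, 50))
  ev <- toy_evaluator(c(feed_EPO = 1, feed_SCF = 1))
  opt <- global_optimize(g, ev)
  expect_equal(unname(opt$grid_point), c(5, 25))
  expect_equal(opt$objective, 30)
  # optimality certificate: no enumerated feasible design does better
  objs <- vapply(enumerate_designs(g), function(d) ev(d)$objective,
                 numeric(1))
  expect_true(all(opt$objective <= objs))
})

test_that("pruned search equals exhaustive search on random grids", {
  set.seed(2024)
  vars <- c("feed_EPO", "feed_SCF", "feed_O2", "flow_per_fiber")
  for (rep in 1:25) {
    nv <- sample(2:3, 1)
    vs <- sample(vars, nv)
    grid_vars <- lapply(stats::setNames(vs, vs), function(v)
      sort(round(runif(sample(2:5, 1), 1, 100), 2)))
    g <- do.call(design_grid, grid_vars)
    expect_lte(length(g), 200L)
    coefs <- stats::setNames(runif(nv, -2, 2), vs)
    cutoff <- runif(1, -100, 300)
    ev <- toy_evaluator(coefs, cutoff)
    bound <- function(design) ev(design)$objective - runif(1, 0, 5)
    exhaustive <- tryCatch(global_optimize(g, ev), error = function(e) e)
    pruned <- tryCatch(global_optimize(g, ev, bound_fn = bound,
                                       prune = TRUE),
                       error = function(e) e)
    if (inherits(exhaustive, "error")) {
      expect_s3_class(pruned, "error")
    } else {
      expect_identical(pruned$grid_point, exhaustive$grid_point)
      expect_identical(pruned$objective, exhaustive$objective)
      expect_lte(pruned$audit$n_evaluated, exhaustive$audit$n_evaluated)
    }
  }
})

test_that("relaxing a constraint never worsens the optimum", {
  set.seed(99)
  for (rep in 1:10) {
    g <- design_grid(feed_EPO = sort(runif(4, 1, 50)),
                     feed_SCF = sort(runif(4, 1, 50)))
    coefs <- c(feed_EPO = runif(1, 0.5, 2), feed_SCF = runif(1, 0.5, 2))
    tight <- global_optimize(g, toy_evaluator(coefs, cutoff = 80))
    loose <- global_optimize(g, toy_evaluator(coefs, cutoff = Inf))
    expect_lte(loose$objective, tight$objective)
  }
})

test_that("adding candidate values never worsens the optimum", {
  ev <- toy_evaluator(c(feed_EPO = 1, feed_SCF = 2))
  g1 <- design_grid(feed_EPO = c(10, 20), feed_SCF = c(30, 40))
  g2 <- design_grid(feed_EPO = c(5, 10, 20), feed_SCF = c(25, 30, 40))
  expect_lte(global_optimize(g2, ev)$objective,
             global_optimize(g1, ev)$objective)
})

test_that("an all-infeasible grid reports the nearest-to-feasible design", {
  g <- design_grid(feed_EPO = c(5, 10))
  ev <- toy_evaluator(c(feed_EPO = 1), cutoff = -10)
  expect_error(global_optimize(g, ev), "infeasible superstructure")
  expect_error(global_optimize(g, ev), "nearest-to-feasible")
})

test_that("grid refinement zooms numeric variables around the incumbent", {
  g <- design_grid(feed_EPO = c(5, 10, 20), n_fibers_B = c(8L, 16L))
  opt <- global_optimize(g, toy_evaluator(c(feed_EPO = 1,
                                            n_fibers_B = 0.1)))
  g2 <- refine_grid(g, opt)
  expect_gt(length(g2$vars$feed_EPO), 3)
  expect_true(all(g2$vars$feed_EPO >= 5 & g2$vars$feed_EPO <= 10))
  expect_identical(g2$vars$n_fibers_B, c(8L, 16L))  # counts not refined
})
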