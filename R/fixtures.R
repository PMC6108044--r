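#' Deterministic toy scenarios for testing and demonstration
#'
#' Small, fully in-code fixtures used throughout the test suite and the
#' examples, so every module is exercisable without external data:
#'
#' * `linear_toy`: a 2-parameter registry (`p1`, `p2`, nominal 1) with the
#'   analytic optimizer output `f*(p) = 2 p1 + 3 p2` — linear, so all
#'   interaction sensitivities `S_ij` are exactly zero.
#' * `multiplicative_toy`: same registry with `f*(p) = 5 p1 p2`, the
#'   minimal nonlinear case with hand-computable `S_ij`.
#' * `grid_small`: a design grid of at most 100 points around the default
#'   design.
#' * `single_fiber`: a single-fiber Krogh transport scenario at a fiber
#'   density of 0.2 fibers/mm^2 (inside the 0.15-0.25 range of the dual
#'   hollow-fiber reactor), with an oxygen-like consumed species.
#'
#' @return Named list of fixtures. Each toy objective fixture contains
#'   `registry`, `objective` (function of realized values) and `optimizer`
#'   (function of a multiplier vector, the contract of
#'   [univariate_scan()]).
#' @export
toy_scenarios <- function() {
  toy_reg <- data.frame(id = c("p1", "p2"), nominal = c(1, 1),
                        unit = c("-", "-"), group = c("toy", "toy"),
                        uncertainty_class = c("level_set", "level_set"),
                        box_halfwidth = c(NA_real_, NA_real_),
                        description = c("toy parameter 1",
                                        "toy parameter 2"),
                        stringsAsFactors = FALSE)
  class(toy_reg) <- c("hd_registry", "data.frame")
  make_toy <- function(fn) {
    list(registry = toy_reg, objective = fn,
         optimizer = function(multipliers)
           fn(realize(toy_reg, multipliers)))
  }
  density <- 0.2  # fibers per mm^2
  R_reactor <- sqrt(1 / (pi * density))  # mm, single fiber
  list(
    linear_toy = make_toy(function(v) 2 * v[["p1"]] + 3 * v[["p2"]]),
    multiplicative_toy = make_toy(function(v) 5 * v[["p1"]] * v[["p2"]]),
    grid_small = design_grid(
      n_fibers_A = c(4L, 8L, 12L),
      n_fibers_B = c(4L, 8L, 12L, 16L),
      feed_O2 = c(0.2, 0.4),   # atmospheric and 2x-atmospheric oxygen
      feed_EPO = c(5, 10),
      feed_SCF = c(25, 50),
      base = hd_design()),
    single_fiber = list(
      density = density,
      reactor_radius = R_reactor,
      fiber_radius = 0.35,
      layout = even_layout(1L, R_reactor, 0.35),
      D = 2e-9,            # m^2/s
      q0 = 5e-4,           # mol/m^3/s
      C_wall = 0.2,        # mol/m^3
      C_critical = 0.02,   # mol/m^3
      R_outer_m = 0.35e-3,
      R_krogh_m = R_reactor * 1e-3))
}
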