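#' Define a discrete design grid
#'
#' Candidate values per design variable. Continuous variables are
#' discretized; the search over the declared grid is exhaustive and
#' therefore exact on that grid.
#'
#' @param ... Named vectors of candidate values, one per design variable
#'   (names must match [hd_design()] arguments, e.g.
#'   `n_fibers_B = c(4, 8, 12)`). Feed concentrations are addressed as
#'   `feed_<species>`, e.g. `feed_EPO = c(5, 10)`.
#' @param base A base `hd_design` supplying every variable not in the grid.
#' @return Object of class `hd_grid` with elements `vars` (named list) and
#'   `base`; `length()` gives the total number of designs.
#' @export
design_grid <- function(..., base = hd_design()) {
  vars <- list(...)
  if (length(vars) == 1L && is.list(vars[[1]]) && is.null(names(vars)))
    vars <- vars[[1]]
  stopifnot(length(vars) > 0, !is.null(names(vars)),
            all(nzchar(names(vars))),
            all(vapply(vars, length, 1L) >= 1L))
  structure(list(vars = vars, base = base), class = "hd_grid")
}

#' @export
length.hd_grid <- function(x) prod(vapply(x$vars, length, 1L))

#' Enumerate all designs of a grid
#'
#' Deterministic lexicographic order on the design vector: the first
#' declared variable is the most significant (varies slowest); order is
#' stable across runs. Combined with strict-improvement search this makes
#' optimizer ties resolve to the lexicographically smallest design.
#'
#' @param grid An `hd_grid`.
#' @return List of `hd_design` objects; each carries an attribute
#'   `"grid_point"`, the named vector of grid coordinates.
#' @export
enumerate_designs <- function(grid) {
  stopifnot(inherits(grid, "hd_grid"))
  combos <- expand.grid(rev(grid$vars), KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  combos <- combos[, names(grid$vars), drop = FALSE]
  lapply(seq_len(nrow(combos)), function(i)
    apply_grid_point(grid$base, combos[i, , drop = FALSE]))
}

apply_grid_point <- function(base, point) {
  d <- unclass(base)
  for (nm in names(point)) {
    val <- point[[nm]]
    if (startsWith(nm, "feed_")) {
      d$feeds[[sub("^feed_", "", nm)]] <- val
    } else if (nm %in% names(d)) {
      d[[nm]] <- if (nm %in% c("n_reactors", "n_fibers_A", "n_fibers_B"))
        as.integer(val) else val
    } else stop("unknown design variable: ", nm, call. = FALSE)
  }
  out <- do.call(hd_design, d[setdiff(names(d), character(0))])
  attr(out, "grid_point") <- unlist(point)
  out
}

#' Deterministic global search over a design grid
#'
#' Exhaustively evaluates every design on the grid (optionally skipping
#' designs whose objective lower bound already exceeds the incumbent) and
#' returns the feasible minimizer. With a sound lower bound the pruned
#' search returns exactly the exhaustive answer. Ties are broken
#' lexicographically on the design's grid coordinates, which the
#' enumeration order guarantees automatically.
#'
#' @param grid An `hd_grid`.
#' @param evaluator Function `design -> list(objective = <number>,
#'   violations = <character vector>)`. A design is feasible iff
#'   `violations` is empty. `objective` may be `NA` for infeasible designs.
#' @param bound_fn Optional function `design -> lower bound on objective`;
#'   used for pruning only, must be a true lower bound.
#' @param prune Use `bound_fn` to skip dominated designs.
#' @return Object of class `hd_optimum`: `design`, `objective`,
#'   `grid_point`, and `audit` (counts of evaluated / pruned / infeasible
#'   designs plus the running incumbent trace).
#' @export
global_optimize <- function(grid, evaluator, bound_fn = NULL,
                            prune = FALSE) {
  designs <- enumerate_designs(grid)
  best <- NULL; best_obj <- Inf
  n_eval <- 0L; n_pruned <- 0L; n_infeas <- 0L
  trace <- list()
  nearest <- NULL; nearest_nviol <- Inf
  for (d in designs) {
    if (prune && !is.null(bound_fn) && is.finite(best_obj) &&
        bound_fn(d) >= best_obj) {
      n_pruned <- n_pruned + 1L
      next
    }
    ev <- evaluator(d)
    n_eval <- n_eval + 1L
    if (length(ev$violations)) {
      n_infeas <- n_infeas + 1L
      if (length(ev$violations) < nearest_nviol) {
        nearest <- list(design = d, violations = ev$violations)
        nearest_nviol <- length(ev$violations)
      }
      next
    }
    if (is.finite(ev$objective) && ev$objective < best_obj) {
      best <- d; best_obj <- ev$objective
      trace[[length(trace) + 1L]] <-
        c(attr(d, "grid_point"), objective = ev$objective)
    }
  }
  if (is.null(best)) {
    msg <- "infeasible superstructure: no feasible design on the grid"
    if (!is.null(nearest))
      msg <- paste0(msg, "; nearest-to-feasible design violates: ",
                    paste(nearest$violations, collapse = "; "))
    stop(msg, call. = FALSE)
  }
  structure(list(design = best, objective = best_obj,
                 grid_point = attr(best, "grid_point"),
                 audit = list(n_designs = length(designs),
                              n_evaluated = n_eval, n_pruned = n_pruned,
                              n_infeasible = n_infeas,
                              incumbent_trace = trace)),
            class = "hd_optimum")
}

#' Campaign-based design evaluator
#'
#' Convenience wrapper turning [simulate_campaign()] into the
#' `evaluator` contract of [global_optimize()].
#'
#' @inheritParams simulate_campaign
#' @param objective Field of the cost breakdown to minimize.
#' @return A function `design -> list(objective, violations, result)`.
#' @export
campaign_evaluator <- function(params = realize(default_registry()),
                               preset = "baseline_gf_model",
                               thresholds = default_thresholds(),
                               objective = "cost_per_unit_rbc") {
  force(params); force(preset); force(thresholds); force(objective)
  function(design) {
    res <- simulate_campaign(design, params, preset, thresholds)
    list(objective = res$cost[[objective]],
         violations = res$feasibility, result = res)
  }
}

#' Refine a grid around an incumbent design (nested zoom)
#'
#' Builds a finer grid spanning one original grid cell around the incumbent
#' for each numeric variable (factor-5 refinement); integer count variables
#' are left on their declared candidates. Two zoom levels emulate a simple
#' continuous refinement while keeping the search exact on each declared
#' grid.
#'
#' @param grid An `hd_grid`.
#' @param optimum An `hd_optimum` from [global_optimize()].
#' @param factor Refinement factor (default 5).
#' @return A new `hd_grid`.
#' @export
refine_grid <- function(grid, optimum, factor = 5) {
  vars <- grid$vars
  gp <- optimum$grid_point
  new_vars <- vars
  for (nm in names(vars)) {
    v <- sort(unique(vars[[nm]]))
    if (length(v) < 2 || nm %in% c("n_reactors", "n_fibers_A", "n_fibers_B",
                                   "fiber_A", "fiber_B")) next
    x0 <- gp[[nm]]
    i <- which.min(abs(v - x0))
    lo <- if (i > 1) v[i - 1] else v[i]
    hi <- if (i < length(v)) v[i + 1] else v[i]
    new_vars[[nm]] <- unique(seq(lo, hi, length.out = 2 * factor + 1))
  }
  design_grid(new_vars, base = grid$base)
}
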