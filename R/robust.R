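#' Worst-case evaluation of a design under parameter uncertainty
#'
#' Evaluates a design over an uncertainty box given as extreme multipliers
#' per parameter and returns the worst (largest) objective and the
#' realization attaining it. Feasibility is robustified constraint-wise: a
#' violation occurring at any probed realization counts against the design.
#'
#' Two modes:
#' * `"vertex_enum"` (up to 12 uncertain parameters): enumerates all
#'   extreme-multiplier combinations (plus the nominal point) and maximizes
#'   exactly over them — exact for the box hull whenever the objective is
#'   vertex-attained (in particular for coordinatewise monotone responses).
#' * `"coordinate_probe"`: probes each parameter's two extremes with the
#'   others nominal, combines the adverse picks and evaluates once more; a
#'   conservative heuristic, exact when the objective is coordinatewise
#'   monotone. Never reports less than the nominal evaluation.
#'
#' @param design The design to evaluate (passed through to `evaluator`).
#' @param evaluator Function `(design, multipliers) -> list(objective,
#'   violations)` where `multipliers` is a named numeric vector.
#' @param uncertainty Data frame with columns `id`, `lo`, `hi` (extreme
#'   multipliers), e.g. from [default_uncertainty()], restricted to the
#'   parameters considered uncertain.
#' @param mode `"vertex_enum"` or `"coordinate_probe"`.
#' @return List: `objective` (worst case), `realization` (named multiplier
#'   vector attaining it), `violations` (union over probed realizations),
#'   `n_evaluations`.
#' @export
worst_case_evaluate <- function(design, evaluator, uncertainty,
                                mode = c("vertex_enum", "coordinate_probe")) {
  mode <- match.arg(mode)
  stopifnot(all(c("id", "lo", "hi") %in% names(uncertainty)))
  k <- nrow(uncertainty)
  ids <- uncertainty$id
  nominal_mult <- stats::setNames(rep(1, k), ids)
  if (mode == "vertex_enum") {
    if (k > 12L)
      stop("budget error: vertex_enum limited to 12 uncertain parameters ",
           "(", k, " requested); use mode = \"coordinate_probe\"",
           call. = FALSE)
    ext <- lapply(seq_len(k), function(i)
      unique(c(uncertainty$lo[i], uncertainty$hi[i])))
    vertices <- expand.grid(ext, KEEP.OUT.ATTRS = FALSE)
    names(vertices) <- ids
    # include the nominal point so the worst case can never undercut it
    vertices <- unique(rbind(vertices, as.list(nominal_mult)))
    worst <- -Inf; worst_mult <- nominal_mult; viol <- character(0)
    for (i in seq_len(nrow(vertices))) {
      mult <- stats::setNames(as.numeric(vertices[i, ]), ids)
      ev <- evaluator(design, mult)
      viol <- union(viol, ev$violations)
      if (is.finite(ev$objective) && ev$objective > worst) {
        worst <- ev$objective; worst_mult <- mult
      }
    }
    list(objective = worst, realization = worst_mult, violations = viol,
         n_evaluations = nrow(vertices))
  } else {
    ev0 <- evaluator(design, nominal_mult)
    viol <- ev0$violations
    adverse <- nominal_mult
    n_ev <- 1L
    for (i in seq_len(k)) {
      best_side <- 1; best_obj <- -Inf
      for (side in c(uncertainty$lo[i], uncertainty$hi[i])) {
        mult <- nominal_mult; mult[[ids[i]]] <- side
        ev <- evaluator(design, mult)
        n_ev <- n_ev + 1L
        viol <- union(viol, ev$violations)
        if (is.finite(ev$objective) && ev$objective > best_obj) {
          best_obj <- ev$objective; best_side <- side
        }
      }
      adverse[[ids[i]]] <- best_side
    }
    evc <- evaluator(design, adverse)
    n_ev <- n_ev + 1L
    viol <- union(viol, evc$violations)
    if (is.finite(evc$objective) &&
        (!is.finite(ev0$objective) || evc$objective >= ev0$objective)) {
      list(objective = evc$objective, realization = adverse,
           violations = viol, n_evaluations = n_ev)
    } else {
      list(objective = ev0$objective, realization = nominal_mult,
           violations = viol, n_evaluations = n_ev)
    }
  }
}

#' Robust counterpart of the superstructure search
#'
#' Minimizes the worst-case objective over designs that remain feasible
#' under every probed parameter realization (static worst-case robust
#' counterpart over an independent per-parameter box), and reports the
#' price of robustness relative to the nominal optimum.
#'
#' @param grid An `hd_grid`.
#' @param evaluator Function `(design, multipliers) -> list(objective,
#'   violations)`; called with an empty multiplier vector for the nominal
#'   problem.
#' @param uncertainty Data frame `id`, `lo`, `hi` of extreme multipliers.
#' @param mode Worst-case mode, see [worst_case_evaluate()].
#' @return Object of class `hd_robust`: `design`, `objective` (worst-case
#'   optimum), `nominal_objective_of_robust_design`, `nominal`
#'   (the nominal `hd_optimum`), `price_of_robustness`
#'   (`robust_opt / nominal_opt - 1`), `realization` (worst-case
#'   multipliers for the chosen design), `grid_point`.
#' @export
robust_optimize <- function(grid, evaluator, uncertainty,
                            mode = c("vertex_enum", "coordinate_probe")) {
  mode <- match.arg(mode)
  nominal_eval <- function(design)
    evaluator(design, stats::setNames(numeric(0), character(0)))
  nominal <- global_optimize(grid, nominal_eval)

  designs <- enumerate_designs(grid)
  best <- NULL; best_wc <- Inf; best_real <- NULL
  binding <- NULL; binding_n <- Inf
  for (d in designs) {
    wc <- worst_case_evaluate(d, evaluator, uncertainty, mode)
    if (length(wc$violations)) {
      if (length(wc$violations) < binding_n) {
        binding <- wc$violations; binding_n <- length(wc$violations)
      }
      next
    }
    if (is.finite(wc$objective) && wc$objective < best_wc) {
      best <- d; best_wc <- wc$objective; best_real <- wc$realization
    }
  }
  if (is.null(best)) {
    msg <- "no design is feasible under the worst case"
    if (!is.null(binding))
      msg <- paste0(msg, "; binding constraints: ",
                    paste(binding, collapse = "; "))
    stop(msg, call. = FALSE)
  }
  nom_of_robust <- nominal_eval(best)$objective
  structure(list(design = best, objective = best_wc,
                 nominal_objective_of_robust_design = nom_of_robust,
                 nominal = nominal,
                 price_of_robustness = best_wc / nominal$objective - 1,
                 realization = best_real,
                 grid_point = attr(best, "grid_point")),
            class = "hd_robust")
}
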