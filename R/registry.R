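#' Default parameter registry
#'
#' Central registry of the 30 uncertain model parameters used throughout the
#' toolkit: cell-kinetic rates, mass-transfer properties, the trans-membrane
#' cell flux, and consumable prices / growth-factor half-lives. Each entry
#' carries a nominal value, unit, group, and an uncertainty class:
#' `"measured_box"` for bioreactor material properties whose error bars are
#' measurable (varied within a +/- `box_halfwidth` fraction), `"level_set"`
#' for everything else (varied over the discrete 50/90/110/150% levels).
#'
#' Nominal values are documented placeholders at literature-plausible orders
#' of magnitude; they are editable via [write_registry()] / [read_registry()]
#' and none of the package's validity checks depend on their exact values.
#'
#' @return A data frame of class `hd_registry` with columns `id`, `nominal`,
#'   `unit`, `group`, `uncertainty_class`, `box_halfwidth`, `description`;
#'   exactly 30 rows.
#' @seealso [realize()], [default_uncertainty()], [write_registry()]
#' @examples
#' reg <- default_registry()
#' nrow(reg)            # 30 scanned parameters
#' table(reg$group)
#' @export
default_registry <- function() {
  e <- function(id, nominal, unit, group, uc, hw, desc) {
    data.frame(id = id, nominal = nominal, unit = unit, group = group,
               uncertainty_class = uc, box_halfwidth = hw,
               description = desc, stringsAsFactors = FALSE)
  }
  L <- "level_set"; B <- "measured_box"
  rows <- rbind(
    # -- cellular kinetics (placeholder nominals, order-of-magnitude) --
    e("beta_max_hsc",  0.5,   "1/day",  "kinetics", L, NA,
      "placeholder: max HSC proliferation rate (SCF-driven)"),
    e("beta_max_prog", 1.0,   "1/day",  "kinetics", L, NA,
      "placeholder: max progenitor proliferation rate (EPO-driven)"),
    e("theta_scf",     10,    "ng/mL",  "kinetics", L, NA,
      "placeholder: SCF half-saturation for HSC proliferation"),
    e("theta_epo",     2,     "ng/mL",  "kinetics", L, NA,
      "placeholder: EPO half-saturation for progenitor proliferation"),
    e("kappa_hsc",     0.3,   "1/day",  "kinetics", L, NA,
      "placeholder: HSC -> progenitor differentiation rate"),
    e("kappa_prog",    0.5,   "1/day",  "kinetics", L, NA,
      "placeholder: progenitor -> RBC differentiation rate"),
    e("delta_hsc",     0.01,  "1/day",  "kinetics", L, NA,
      "placeholder: HSC death rate"),
    e("delta_prog",    0.05,  "1/day",  "kinetics", L, NA,
      "placeholder: progenitor death rate"),
    e("delta_rbc",     0.05,  "1/day",  "kinetics", L, NA,
      "placeholder: RBC loss rate in scaffold"),
    e("amp_hsc",       4,     "cells/cell", "kinetics", L, NA,
      "placeholder: progeny per HSC differentiating into progenitors"),
    e("amp_prog",      16,    "cells/cell", "kinetics", L, NA,
      "placeholder: RBC progeny per differentiating progenitor"),
    # -- mass transfer (material properties: measured_box) --
    e("d_glc",  6.0e-10, "m2/s", "transport", B, 0.1,
      "placeholder: glucose diffusivity in scaffold"),
    e("d_lac",  9.0e-10, "m2/s", "transport", B, 0.1,
      "placeholder: lactate diffusivity in scaffold"),
    e("d_o2",   2.0e-9,  "m2/s", "transport", B, 0.1,
      "placeholder: oxygen diffusivity in scaffold"),
    e("d_epo",  1.0e-10, "m2/s", "transport", B, 0.1,
      "placeholder: EPO diffusivity in scaffold"),
    e("d_scf",  1.2e-10, "m2/s", "transport", B, 0.1,
      "placeholder: SCF diffusivity in scaffold"),
    e("perm_membrane", 20, "um/s", "transport", B, 0.1,
      "placeholder: lumped membrane permeability scale"),
    e("vmax_glc", 5.0e-17, "mol/cell/s", "transport", L, NA,
      "placeholder: per-cell max glucose uptake"),
    e("vmax_o2",  1.0e-17, "mol/cell/s", "transport", L, NA,
      "placeholder: per-cell max oxygen uptake (erythroid cells are largely glycolytic)"),
    e("km_glc",  0.5,  "mol/m3", "transport", L, NA,
      "placeholder: Michaelis constant, glucose uptake"),
    e("km_o2",   0.01, "mol/m3", "transport", L, NA,
      "placeholder: Michaelis constant, oxygen uptake"),
    e("lac_yield", 2,  "mol/mol", "transport", L, NA,
      "placeholder: lactate produced per glucose consumed"),
    # -- trans-membrane cell flux --
    e("j_cells", 2.0e5, "cells/cm2/day", "flux", L, NA,
      "placeholder: RBC flux coefficient through set-B (ceramic) fibers"),
    # -- consumable prices and growth-factor half-lives --
    e("price_epo",  0.6,  "USD/ug", "cost", L, NA,
      "placeholder: EPO price"),
    e("price_scf",  0.34, "USD/ug", "cost", L, NA,
      "placeholder: SCF price"),
    e("price_media", 0.1, "USD/L",  "cost", L, NA,
      "placeholder: base media price per litre replaced"),
    e("t_half_epo", 0.5,  "day",    "cost", L, NA,
      "placeholder: EPO half-life in culture"),
    e("t_half_scf", 1.0,  "day",    "cost", L, NA,
      "placeholder: SCF half-life in culture"),
    e("cost_fiber_polymeric", 0.05, "USD/fiber", "cost", L, NA,
      "placeholder: amortized polymeric fiber cost per campaign"),
    e("cost_fiber_ceramic",   0.2,  "USD/fiber", "cost", L, NA,
      "placeholder: amortized ceramic fiber cost per campaign (specialty item)")
  )
  rownames(rows) <- NULL
  class(rows) <- c("hd_registry", "data.frame")
  stopifnot(nrow(rows) == 30L, all(rows$nominal > 0))
  rows
}

#' Realize parameter values from a registry and multiplier map
#'
#' Applies multiplicative perturbations to registry nominals. Parameters not
#' listed in `multipliers` stay at their nominal value, so a scan only needs
#' to name the parameters it moves.
#'
#' @param registry A registry data frame from [default_registry()] or
#'   [read_registry()].
#' @param multipliers Named numeric vector of multipliers, names being
#'   parameter ids present in the registry. May be empty (all nominal).
#' @return Named numeric vector of realized values, one per registry entry,
#'   in registry order.
#' @examples
#' p <- realize(default_registry(), c(j_cells = 1.5))
#' p[["j_cells"]] / default_registry()$nominal[default_registry()$id == "j_cells"]
#' @export
realize <- function(registry, multipliers = numeric(0)) {
  stopifnot(inherits(registry, "data.frame"))
  vals <- stats::setNames(registry$nominal, registry$id)
  if (length(multipliers)) {
    ids <- names(multipliers)
    if (is.null(ids) || any(!nzchar(ids)))
      stop("multipliers must be a named vector", call. = FALSE)
    unknown <- setdiff(ids, registry$id)
    if (length(unknown))
      stop("unknown parameter id(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    vals[ids] <- vals[ids] * as.numeric(multipliers)
  }
  vals
}

#' Default uncertainty specification
#'
#' One row per registry parameter giving the perturbation range used by the
#' sensitivity and robust modules. `level_set` parameters take the discrete
#' multipliers L1 = 0.5, L2 = 0.9, U1 = 1.1, U2 = 1.5 of nominal;
#' `measured_box` parameters vary continuously within
#' `[1 - box_halfwidth, 1 + box_halfwidth]`.
#'
#' @param registry Registry data frame.
#' @param levels Numeric multipliers `c(L1, L2, U1, U2)` for level-set
#'   parameters; must satisfy `L1 < L2 < 1 < U1 < U2`.
#' @return Data frame with columns `id`, `class`, `lo`, `hi` (the extreme
#'   multipliers) plus the full level set as an attribute `"levels"`.
#' @export
default_uncertainty <- function(registry = default_registry(),
                                levels = c(L1 = 0.5, L2 = 0.9,
                                           U1 = 1.1, U2 = 1.5)) {
  stopifnot(length(levels) == 4L,
            levels[1] < levels[2], levels[2] < 1,
            1 < levels[3], levels[3] < levels[4])
  lo <- ifelse(registry$uncertainty_class == "measured_box",
               1 - registry$box_halfwidth, levels[[1]])
  hi <- ifelse(registry$uncertainty_class == "measured_box",
               1 + registry$box_halfwidth, levels[[4]])
  out <- data.frame(id = registry$id, class = registry$uncertainty_class,
                    lo = lo, hi = hi, stringsAsFactors = FALSE)
  attr(out, "levels") <- levels
  out
}

#' Write / read a parameter registry as YAML
#'
#' Serialization is deterministic (entries in registry order, fixed field
#' order) so write -> read -> write round-trips byte-identically.
#'
#' @param registry Registry data frame.
#' @param path File path to write to / read from.
#' @return `write_registry()` returns `path` invisibly; `read_registry()`
#'   returns an `hd_registry` data frame.
#' @export
write_registry <- function(registry, path) {
  entries <- lapply(seq_len(nrow(registry)), function(i) {
    r <- registry[i, ]
    x <- list(id = r$id, nominal = r$nominal, unit = r$unit,
              group = r$group, uncertainty_class = r$uncertainty_class,
              description = r$description)
    if (!is.na(r$box_halfwidth)) x$box_halfwidth <- r$box_halfwidth
    x
  })
  yaml::write_yaml(list(parameters = entries), path, precision = 15)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$parameters)) stop("not a registry file: ", path, call. = FALSE)
  rows <- do.call(rbind, lapply(doc$parameters, function(x) {
    data.frame(id = x$id, nominal = as.numeric(x$nominal), unit = x$unit,
               group = x$group, uncertainty_class = x$uncertainty_class,
               box_halfwidth = if (is.null(x$box_halfwidth)) NA_real_
                               else as.numeric(x$box_halfwidth),
               description = x$description, stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  class(rows) <- c("hd_registry", "data.frame")
  rows
}
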