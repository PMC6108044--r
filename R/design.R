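#' Construct a bioreactor superstructure design point
#'
#' One candidate point in the dual hollow-fiber superstructure: how many
#' parallel reactors, how many fibers of each set (A = polymeric, nutrient
#' supply / waste removal; B = ceramic, growth-factor recycle and cell
#' harvest), reactor geometry, per-fiber flow, feed concentrations, seeding
#' and the culture horizon.
#'
#' @param n_reactors Number of parallel reactors, integer >= 1.
#' @param n_fibers_A,n_fibers_B Fiber counts per set, integer >= 1.
#' @param fiber_A,fiber_B Fiber catalog ids (see [fiber_catalog()]).
#' @param reactor_radius Cross-section radius (mm).
#' @param reactor_length Reactor length (mm); aspect ratio is
#'   `length / (2 * radius)`.
#' @param flow_per_fiber Lumen flow per fiber (uL/min).
#' @param feeds Named feed concentrations: `Glc`, `O2`, `Lac` (mol/m^3) and
#'   `EPO`, `SCF` (ng/mL).
#' @param seeding_density Initial HSC density in the scaffold (cells/mL).
#' @param horizon Culture horizon (days), default 30.
#' @param gamma_pack Maximum fraction of the cross-section occupied by
#'   fibers, default 0.5.
#' @return Object of class `hd_design`.
#' @export
hd_design <- function(n_reactors = 1L, n_fibers_A = 8L, n_fibers_B = 8L,
                      fiber_A = "polymeric_standard",
                      fiber_B = "ceramic_standard",
                      reactor_radius = 5, reactor_length = 30,
                      flow_per_fiber = 100,
                      feeds = c(Glc = 25, O2 = 0.2, Lac = 0,
                                EPO = 10, SCF = 50),
                      seeding_density = 1e6, horizon = 30,
                      gamma_pack = 0.5) {
  d <- list(n_reactors = as.integer(n_reactors),
            n_fibers_A = as.integer(n_fibers_A),
            n_fibers_B = as.integer(n_fibers_B),
            fiber_A = fiber_A, fiber_B = fiber_B,
            reactor_radius = reactor_radius,
            reactor_length = reactor_length,
            flow_per_fiber = flow_per_fiber,
            feeds = feeds, seeding_density = seeding_density,
            horizon = horizon, gamma_pack = gamma_pack)
  stopifnot(d$n_reactors >= 1L, d$n_fibers_A >= 1L, d$n_fibers_B >= 1L,
            reactor_radius > 0, reactor_length > 0, flow_per_fiber > 0,
            seeding_density >= 0, horizon > 0,
            all(c("Glc", "O2", "Lac", "EPO", "SCF") %in% names(feeds)),
            all(feeds >= 0))
  class(d) <- "hd_design"
  d
}

#' Packing fraction of a design
#'
#' Fraction of the reactor cross-section occupied by fiber outer
#' cross-sections; must not exceed `gamma_pack`.
#' @param design An `hd_design`.
#' @return Packing fraction (unitless).
#' @export
packing_fraction <- function(design) {
  fa <- fiber_catalog(design$fiber_A); fb <- fiber_catalog(design$fiber_B)
  area <- pi * design$reactor_radius^2
  occ <- design$n_fibers_A * pi * (fa$R_outer_um / 1000)^2 +
    design$n_fibers_B * pi * (fb$R_outer_um / 1000)^2
  occ / area
}

#' Species transport specification table
#'
#' Per-species transport constants assembled from realized registry values:
#' diffusivity, per-cell uptake, Michaelis constant, role, critical /
#' ceiling concentration and fiber-set assignment. Glc, Lac and O2 ride on
#' fiber set A; the growth factors EPO and SCF on set B.
#'
#' @param params Named numeric vector from [realize()].
#' @return Data frame with one row per species.
#' @export
species_table <- function(params = realize(default_registry())) {
  data.frame(
    name = c("Glc", "Lac", "O2", "EPO", "SCF"),
    fiber_set = c("A", "A", "A", "B", "B"),
    role = c("consumed", "produced", "consumed", "consumed", "consumed"),
    D = unname(params[c("d_glc", "d_lac", "d_o2", "d_epo", "d_scf")]),
    Vmax = c(unname(params[["vmax_glc"]]), NA, unname(params[["vmax_o2"]]),
             NA, NA),
    K_m = c(unname(params[["km_glc"]]), NA, unname(params[["km_o2"]]),
            NA, NA),
    # critical floors for consumed species; toxicity ceiling for lactate
    C_critical = c(1.0, 30, 0.02, NA, NA),
    stringsAsFactors = FALSE)
}

#' Default feasibility thresholds
#'
#' @param phi_max Maximum tolerated limited fraction per consumed species.
#' @param lac_ceiling Lactate toxicity ceiling (mol/m^3).
#' @param min_units Optional harvest demand floor (RBC units per campaign);
#'   default 0 (off).
#' @return Named list of thresholds.
#' @export
default_thresholds <- function(phi_max = 0.5, lac_ceiling = 30,
                               min_units = 0) {
  list(phi_max = phi_max, lac_ceiling = lac_ceiling, min_units = min_units)
}

# fixed non-registry constants of the campaign cost model
.hd_const <- list(
  cells_per_unit = 2e12,   # transfusion unit of RBC (configurable below)
  rho_ref = 1e6,           # reference density for the harvest flux law
  shell_cost = 0.01,       # amortized reactor shell, USD/reactor/campaign
  reservoir_mL = 5)        # recycle reservoir volume per loop, mL

#' Simulate one design over a culture campaign
#'
#' The coupled daily loop behind every design evaluation. Mass transfer is
#' treated as quasi-steady within each day (transport equilibrates in
#' minutes, kinetics evolve over days): set-A nutrient fields (Glc, O2) are
#' solved by the axial lumen balance, a lumped membrane resistance and the
#' zeroth-order Krogh annulus profile, iterated to a consistent uptake
#' rate; lactate is the mirrored produced species; growth factors in the
#' set-B recycle loop decay with their half-lives and are topped up to the
#' feed level daily (top-up mass priced at the registry unit price).
#' Cell kinetics then advance one day by explicit Euler with proliferation
#' attenuated by the nutrient-limited volume fraction, and produced RBC are
#' harvested through the set-B membrane at the cell-flux law
#' ([harvest_rate()]).
#'
#' All extensive quantities scale exactly linearly with `n_reactors`, so
#' cost per unit is invariant to pure parallelization.
#'
#' @param design An [hd_design()].
#' @param params Named numeric vector of realized parameter values.
#' @param preset Kinetics preset name or an `hd_kinetics` object.
#' @param thresholds Feasibility thresholds, see [default_thresholds()].
#' @param cells_per_unit Cells per transfusion unit of RBC (default 2e12).
#' @param seeding_split Initial fractions of seeded cells per compartment.
#' @return Object of class `hd_campaign`: `rbc_units`, `cost` (list
#'   `gf_epo`, `gf_scf`, `media`, `materials`, `total`,
#'   `cost_per_unit_rbc`), `feasibility` (character vector of violated
#'   constraints, empty if feasible), `phi_max` per species, `lac_max`,
#'   `harvested_cells`, `production_cells` (cumulative amplified inflow
#'   into the RBC compartment), `deaths_rbc`, `final_state`, and a daily
#'   `trajectory` data frame.
#' @export
simulate_campaign <- function(design, params = realize(default_registry()),
                              preset = "baseline_gf_model",
                              thresholds = default_thresholds(),
                              cells_per_unit = .hd_const$cells_per_unit,
                              seeding_split = c(HSC = 1, Prog = 0, RBC = 0)) {
  stopifnot(inherits(design, "hd_design"))
  kin <- if (inherits(preset, "hd_kinetics")) preset
         else kinetic_preset(preset, params)
  pf <- packing_fraction(design)
  if (pf > design$gamma_pack)
    return(.hd_infeasible_campaign(design, sprintf(
      "packing: fiber area fraction %.3f exceeds %.2f", pf,
      design$gamma_pack)))

  fa <- fiber_catalog(design$fiber_A); fb <- fiber_catalog(design$fiber_B)
  area_mm2 <- pi * design$reactor_radius^2
  L_mm <- design$reactor_length
  occ_mm2 <- design$n_fibers_A * pi * (fa$R_outer_um / 1000)^2 +
    design$n_fibers_B * pi * (fb$R_outer_um / 1000)^2
  V_scaffold_mL <- (area_mm2 - occ_mm2) * L_mm / 1000
  V_scaffold_m3 <- V_scaffold_mL * 1e-6
  # per-set Krogh geometry (each set independently tiles the cross-section)
  Rk_A <- krogh_radius(area_mm2, design$n_fibers_A) * 1e-3   # m
  Rk_B <- krogh_radius(area_mm2, design$n_fibers_B) * 1e-3
  Ro_A <- fa$R_outer_um * 1e-6; Ro_B <- fb$R_outer_um * 1e-6
  A_A_m2 <- design$n_fibers_A * 2 * pi * Ro_A * (L_mm * 1e-3)
  A_B_cm2 <- design$n_fibers_B * 2 * pi * (fb$R_outer_um * 1e-4) *
    (L_mm / 10)
  Q_m3s <- design$flow_per_fiber * 1e-9 / 60
  perm_scale <- unname(params[["perm_membrane"]]) / 20  # vs ceramic ref
  perm_A <- fa$perm_um_s * perm_scale * 1e-6  # m/s
  sp <- species_table(params)

  # growth factors: daily top-up, decay-averaged availability over the day
  gf_eff <- function(feed, t_half) {
    feed * t_half / log(2) * (1 - 2^(-1 / t_half))
  }
  t_half <- c(EPO = unname(params[["t_half_epo"]]),
              SCF = unname(params[["t_half_scf"]]))
  price <- c(EPO = unname(params[["price_epo"]]),
             SCF = unname(params[["price_scf"]]))
  V_loop_B_mL <- V_scaffold_mL + design$n_fibers_B *
    pi * (fb$R_lumen_um / 1000)^2 * L_mm / 1000 + .hd_const$reservoir_mL
  V_loop_A_mL <- V_scaffold_mL + design$n_fibers_A *
    pi * (fa$R_lumen_um / 1000)^2 * L_mm / 1000 + .hd_const$reservoir_mL

  state <- cell_state(design$seeding_density *
                        seeding_split[c("HSC", "Prog", "RBC")])
  harvested <- 0; production <- 0; deaths_rbc <- 0
  cost_gf <- c(EPO = 0, SCF = 0); cost_media <- 0
  phi_seen <- c(Glc = 0, O2 = 0, Lac = 0)
  lac_max_seen <- 0
  starved <- character(0)
  horizon <- as.integer(round(design$horizon))
  traj <- matrix(NA_real_, horizon, 5,
                 dimnames = list(NULL, c("day", "HSC", "Prog", "RBC",
                                         "harvested")))

  for (day in seq_len(horizon)) {
    rho_tot_m3 <- sum(state$density) * 1e6  # cells/m^3
    # --- set A consumed species: Glc, O2 ---
    phi_day <- c(Glc = 0, O2 = 0)
    mean_ann <- c(Glc = design$feeds[["Glc"]], O2 = design$feeds[["O2"]])
    # damped fixed point: local uptake depends on the local concentration,
    # which depends on the uptake; damping suppresses the oscillation the
    # anoxic clamp induces at high cell density
    for (s in c("Glc", "O2")) {
      row <- sp[sp$name == s, ]
      Cm <- mean_ann[[s]]
      for (iter in 1:20) {
        q_vol <- row$Vmax * rho_tot_m3 * Cm / (row$K_m + Cm)  # mol/m^3/s
        total_mol_s <- q_vol * V_scaffold_m3
        e_per_len <- total_mol_s / (design$n_fibers_A * L_mm * 1e-3)
        ax <- axial_lumen_profile(Q_m3s, design$feeds[[s]], e_per_len,
                                  L_mm * 1e-3)
        J_area <- total_mol_s / max(A_A_m2, 1e-300)
        C_wall <- max(ax$mean_C - J_area / max(perm_A, 1e-300), 0)
        rad <- radial_profile_zeroth_order(C_wall, q_vol, row$D, Ro_A, Rk_A)
        Cm_new <- 0.5 * Cm + 0.5 * rad$mean_C
        done <- abs(Cm_new - Cm) < 1e-4 * max(design$feeds[[s]], 1e-12)
        Cm <- Cm_new
        if (done) break
      }
      if (ax$starved) starved <- union(starved, s)
      phi_day[[s]] <- limited_fraction(rad, row$C_critical)
      mean_ann[[s]] <- rad$mean_C
    }
    # --- lactate production mirrors glucose uptake ---
    row_g <- sp[sp$name == "Glc", ]; row_l <- sp[sp$name == "Lac", ]
    q_glc <- row_g$Vmax * rho_tot_m3 * mean_ann[["Glc"]] /
      (row_g$K_m + mean_ann[["Glc"]])
    q_lac <- unname(params[["lac_yield"]]) * q_glc
    lac_lumen <- q_lac * V_scaffold_m3 /
      (design$n_fibers_A * Q_m3s) / 2  # mean lumen rise from zero feed
    rad_l <- radial_profile_zeroth_order(lac_lumen, -q_lac, row_l$D,
                                         Ro_A, Rk_A)
    phi_lac <- limited_fraction(rad_l, row_l$C_critical,
                                direction = "above")
    lac_max_seen <- max(lac_max_seen, max(rad_l$profile$C))
    phi_seen <- pmax(phi_seen, c(phi_day, Lac = phi_lac))

    # --- set B growth factors: decay-averaged level, top-up cost ---
    G <- c(EPO = gf_eff(design$feeds[["EPO"]], t_half[["EPO"]]),
           SCF = gf_eff(design$feeds[["SCF"]], t_half[["SCF"]]))
    topup_ng <- design$feeds[c("EPO", "SCF")] *
      (1 - 2^(-1 / t_half)) * V_loop_B_mL
    cost_gf <- cost_gf + unname(topup_ng) / 1000 * price  # ng -> ug
    cost_media <- cost_media +
      (V_loop_A_mL / 1000) * unname(params[["price_media"]])

    # --- kinetics: one day of Euler steps under today's environment ---
    limitation <- 1 - max(phi_day)
    sim <- simulate_kinetics(state, G, kin, t_end = 1, dt = kin$dt,
                             limitation = limitation)
    state <- sim$state
    production <- production + sim$inflow_rbc
    deaths_rbc <- deaths_rbc + sim$deaths[["RBC"]]

    # --- harvest through set-B membranes ---
    H <- harvest_rate(state$density[["RBC"]], A_B_cm2,
                      unname(params[["j_cells"]]), .hd_const$rho_ref)
    H <- min(H, state$density[["RBC"]] * V_scaffold_mL)
    dens <- state$density
    dens[["RBC"]] <- max(dens[["RBC"]] - H / V_scaffold_mL, 0)
    state <- cell_state(dens, state$time)
    harvested <- harvested + H
    traj[day, ] <- c(day, dens[["HSC"]], dens[["Prog"]], dens[["RBC"]], H)
  }

  materials <- design$n_fibers_A * unname(params[["cost_fiber_polymeric"]]) +
    design$n_fibers_B * unname(params[["cost_fiber_ceramic"]]) +
    .hd_const$shell_cost
  nR <- design$n_reactors
  cost <- list(gf_epo = unname(cost_gf[["EPO"]]) * nR,
               gf_scf = unname(cost_gf[["SCF"]]) * nR,
               media = cost_media * nR,
               materials = materials * nR)
  cost$total <- cost$gf_epo + cost$gf_scf + cost$media + cost$materials
  rbc_units <- harvested * nR / cells_per_unit
  cost$cost_per_unit_rbc <- if (rbc_units > 0) cost$total / rbc_units
                            else NA_real_

  res <- structure(list(
    design = design, rbc_units = rbc_units, cost = cost,
    phi_max = phi_seen, lac_max = lac_max_seen, starved = starved,
    harvested_cells = harvested * nR,
    production_cells = production * V_scaffold_mL * nR,
    deaths_rbc = deaths_rbc * V_scaffold_mL * nR,
    scaffold_mL = V_scaffold_mL,
    final_state = state,
    trajectory = as.data.frame(traj)), class = "hd_campaign")
  res$feasibility <- check_feasibility(design, res, thresholds)
  res
}

.hd_infeasible_campaign <- function(design, why) {
  structure(list(design = design, rbc_units = 0,
                 cost = list(gf_epo = 0, gf_scf = 0, media = 0,
                             materials = 0, total = 0,
                             cost_per_unit_rbc = NA_real_),
                 phi_max = c(Glc = NA, O2 = NA, Lac = NA),
                 lac_max = NA_real_, starved = character(0),
                 harvested_cells = 0, production_cells = 0,
                 deaths_rbc = 0, scaffold_mL = NA_real_,
                 final_state = NULL, trajectory = NULL,
                 feasibility = why), class = "hd_campaign")
}

#' Check feasibility of a campaign result
#'
#' Evaluates the named design constraints: cross-section packing, per-species
#' limited-fraction caps, the lactate toxicity ceiling, nutrient starvation,
#' a "no product" check, and an optional harvest demand floor. Violations
#' are reported by name; the optimizer decides how to handle them.
#'
#' @param design An `hd_design`.
#' @param result An `hd_campaign` from [simulate_campaign()].
#' @param thresholds See [default_thresholds()]; `phi_max` may be a single
#'   number or a named per-species vector.
#' @return Character vector of violation descriptions (empty if feasible).
#' @export
check_feasibility <- function(design, result,
                              thresholds = default_thresholds()) {
  v <- character(0)
  pf <- packing_fraction(design)
  if (pf > design$gamma_pack)
    v <- c(v, sprintf("packing: %.3f > %.2f", pf, design$gamma_pack))
  phim <- thresholds$phi_max
  for (s in c("Glc", "O2")) {
    lim <- if (length(phim) > 1) phim[[s]] else phim
    if (!is.na(result$phi_max[[s]]) && result$phi_max[[s]] > lim)
      v <- c(v, sprintf("limited_fraction_%s: %.3f > %.3f", s,
                        result$phi_max[[s]], lim))
  }
  if (!is.na(result$lac_max) && result$lac_max > thresholds$lac_ceiling)
    v <- c(v, sprintf("lactate_ceiling: %.2f > %.2f", result$lac_max,
                      thresholds$lac_ceiling))
  if (length(result$starved))
    v <- c(v, paste0("starvation: ", paste(result$starved, collapse = ",")))
  if (result$rbc_units <= 0)
    v <- c(v, "no product")
  if (!is.null(thresholds$min_units) && thresholds$min_units > 0 &&
      result$rbc_units < thresholds$min_units)
    v <- c(v, sprintf("harvest_floor: %.4g < %.4g units",
                      result$rbc_units, thresholds$min_units))
  v
}
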