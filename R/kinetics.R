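#' Hill-type growth-factor dependence of proliferation
#'
#' Proliferation rate as a saturating (Hill) function of the driving
#' growth-factor concentration: `beta_max * G^n / (theta^n + G^n)`.
#' With the default `n_hill = 1` this is a Monod/Michaelis form; larger
#' `n_hill` gives a switch-like response.
#'
#' @param G Growth-factor concentration (ng/mL), >= 0.
#' @param beta_max Maximum proliferation rate (1/day), >= 0.
#' @param theta Half-saturation concentration (ng/mL), > 0.
#' @param n_hill Hill coefficient (unitless), > 0. Default 1.
#' @return Proliferation rate in 1/day; equals `beta_max/2` at `G = theta`
#'   and 0 at `G = 0`; monotone nondecreasing in `G`.
#' @examples
#' proliferation_rate(G = 2, beta_max = 1, theta = 2)  # half-saturation
#' @export
proliferation_rate <- function(G, beta_max, theta, n_hill = 1) {
  if (any(theta <= 0)) stop("theta must be > 0", call. = FALSE)
  stopifnot(all(G >= 0), all(beta_max >= 0), all(n_hill > 0))
  gn <- G^n_hill
  beta_max * gn / (theta^n_hill + gn)
}

#' Exponential growth-factor decay
#'
#' Half-life decay `C0 * 2^(-t / t_half)`; the dominant driver of
#' growth-factor consumable cost over a culture campaign.
#'
#' @param C0 Initial concentration (ng/mL), >= 0.
#' @param t Elapsed time (days), >= 0.
#' @param t_half Half-life (days), > 0.
#' @return Concentration at time `t` (ng/mL).
#' @export
gf_decay <- function(C0, t, t_half) {
  stopifnot(all(C0 >= 0), all(t >= 0), all(t_half > 0))
  C0 * 2^(-t / t_half)
}

# Compartment chain used by the default model. HSC differentiate into a
# pooled progenitor compartment (Gran/Leuk lineages share kinetics in the
# default wiring; a 50/50 split is reported for 4-type metabolic
# bookkeeping), progenitors amplify into RBC.
hd_compartments <- c("HSC", "Prog", "RBC")

#' Kinetic parameter presets
#'
#' Builds a complete kinetic parameter set for the compartment chain
#' HSC -> progenitor (Gran/Leuk pooled) -> RBC from realized registry
#' values. Two presets are available:
#'
#' * `"baseline_gf_model"`: growth-factor-driven hematopoiesis; HSC
#'   proliferation driven by SCF, progenitor proliferation by EPO.
#' * `"suspension_2d_model"`: a pessimistic 2-D suspension-culture
#'   alternative used to bound performance; identical structure and
#'   nutrient demands but attenuated proliferation and amplification,
#'   so that cumulative RBC output never exceeds the baseline under
#'   identical inputs.
#'
#' @param name Preset name, one of `"baseline_gf_model"`,
#'   `"suspension_2d_model"`.
#' @param params Named numeric vector of realized parameter values
#'   (see [realize()]); defaults to registry nominals.
#' @param n_hill Hill coefficient for the growth-factor response.
#' @param dt Default Euler step (days).
#' @return An object of class `hd_kinetics`: per-compartment vectors
#'   `beta_max`, `theta`, `n_hill`, `kappa`, `delta`, `amp` (progeny per
#'   differentiating cell, applied to the flux into the next compartment),
#'   a `gf` driver map, `preset_name`, and `dt`.
#' @export
kinetic_preset <- function(name = c("baseline_gf_model", "suspension_2d_model"),
                           params = realize(default_registry()),
                           n_hill = 1, dt = 0.01) {
  if (!is.character(name) || !name[1] %in%
      c("baseline_gf_model", "suspension_2d_model"))
    stop("unknown kinetic preset: ", name[1], call. = FALSE)
  name <- name[1]
  # suspension culture bound: same proliferation and nutrient demand, but
  # weaker erythroid amplification (fewer RBC per differentiating
  # progenitor), a pessimistic output bound of order 15%
  att_beta <- 1
  att_amp  <- if (name == "suspension_2d_model") 0.85 else 1
  k <- list(
    compartments = hd_compartments,
    beta_max = c(HSC = unname(params[["beta_max_hsc"]]) * att_beta,
                 Prog = unname(params[["beta_max_prog"]]) * att_beta,
                 RBC = 0),
    theta = c(HSC = unname(params[["theta_scf"]]),
              Prog = unname(params[["theta_epo"]]),
              RBC = 1),
    n_hill = c(HSC = n_hill, Prog = n_hill, RBC = n_hill),
    kappa = c(HSC = unname(params[["kappa_hsc"]]),
              Prog = unname(params[["kappa_prog"]]),
              RBC = 0),
    delta = c(HSC = unname(params[["delta_hsc"]]),
              Prog = unname(params[["delta_prog"]]),
              RBC = unname(params[["delta_rbc"]])),
    amp = c(HSC = max(1, unname(params[["amp_hsc"]]) * att_amp),
            Prog = max(1, unname(params[["amp_prog"]]) * att_amp),
            RBC = 1),
    gf = c(HSC = "SCF", Prog = "EPO", RBC = "none"),
    preset_name = name,
    dt = dt
  )
  stopifnot(all(k$beta_max >= 0), all(k$kappa >= 0), all(k$delta >= 0),
            all(k$amp >= 1), all(k$theta > 0))
  class(k) <- "hd_kinetics"
  k
}

#' Construct a cell-compartment state
#'
#' @param density Named numeric vector of cell densities (cells/mL) for
#'   compartments `HSC`, `Prog`, `RBC`; nonnegative and finite.
#' @param time Simulation time (days).
#' @return Object of class `hd_state`.
#' @export
cell_state <- function(density = c(HSC = 0, Prog = 0, RBC = 0), time = 0) {
  stopifnot(all(hd_compartments %in% names(density)),
            all(is.finite(density)), all(density >= 0))
  structure(list(density = density[hd_compartments], time = time),
            class = "hd_state")
}

#' One explicit Euler step of the compartment model
#'
#' Advances `dN_c/dt = beta_c(G) N_c - kappa_c N_c - delta_c N_c +
#' A_{c-1} kappa_{c-1} N_{c-1}` by `dt`. Proliferation `beta_c(G)` is the
#' Hill response to the compartment's driving growth factor, optionally
#' attenuated by a nutrient-limitation factor (fraction of scaffold volume
#' that is not nutrient-limited). Densities that would undershoot zero are
#' clamped at zero with a warning; a step producing a relative change above
#' 50% in any compartment aborts with a step-size error.
#'
#' @param state An `hd_state`.
#' @param gf Named numeric vector of growth-factor concentrations (ng/mL),
#'   e.g. `c(EPO = 10, SCF = 50)`.
#' @param params An `hd_kinetics` preset.
#' @param dt Step size in days, > 0.
#' @param limitation Multiplier in `[0, 1]` applied to proliferation rates
#'   (1 = unlimited).
#' @return New `hd_state`; attribute `"fluxes"` holds the per-compartment
#'   amounts (cells/mL) moved this step: `growth`, `diff_out`, `death`,
#'   `inflow` (amplified differentiation inflow).
#' @export
kinetics_step <- function(state, gf, params, dt, limitation = 1) {
  stopifnot(inherits(state, "hd_state"), inherits(params, "hd_kinetics"),
            dt > 0, limitation >= 0, limitation <= 1)
  N <- state$density
  comps <- params$compartments
  beta <- vapply(comps, function(cc) {
    drv <- params$gf[[cc]]
    if (identical(drv, "none") || params$beta_max[[cc]] == 0) return(0)
    G <- if (drv %in% names(gf)) gf[[drv]] else 0
    proliferation_rate(G, params$beta_max[[cc]], params$theta[[cc]],
                       params$n_hill[[cc]])
  }, numeric(1)) * limitation

  growth   <- beta * N * dt
  diff_out <- params$kappa[comps] * N * dt
  death    <- params$delta[comps] * N * dt
  # amplified inflow: compartment c receives A_{c-1} * outflow of c-1
  inflow <- c(0, (params$amp[comps] * diff_out)[-length(comps)])
  names(inflow) <- comps

  # step-size guard on the compartment's own turnover: explicit Euler is
  # unreliable once rate * dt approaches 1; inflow from an upstream
  # compartment can legitimately dwarf a near-empty compartment and is
  # excluded from the check
  own_rate <- beta + params$kappa[comps] + params$delta[comps]
  if (any(own_rate * dt > 0.5))
    stop("kinetics step size too large: rate * dt = ",
         sprintf("%.2f", max(own_rate * dt)), " exceeds 0.5; reduce dt",
         call. = FALSE)
  Nn <- N + growth - diff_out - death + inflow
  if (any(Nn < 0)) {
    warning("cell density undershot zero; clamped", call. = FALSE)
    Nn <- pmax(Nn, 0)
  }
  out <- cell_state(Nn, state$time + dt)
  attr(out, "fluxes") <- list(growth = growth, diff_out = diff_out,
                              death = death, inflow = inflow)
  out
}

#' Simulate the compartment model over an interval
#'
#' Repeated [kinetics_step()] with fixed growth-factor concentrations;
#' a convenience used by tests and the campaign simulator.
#'
#' @inheritParams kinetics_step
#' @param t_end End time (days).
#' @param record If `TRUE`, return the full trajectory as a tidy data frame
#'   (`time`, `compartment`, `density`) in addition to the final state.
#' @return List with `state` (final `hd_state`), `inflow_rbc` (cumulative
#'   amplified inflow into the RBC compartment, cells/mL), `deaths`
#'   (cumulative per-compartment deaths), and optionally `trajectory`.
#' @export
simulate_kinetics <- function(state, gf, params, t_end,
                              dt = params$dt, limitation = 1,
                              record = FALSE) {
  n_steps <- max(1L, round(t_end / dt))
  dt <- t_end / n_steps
  comps <- params$compartments
  # growth factors are fixed over the interval, so the per-compartment
  # rates are constant and are computed once (same arithmetic as
  # kinetics_step, which remains the single-step reference path)
  beta <- vapply(comps, function(cc) {
    drv <- params$gf[[cc]]
    if (identical(drv, "none") || params$beta_max[[cc]] == 0) return(0)
    G <- if (drv %in% names(gf)) gf[[drv]] else 0
    proliferation_rate(G, params$beta_max[[cc]], params$theta[[cc]],
                       params$n_hill[[cc]])
  }, numeric(1)) * limitation
  kap <- params$kappa[comps]; del <- params$delta[comps]
  amp <- params$amp[comps]
  own_rate <- beta + kap + del
  if (any(own_rate * dt > 0.5))
    stop("kinetics step size too large: rate * dt = ",
         sprintf("%.2f", max(own_rate * dt)), " exceeds 0.5; reduce dt",
         call. = FALSE)
  N <- state$density[comps]
  nc <- length(comps)
  inflow_rbc <- 0
  deaths <- stats::setNames(numeric(nc), comps)
  clamped <- FALSE
  traj <- if (record) vector("list", n_steps + 1L) else NULL
  if (record) traj[[1L]] <- c(time = state$time, N)
  for (s in seq_len(n_steps)) {
    growth <- beta * N * dt
    diff_out <- kap * N * dt
    death <- del * N * dt
    inflow <- c(0, (amp * diff_out)[-nc])
    Nn <- N + growth - diff_out - death + inflow
    if (any(Nn < 0)) { clamped <- TRUE; Nn <- pmax(Nn, 0) }
    inflow_rbc <- inflow_rbc + unname(inflow[nc])
    deaths <- deaths + death
    N <- Nn
    if (record) traj[[s + 1L]] <- c(time = state$time + s * dt, N)
  }
  if (clamped) warning("cell density undershot zero; clamped",
                       call. = FALSE)
  names(N) <- comps
  out <- list(state = cell_state(N, state$time + t_end),
              inflow_rbc = inflow_rbc, deaths = deaths)
  if (record) {
    m <- do.call(rbind, traj)
    out$trajectory <- data.frame(
      time = rep(m[, "time"], times = length(hd_compartments)),
      compartment = rep(hd_compartments, each = nrow(m)),
      density = as.vector(m[, hd_compartments]))
  }
  out
}
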