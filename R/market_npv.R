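#' Net present value of a cash-flow schedule
#'
#' `NPV(i) = sum_t R_t / (1 + i)^t` over the schedule's `(t, R_t)` pairs.
#'
#' @param schedule Data frame with integer column `t` (year index, >= 0)
#'   and numeric column `amount` (USD; negative = outflow).
#' @param i Discount rate (fraction), must be > -1.
#' @return NPV in USD.
#' @examples
#' npv(data.frame(t = 1, amount = 100), i = 0.11)  # 90.09
#' @export
npv <- function(schedule, i) {
  if (i <= -1) stop("invalid rate: discount rate must be > -1",
                    call. = FALSE)
  stopifnot(all(c("t", "amount") %in% names(schedule)),
            all(schedule$t >= 0), all(schedule$t == round(schedule$t)))
  sum(schedule$amount / (1 + i)^schedule$t)
}

#' Rare-blood market size construction
#'
#' Builds the annual addressable market for bioreactor-produced rare blood
#' from three segments: (1) rare-blood usage, extrapolated from current US
#' usage by an availability multiplier and the First-World population
#' ratio; (2) hospital blood-bank shortages, the fraction of total annual
#' transfusion units corresponding to one shortage day at the affected
#' hospitals (`total * fraction / 365`); (3) a military security demand.
#'
#' @param base_us_units_per_yr Current US rare-blood usage (units/yr).
#' @param availability_multiplier Uplift for improved availability.
#' @param population_ratio First-World over US population.
#' @param total_transfusion_units_per_yr Total transfusion market
#'   (units/yr).
#' @param shortage_hospital_fraction Fraction of hospitals with at least
#'   one shortage day per year.
#' @param military_units_per_yr Military demand (units/yr).
#' @return List with `rare`, `shortage`, `military`, `total` (units/yr);
#'   `total` is the exact sum of the three segments.
#' @examples
#' rare_blood_market()$total  # about 1.32e5 units per year
#' @export
rare_blood_market <- function(base_us_units_per_yr = 1800,
                              availability_multiplier = 5,
                              population_ratio = 2.0e9 / 3.2e8,
                              total_transfusion_units_per_yr = 9.2e7,
                              shortage_hospital_fraction = 0.103,
                              military_units_per_yr = 5.0e4) {
  stopifnot(base_us_units_per_yr >= 0, availability_multiplier >= 0,
            population_ratio >= 0, total_transfusion_units_per_yr >= 0,
            shortage_hospital_fraction >= 0, military_units_per_yr >= 0)
  rare <- base_us_units_per_yr * availability_multiplier * population_ratio
  shortage <- total_transfusion_units_per_yr * shortage_hospital_fraction /
    365
  list(rare = rare, shortage = shortage, military = military_units_per_yr,
       total = rare + shortage + military_units_per_yr)
}

#' Construct a market scenario
#'
#' @param price Product price (USD/unit).
#' @param market_size Addressable market (units/yr).
#' @param share Captured market share, in `[0, 1]`.
#' @param success_prob Probability of clearing clinical trials, `[0, 1]`.
#' @param discount_rate Discount rate `i` (fraction), default 11%.
#' @param dev_cost_per_year Development outlay per year (USD), default
#'   $600k (four operators at $150k fully loaded).
#' @param dev_years Development years before revenue, default 2.
#' @param horizon Total horizon `N` in years, default 20.
#' @return Object of class `hd_scenario`.
#' @export
market_scenario <- function(price, market_size, share = 0.4,
                            success_prob = 0.104, discount_rate = 0.11,
                            dev_cost_per_year = 6e5, dev_years = 2L,
                            horizon = 20L) {
  s <- list(price = price, market_size = market_size, share = share,
            success_prob = success_prob, discount_rate = discount_rate,
            dev_cost_per_year = dev_cost_per_year,
            dev_years = as.integer(dev_years),
            horizon = as.integer(horizon))
  stopifnot(price >= 0, market_size >= 0, share >= 0, share <= 1,
            success_prob >= 0, success_prob <= 1,
            dev_cost_per_year >= 0, s$dev_years >= 0,
            s$horizon >= s$dev_years)
  class(s) <- "hd_scenario"
  s
}

#' Discounted payout of a market scenario
#'
#' Cash-flow conventions (declared defaults, configurable):
#' flows occur at year end (`t = 1 .. N`); years `1..dev_years` carry the
#' development outflow; years `dev_years+1 .. N` carry the revenue
#' `price * market_size * share`, weighted by the success probability;
#' development costs are committed regardless of trial outcome and are not
#' success-weighted.
#'
#' @param scenario An [market_scenario()].
#' @param weight_dev_by_success Alternative convention: also weight the
#'   development outflow by `success_prob`.
#' @return List with `npv` (USD) and the full `schedule` data frame.
#' @export
scenario_payout <- function(scenario, weight_dev_by_success = FALSE) {
  stopifnot(inherits(scenario, "hd_scenario"))
  s <- scenario
  t_dev <- seq_len(s$dev_years)
  t_rev <- if (s$horizon > s$dev_years)
    (s$dev_years + 1L):s$horizon else integer(0)
  dev_w <- if (weight_dev_by_success) s$success_prob else 1
  sched <- rbind(
    if (length(t_dev)) data.frame(t = t_dev,
                                  amount = -s$dev_cost_per_year * dev_w),
    if (length(t_rev)) data.frame(
      t = t_rev,
      amount = s$price * s$market_size * s$share * s$success_prob))
  list(npv = npv(sched, s$discount_rate), schedule = sched)
}

#' Bioreactor fabrication and culture labor table
#'
#' The default table lists every fabrication, culture and analysis
#' activity with its duration in days and hours of hands-on work per day;
#' person-days follow the 8-hour-day rule
#' `person_days = days * hours_per_day / 8`.
#'
#' @return Data frame `stage`, `activity`, `days`, `hours_per_day`.
#' @export
labor_table_default <- function() {
  data.frame(
    stage = c("fiber_creation", "fiber_creation",
              "bioreactor_fabrication", "bioreactor_fabrication",
              "precondition_and_culture", "precondition_and_culture",
              "precondition_and_culture", "precondition_and_culture",
              "precondition_and_culture", "terminal_analyses"),
    activity = c("fiber_milling_extrusion", "fiber_sintering",
                 "fiber_potting", "scaffold_formation",
                 "coating", "sterilization", "conditioning", "seeding",
                 "culture", "terminal_analyses"),
    days = c(5, 4, 1, 11, 3, 1, 3, 1, 35, 5),
    hours_per_day = c(5, 1, 4, 1, 4, 11, 0.5, 14, 2, 6),
    stringsAsFactors = FALSE)
}

#' Labor totals under the 8-hour person-day rule
#'
#' @param table Labor table as from [labor_table_default()]; columns
#'   `days`, `hours_per_day` required, optional `stage` for subtotals.
#' @return List with `total_days`, `total_person_days`, `by_activity`
#'   (input plus a `person_days` column) and, when `stage` is present,
#'   `by_stage` subtotals.
#' @examples
#' labor_totals(labor_table_default())$total_person_days  # 22.8125
#' @export
labor_totals <- function(table) {
  stopifnot(all(c("days", "hours_per_day") %in% names(table)),
            all(table$days >= 0), all(table$hours_per_day >= 0))
  if (nrow(table) == 0)
    return(list(total_days = 0, total_person_days = 0,
                by_activity = table))
  table$person_days <- table$days * table$hours_per_day / 8
  out <- list(total_days = sum(table$days),
              total_person_days = sum(table$person_days),
              by_activity = table)
  if ("stage" %in% names(table)) {
    ag <- aggregate(cbind(days, person_days) ~ stage, table, sum)
    out$by_stage <- ag[match(unique(table$stage), ag$stage), ]
    rownames(out$by_stage) <- NULL
  }
  out
}

#' Experiments per operator-year
#'
#' One operator runs bioreactor experiments in duplicate on a fixed cycle;
#' the number of new experiments per year is `floor(year_days /
#' cycle_days)`.
#'
#' @param cycle_days Days per experiment cycle (default 48).
#' @param year_days Days per year (default 365).
#' @return Integer count.
#' @examples
#' experiments_per_operator_year(48)  # 7
#' @export
experiments_per_operator_year <- function(cycle_days = 48,
                                          year_days = 365) {
  stopifnot(cycle_days > 0, year_days >= 0)
  as.integer(floor(year_days / cycle_days))
}

#' Size of a response-surface characterization campaign
#'
#' Number of experiments to map an `n_factors`-dimensional response
#' surface; a corner-point (two-level full factorial) design needs `2^n`
#' runs. For the five free design decisions (seeding density and four feed
#' concentrations) this is 32 — "on the order of 30" experiments.
#'
#' @param n_factors Number of design factors, >= 1.
#' @param design Design type; only `"corner_points"` is implemented.
#' @return Integer experiment count.
#' @export
design_campaign_size <- function(n_factors = 5,
                                 design = c("corner_points")) {
  design <- match.arg(design)
  stopifnot(n_factors >= 1)
  as.integer(2^n_factors)
}

#' Development cost per year
#'
#' @param n_operators Operators employed (default 4).
#' @param cost_per_operator Fully loaded cost per operator-year, including
#'   lab and materials (USD, default $150k).
#' @return USD per year.
#' @export
dev_cost_per_year <- function(n_operators = 4, cost_per_operator = 1.5e5) {
  stopifnot(n_operators >= 0, cost_per_operator >= 0)
  n_operators * cost_per_operator
}
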