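#' Hollow-fiber geometry catalog
#'
#' Geometry and membrane properties for the two fiber families of the dual
#' hollow-fiber bioreactor: polymeric fibers (set A: nutrient supply and
#' waste removal) and ceramic fibers (set B: growth-factor recycling and
#' cell harvest). Dimensions are stored in micrometres and converted to SI
#' internally by the solvers.
#'
#' @param id Catalog id, `"polymeric_standard"` or `"ceramic_standard"`.
#' @return List of class `hd_fiber`: `R_lumen_um`, `R_outer_um`,
#'   `fiber_type`, `perm_um_s` (reference membrane permeability).
#' @export
fiber_catalog <- function(id = c("polymeric_standard", "ceramic_standard")) {
  cat <- list(
    polymeric_standard = list(R_lumen_um = 300, R_outer_um = 400,
                              fiber_type = "polymeric", perm_um_s = 50),
    ceramic_standard   = list(R_lumen_um = 250, R_outer_um = 350,
                              fiber_type = "ceramic", perm_um_s = 20))
  if (!is.character(id) || !id[1] %in% names(cat))
    stop("unknown fiber catalog id: ", id[1], call. = FALSE)
  structure(cat[[id[1]]], class = "hd_fiber", id = id[1])
}

#' Krogh radius for an evenly tiled cross-section
#'
#' Under the Krogh approximation each fiber serves an exclusive concentric
#' cylinder of tissue; with `n_fibers` evenly distributed over a
#' cross-section of the given area, `R_k = sqrt(area / (pi * n_fibers))`.
#'
#' @param cross_section_area Cross-section area (mm^2), > 0.
#' @param n_fibers Number of fibers, integer >= 1.
#' @return Krogh radius in mm.
#' @examples
#' krogh_radius(pi, 1)          # 1 mm
#' 1 / krogh_radius(1 / 0.2, 1)^2 / pi  # fiber density 0.2 / mm^2
#' @export
krogh_radius <- function(cross_section_area, n_fibers) {
  if (length(n_fibers) != 1L || n_fibers < 1)
    stop("invalid design: n_fibers must be >= 1", call. = FALSE)
  stopifnot(cross_section_area > 0)
  sqrt(cross_section_area / (pi * n_fibers))
}

#' Analytic zeroth-order Krogh annulus profile
#'
#' Steady radial concentration in the Krogh annulus for constant
#' (zeroth-order) volumetric consumption `q0`:
#' `C(r) = C_wall + q0/(4 D) (r^2 - R_outer^2) - q0 R_krogh^2/(2 D)
#' log(r / R_outer)`, with Dirichlet `C_wall` at the fiber outer wall and
#' zero flux at the Krogh radius. Where the expression crosses zero the
#' profile is truncated at zero and an anoxic-region flag is raised
#' (constant consumption cannot be sustained there).
#'
#' For a produced species pass a negative `q0`: the profile then rises away
#' from the fiber.
#'
#' @param C_wall Concentration at the fiber outer wall (mol/m^3).
#' @param q0 Volumetric consumption rate (mol/m^3/s); negative = production.
#' @param D Diffusivity in the scaffold (m^2/s), > 0.
#' @param R_outer Fiber outer radius (m), < `R_krogh`.
#' @param R_krogh Krogh radius (m).
#' @param n_r Number of radial grid points (default 101).
#' @return Object of class `hd_radial`: data frame `profile` (`r`, `C`),
#'   logical `anoxic`, `mean_C` (volume-weighted mean), and the geometry.
#' @export
radial_profile_zeroth_order <- function(C_wall, q0, D, R_outer, R_krogh,
                                        n_r = 101) {
  if (!(D > 0)) stop("invalid geometry: D must be > 0", call. = FALSE)
  if (!(R_outer < R_krogh) || R_outer <= 0)
    stop("invalid geometry: need 0 < R_outer < R_krogh", call. = FALSE)
  r <- seq(R_outer, R_krogh, length.out = n_r)
  C <- C_wall + q0 / (4 * D) * (r^2 - R_outer^2) -
    q0 * R_krogh^2 / (2 * D) * log(r / R_outer)
  anoxic <- any(C < 0)
  C <- pmax(C, 0)
  structure(list(profile = quick_df(r = r, C = C),
                 anoxic = anoxic,
                 mean_C = radial_mean(r, C),
                 R_outer = R_outer, R_krogh = R_krogh),
            class = "hd_radial")
}

# data.frame constructor without the validation overhead; columns are
# known-good equal-length numeric vectors
quick_df <- function(...) {
  df <- list(...)
  attr(df, "row.names") <- c(NA_integer_, -length(df[[1]]))
  class(df) <- "data.frame"
  df
}

# volume-weighted (2 pi r dr) mean over a radial grid
radial_mean <- function(r, C) {
  w <- r
  sum(diff(r) * (w[-1] * C[-1] + w[-length(w)] * C[-length(C)]) / 2) /
    sum(diff(r) * (w[-1] + w[-length(w)]) / 2)
}

#' Michaelis-Menten radial annulus profile (numeric)
#'
#' Solves the steady reaction-diffusion two-point boundary value problem
#' `1/r d/dr (r D dC/dr) = Vrho C / (K_m + C)` on the Krogh annulus with
#' Dirichlet `C_wall` at the fiber wall and no flux at the Krogh radius,
#' by second-order finite differences with Picard linearization of the
#' uptake term.
#'
#' @inheritParams radial_profile_zeroth_order
#' @param Vrho Volumetric maximum uptake `V_max * cell_density`
#'   (mol/m^3/s), >= 0.
#' @param K_m Michaelis constant (mol/m^3), > 0.
#' @param tol Picard convergence tolerance on the max absolute update.
#' @param max_iter Maximum Picard iterations.
#' @return An `hd_radial` object (see [radial_profile_zeroth_order()]).
#' @export
radial_profile_mm <- function(C_wall, Vrho, K_m, D, R_outer, R_krogh,
                              n_r = 101, tol = 1e-12, max_iter = 200) {
  if (!(D > 0) || !(K_m > 0)) stop("invalid parameter: D, K_m must be > 0",
                                   call. = FALSE)
  if (!(R_outer < R_krogh) || R_outer <= 0)
    stop("invalid geometry: need 0 < R_outer < R_krogh", call. = FALSE)
  stopifnot(Vrho >= 0, C_wall >= 0)
  r <- seq(R_outer, R_krogh, length.out = n_r)
  h <- r[2] - r[1]
  C <- rep(C_wall, n_r)
  for (iter in seq_len(max_iter)) {
    a <- Vrho / (D * (K_m + C))  # linearized reaction coefficient (1/m^2)
    # tridiagonal system, finite-volume discretization of (1/r)(r C')' = a C
    lo <- numeric(n_r - 1); di <- numeric(n_r); up <- numeric(n_r - 1)
    b <- numeric(n_r)
    di[1] <- 1; b[1] <- C_wall  # Dirichlet at fiber wall
    rp <- r + h / 2; rm <- r - h / 2
    i <- 2:(n_r - 1)
    lo[i - 1] <- rm[i] / (r[i] * h^2)
    up[i]     <- rp[i] / (r[i] * h^2)
    di[i]     <- -(rm[i] + rp[i]) / (r[i] * h^2) - a[i]
    # no-flux at R_krogh: outer face flux = 0 over the half control
    # volume of width h/2 at the last node
    di[n_r] <- -2 * rm[n_r] / (r[n_r] * h^2) - a[n_r]
    lo[n_r - 1] <- 2 * rm[n_r] / (r[n_r] * h^2)
    M <- Matrix::bandSparse(n_r, n_r, k = -1:1,
                            diagonals = list(lo, di, up))
    Cn <- as.numeric(Matrix::solve(M, b))
    delta <- max(abs(Cn - C))
    C <- pmax(Cn, 0)
    if (delta < tol * max(C_wall, 1e-300)) break
  }
  if (delta >= tol * max(C_wall, 1e-300) && delta > 1e-9 * max(C_wall, 1e-300))
    stop(sprintf("radial MM solver did not converge: residual %.3e", delta),
         call. = FALSE)
  structure(list(profile = quick_df(r = r, C = C),
                 anoxic = any(C <= 0),
                 mean_C = radial_mean(r, C),
                 R_outer = R_outer, R_krogh = R_krogh),
            class = "hd_radial")
}

#' Cross-section-averaged axial lumen profile
#'
#' Plug-flow balance of the Poiseuille lumen stream:
#' `dC/dz = -e(z) / Q`, where `e(z)` is the per-length extraction rate into
#' the scaffold. Integrated by the trapezoid rule on a uniform z-grid;
#' concentrations are clamped at zero with a starvation flag if extraction
#' exceeds the available mass, in which case the realized extraction is
#' reduced accordingly.
#'
#' @param Q Volumetric flow per fiber (m^3/s), > 0.
#' @param C_in Inlet concentration (mol/m^3).
#' @param extraction Either a function of `z` (per-length extraction,
#'   mol/m/s) or a numeric vector on the z-grid.
#' @param L Fiber length (m).
#' @param n_z Number of axial grid points (default 101).
#' @return Object of class `hd_axial`: data frame `profile` (`z`, `C`),
#'   `outlet`, `mean_C`, `extracted` (realized total extraction, mol/s),
#'   `starved` flag.
#' @export
axial_lumen_profile <- function(Q, C_in, extraction, L, n_z = 101) {
  stopifnot(Q > 0, C_in >= 0, L > 0)
  z <- seq(0, L, length.out = n_z)
  e <- if (is.function(extraction)) vapply(z, extraction, numeric(1))
       else rep_len(extraction, n_z)
  # cumulative trapezoid of e over z
  cum <- c(0, cumsum(diff(z) * (e[-1] + e[-n_z]) / 2))
  C <- C_in - cum / Q
  starved <- any(C < 0)
  if (starved) {
    C <- pmax(C, 0)
    # realized extraction limited by available mass
    extracted <- (C_in - C[n_z]) * Q
  } else {
    extracted <- cum[n_z]
  }
  structure(list(profile = quick_df(z = z, C = C),
                 outlet = C[n_z],
                 mean_C = mean(C),
                 extracted = extracted,
                 starved = starved),
            class = "hd_axial")
}

#' Limited fraction of the annulus volume
#'
#' Volume-weighted fraction of the Krogh annulus in which the species falls
#' below its critical concentration (`direction = "below"`, consumed
#' species) or exceeds a toxicity ceiling (`direction = "above"`, produced
#' species such as lactate).
#'
#' @param solution An `hd_radial` solution.
#' @param C_critical Critical concentration (mol/m^3).
#' @param direction `"below"` or `"above"`.
#' @return Limited fraction `phi` in `[0, 1]`.
#' @export
limited_fraction <- function(solution, C_critical, direction = "below") {
  stopifnot(inherits(solution, "hd_radial"))
  direction <- match.arg(direction, c("below", "above"))
  r <- solution$profile$r; C <- solution$profile$C
  lim <- if (direction == "below") C < C_critical else C > C_critical
  w <- r
  num <- sum(diff(r) * (w[-1] * lim[-1] + w[-length(w)] * lim[-length(lim)]) / 2)
  den <- sum(diff(r) * (w[-1] + w[-length(w)]) / 2)
  phi <- num / den
  min(max(phi, 0), 1)
}

#' Trans-membrane cell harvest rate
#'
#' Produced RBC exit the scaffold through the ceramic (set-B) fiber
#' membranes. The harvest rate is linear in the flux coefficient, the
#' membrane area, and the RBC density relative to a reference density:
#' `rate = J_cells * area * (rho_rbc / rho_ref)`.
#'
#' @param rho_rbc RBC density in the scaffold (cells/mL), >= 0.
#' @param membrane_area Set-B membrane area (cm^2), >= 0.
#' @param J_cells Flux coefficient (cells/cm^2/day), >= 0.
#' @param rho_ref Reference density (cells/mL), default 1e6.
#' @return Harvest rate in cells/day. Removal from the RBC compartment is
#'   the caller's responsibility.
#' @export
harvest_rate <- function(rho_rbc, membrane_area, J_cells, rho_ref = 1e6) {
  stopifnot(rho_rbc >= 0, membrane_area >= 0, J_cells >= 0, rho_ref > 0)
  J_cells * membrane_area * (rho_rbc / rho_ref)
}
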