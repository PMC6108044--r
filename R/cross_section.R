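#' Random and even cross-section fiber layouts
#'
#' `sample_layout()` draws a random sequential placement of `n_fibers`
#' non-overlapping fibers inside a circular reactor cross-section,
#' reproducible per seed (the global RNG state is preserved).
#' `even_layout()` returns a deterministic evenly spaced reference layout:
#' one centered fiber for `n_fibers = 1`, otherwise a ring at 0.55 of the
#' reactor radius (near the centroids of equal angular sectors).
#'
#' @param n_fibers Number of fibers, >= 1.
#' @param reactor_radius Reactor cross-section radius (mm).
#' @param fiber_radius Fiber outer radius (mm).
#' @param min_gap Minimum clearance between fiber walls and to the reactor
#'   wall (mm).
#' @param seed Integer RNG seed (required for `sample_layout`).
#' @param max_tries Maximum rejection-sampling attempts per fiber.
#' @return Object of class `hd_layout`: `reactor_radius`, `fiber_radius`,
#'   `centers` (n x 2 matrix, mm), `seed`, and `density` (fibers/mm^2).
#' @export
sample_layout <- function(n_fibers, reactor_radius, fiber_radius = 0.35,
                          min_gap = 0.1, seed, max_tries = 10000L) {
  if (missing(seed) || is.null(seed))
    stop("sample_layout requires an explicit seed", call. = FALSE)
  stopifnot(n_fibers >= 1, reactor_radius > fiber_radius + min_gap)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  r_max <- reactor_radius - fiber_radius - min_gap
  centers <- matrix(NA_real_, n_fibers, 2)
  for (k in seq_len(n_fibers)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      # uniform in the admissible disc
      rr <- r_max * sqrt(stats::runif(1))
      th <- stats::runif(1, 0, 2 * pi)
      p <- c(rr * cos(th), rr * sin(th))
      ok <- TRUE
      if (k > 1) {
        d <- sqrt(rowSums((centers[seq_len(k - 1), , drop = FALSE] -
                             matrix(p, k - 1, 2, byrow = TRUE))^2))
        ok <- all(d >= 2 * fiber_radius + min_gap)
      }
      if (ok) { centers[k, ] <- p; placed <- TRUE; break }
    }
    if (!placed)
      stop("infeasible packing: could not place fiber ", k, " after ",
           max_tries, " tries", call. = FALSE)
  }
  new_layout(reactor_radius, fiber_radius, centers, seed)
}

#' @rdname sample_layout
#' @export
even_layout <- function(n_fibers, reactor_radius, fiber_radius = 0.35) {
  stopifnot(n_fibers >= 1, reactor_radius > fiber_radius)
  if (n_fibers == 1L) {
    centers <- matrix(0, 1, 2)
  } else {
    r0 <- 0.55 * reactor_radius
    th <- 2 * pi * (seq_len(n_fibers) - 1) / n_fibers
    centers <- cbind(r0 * cos(th), r0 * sin(th))
  }
  new_layout(reactor_radius, fiber_radius, centers, seed = NA_integer_)
}

new_layout <- function(reactor_radius, fiber_radius, centers, seed) {
  structure(list(reactor_radius = reactor_radius,
                 fiber_radius = fiber_radius,
                 centers = centers, seed = seed,
                 density = nrow(centers) / (pi * reactor_radius^2)),
            class = "hd_layout")
}

#' Steady diffusion-consumption field on an explicit cross-section
#'
#' Solves `D lap(C) = q(C)` on the scaffold region of a reactor
#' cross-section with arbitrary fiber placement: Dirichlet `C_fiber_wall`
#' on every fiber boundary (Shortley-Weller fractional-spacing stencil for
#' second-order boundary accuracy), zero flux on the reactor wall, 5-point
#' stencil in the interior, assembled sparse and solved directly. Nonlinear
#' Michaelis-Menten uptake and the anoxic cut-off of constant uptake are
#' handled by Picard iteration.
#'
#' @param layout An `hd_layout` cross-section (dimensions in mm).
#' @param D Scaffold diffusivity (m^2/s).
#' @param q Consumption model: either a single number (constant volumetric
#'   rate, mol/m^3/s, switched off where the field is exhausted) or a list
#'   `list(Vrho = ..., K_m = ...)` for Michaelis-Menten uptake.
#' @param C_fiber_wall Dirichlet concentration on fiber walls (mol/m^3).
#' @param h Grid spacing (mm).
#' @param max_picard Maximum Picard iterations for nonlinear uptake.
#' @param tol Relative Picard tolerance.
#' @return Object of class `hd_field`: `x`, `y` grid vectors (mm), matrix
#'   `C` (NA outside the scaffold region), `h`, the `layout`, and
#'   `n_unknowns`.
#' @export
solve_field <- function(layout, D, q, C_fiber_wall, h,
                        max_picard = 300L, tol = 1e-10) {
  stopifnot(inherits(layout, "hd_layout"), D > 0, C_fiber_wall >= 0, h > 0)
  R <- layout$reactor_radius
  hm <- h * 1e-3  # grid spacing in metres for the physics
  x <- seq(-R, R, by = h)
  y <- x
  nx <- length(x); ny <- length(y)
  X <- matrix(x, nx, ny); Y <- matrix(y, nx, ny, byrow = TRUE)
  rad2 <- X^2 + Y^2
  in_reactor <- rad2 < R^2
  in_fiber <- matrix(FALSE, nx, ny)
  nearest_fiber <- matrix(0L, nx, ny)
  for (f in seq_len(nrow(layout$centers))) {
    d2 <- (X - layout$centers[f, 1])^2 + (Y - layout$centers[f, 2])^2
    hit <- d2 <= layout$fiber_radius^2
    in_fiber <- in_fiber | hit
    nearest_fiber[hit] <- f
  }
  unknown <- in_reactor & !in_fiber
  idx <- matrix(0L, nx, ny)
  idx[unknown] <- seq_len(sum(unknown))
  n <- sum(unknown)
  if (n == 0L) stop("no scaffold nodes at this grid spacing", call. = FALSE)

  # neighbour maps: nb[i, j] = M[i + di, j + dj], padded at the frame
  shift <- function(M, di, dj, fill) {
    out <- matrix(fill, nx, ny)
    xs <- max(1, 1 - di):min(nx, nx - di)
    ys <- max(1, 1 - dj):min(ny, ny - dj)
    out[xs, ys] <- M[xs + di, ys + dj]
    out
  }
  shifts <- list(L = c(-1L, 0L), R = c(1L, 0L), D = c(0L, -1L), U = c(0L, 1L))
  nb_unknown <- lapply(shifts, function(d)
    shift(unknown, d[1], d[2], FALSE))
  nb_idx <- lapply(shifts, function(d) shift(idx, d[1], d[2], 0L))
  nb_fiber <- lapply(shifts, function(d) shift(in_fiber, d[1], d[2], FALSE))
  nb_react <- lapply(shifts, function(d) shift(in_reactor, d[1], d[2], FALSE))

  wall_band <- unknown & rad2 > (R - 1.5 * h)^2
  regular <- unknown & !wall_band
  for (s in names(shifts)) regular <- regular & nb_unknown[[s]]

  inv_h2 <- 1 / hm^2
  kreg <- idx[regular]
  ti <- c(kreg, kreg, unlist(lapply(names(shifts), function(s) kreg)))
  tj <- c(kreg, kreg, unlist(lapply(names(shifts), function(s)
    nb_idx[[s]][regular])))
  # diagonal split into two entries of -2/h^2 keeps the c() shapes aligned
  tv <- c(rep(-2 * inv_h2, 2 * length(kreg)),
          rep(inv_h2, 4L * length(kreg)))
  bdir <- numeric(n)

  # irregular unknown nodes: near a fiber the Dirichlet wall uses a
  # Shortley-Weller fractional-spacing stencil; at the reactor wall an
  # exterior neighbour is replaced by a mirror ghost -- its value is taken
  # at the radial reflection of the ghost point across the circular wall
  # (bilinear interpolation from interior nodes), which imposes the
  # zero-normal-flux condition on the true circle to second order
  irr <- which(unknown & !regular, arr.ind = TRUE)
  src_scale <- rep(1, n)
  if (nrow(irr)) {
    cap <- 128L * nrow(irr)
    ei <- integer(cap); ej <- integer(cap); ev <- numeric(cap); m <- 0L

    # quadratic least-squares interpolation weights at an interior point;
    # candidates surround the point, so this is stable interpolation with
    # O(h^3) error
    interp_at <- function(px0, py0) {
      i0 <- floor((px0 - x[1]) / h) + 1
      j0 <- floor((py0 - y[1]) / h) + 1
      is <- max(1, i0 - 1):min(nx, i0 + 2)
      js <- max(1, j0 - 1):min(ny, j0 + 2)
      cand <- as.matrix(expand.grid(i = is, j = js))
      kc <- idx[cand]
      keep <- kc > 0L
      if (sum(keep) < 3L) {
        if (!any(keep)) return(NULL)
        d2 <- (x[cand[keep, 1]] - px0)^2 + (y[cand[keep, 2]] - py0)^2
        return(list(k = kc[keep][which.min(d2)], w = 1))
      }
      xi <- (x[cand[keep, 1]] - px0) / h
      yi <- (y[cand[keep, 2]] - py0) / h
      W <- exp(-(xi^2 + yi^2))
      A <- if (sum(keep) >= 8L) cbind(1, xi, yi, xi^2, xi * yi, yi^2)
           else cbind(1, xi, yi)
      AtW <- t(A * W)
      Mp <- AtW %*% A + diag(c(0, rep(1e-8, ncol(A) - 1)))
      wts <- as.numeric(solve(Mp, AtW)[1, ])
      list(k = kc[keep], w = wts)
    }

    # ghost closure at the circular no-flux wall: the radial profile
    # through the ghost is modelled as c0 + c2 s^2 + c3 s^3 in the signed
    # wall distance s (the linear term vanishes because the normal flux
    # is zero), fitted through three interior samples at s = -h, -2h, -3h
    # and evaluated at the ghost's s > 0. The closure error is O(h^4)
    # before the 1/h flux amplification, keeping the field second order.
    Minv_ghost <- solve(matrix(c(1, 1, 1, 1, 4, 9, -1, -8, -27), 3, 3))
    mirror_entries <- function(gx, gy) {
      rg <- sqrt(gx^2 + gy^2)
      ux <- gx / rg; uy <- gy / rg
      sg <- (rg - R) / h  # ghost wall distance in units of h
      alpha <- as.numeric(c(1, sg^2, sg^3) %*% Minv_ghost)
      ks <- integer(0); ws <- numeric(0)
      for (k3 in 1:3) {
        pk <- interp_at((R - k3 * h) * ux, (R - k3 * h) * uy)
        if (is.null(pk)) return(NULL)
        ks <- c(ks, pk$k); ws <- c(ws, alpha[k3] * pk$w)
      }
      list(k = ks, w = ws)
    }

    for (kk in seq_len(nrow(irr))) {
      ii <- irr[kk, 1]; jj <- irr[kk, 2]
      k <- idx[ii, jj]
      px <- x[ii]; py <- y[jj]
      diag_acc <- 0
      for (axis in 1:2) {
        sn <- if (axis == 1) c("L", "R") else c("D", "U")
        side <- vector("list", 2)
        for (s2 in 1:2) {
          nm <- sn[s2]
          d <- shifts[[nm]]
          if (nb_unknown[[nm]][ii, jj]) {
            side[[s2]] <- list(type = "U", sp = hm,
                               k2 = nb_idx[[nm]][ii, jj], w = 1)
          } else if (nb_fiber[[nm]][ii, jj]) {
            i2 <- ii + d[1]; j2 <- jj + d[2]
            f <- nearest_fiber[i2, j2]
            th <- .theta_to_circle(px, py, d[1], d[2], h,
                                   layout$centers[f, 1],
                                   layout$centers[f, 2],
                                   layout$fiber_radius)
            side[[s2]] <- list(type = "D", sp = th * hm)
          } else {
            me <- mirror_entries(px + d[1] * h, py + d[2] * h)
            if (is.null(me)) side[[s2]] <- list(type = "N")
            else side[[s2]] <- list(type = "U", sp = hm,
                                    k2 = me$k, w = me$w)
          }
        }
        tl <- side[[1]]$type; tr <- side[[2]]$type
        add_side <- function(s, coef) {
          if (s$type == "U") {
            for (e in seq_along(s$k2)) {
              m <<- m + 1L; ei[m] <<- k; ej[m] <<- s$k2[e]
              ev[m] <<- coef * s$w[e]
            }
          } else bdir[k] <<- bdir[k] + coef
        }
        if (tl == "N" && tr == "N") next
        if (tl == "N" || tr == "N") {
          s <- if (tl == "N") side[[2]] else side[[1]]
          coef <- 1 / (s$sp * hm)
          diag_acc <- diag_acc - coef
          add_side(s, coef)
        } else {
          hl <- side[[1]]$sp; hr <- side[[2]]$sp
          cl <- 2 / (hl * (hl + hr)); cr <- 2 / (hr * (hl + hr))
          diag_acc <- diag_acc - (cl + cr)
          add_side(side[[1]], cl)
          add_side(side[[2]], cr)
        }
      }
      m <- m + 1L; ei[m] <- k; ej[m] <- k; ev[m] <- diag_acc
    }
    ti <- c(ti, ei[seq_len(m)]); tj <- c(tj, ej[seq_len(m)])
    tv <- c(tv, ev[seq_len(m)])
  }
  A_lap <- Matrix::sparseMatrix(i = ti, j = tj, x = tv, dims = c(n, n))
  b_base <- -bdir * C_fiber_wall  # Dirichlet terms moved to RHS

  # Constant uptake is first attempted as a single exact linear solve; if
  # part of the domain would be driven negative (anoxic), the cut-off is
  # regularized as Michaelis-Menten uptake with a half-saturation far
  # below any critical threshold (the reaction interface it smears is
  # much thinner than a grid cell), which the semi-implicit Picard
  # iteration handles robustly.
  mm <- is.list(q)
  if (!mm) {
    Cn <- as.numeric(Matrix::solve(A_lap, b_base + src_scale * (q / D)))
    if (all(Cn >= -1e-12 * max(C_fiber_wall, 1)))
      return(.hd_field(x, y, Cn, unknown, h, layout, n))
    q <- list(Vrho = q, K_m = 1e-3 * max(C_fiber_wall, 1e-12))
  }
  # Newton iteration on F(C) = A_lap C - s (Vrho/D) C/(K_m + C) - b_base,
  # with clamping at zero and step halving as a safeguard
  Vd <- src_scale * q$Vrho / D
  resid <- function(C) as.numeric(A_lap %*% C) - Vd * C / (q$K_m + C) -
    b_base
  Cv <- pmax(as.numeric(Matrix::solve(
    A_lap - Matrix::Diagonal(n, Vd / (q$K_m + C_fiber_wall)), b_base)), 0)
  Fv <- resid(Cv)
  converged <- FALSE
  for (it in seq_len(max_picard)) {
    J <- A_lap - Matrix::Diagonal(n, Vd * q$K_m / (q$K_m + Cv)^2)
    step <- as.numeric(Matrix::solve(J, Fv))
    lam <- 1
    for (half in 1:8) {
      Cn <- pmax(Cv - lam * step, 0)
      Fn <- resid(Cn)
      if (sqrt(sum(Fn^2)) <= sqrt(sum(Fv^2)) || half == 8L) break
      lam <- lam / 2
    }
    delta <- max(abs(Cn - Cv))
    Cv <- Cn; Fv <- Fn
    if (delta < tol * max(C_fiber_wall, 1e-300)) { converged <- TRUE; break }
  }
  if (!converged && delta > 1e-6 * max(C_fiber_wall, 1e-300))
    stop(sprintf(
      "cross-section solver did not converge after %d iterations (residual %.3g)",
      it, delta), call. = FALSE)
  Cv <- pmax(Cv, 0)

  .hd_field(x, y, Cv, unknown, h, layout, n)
}

.hd_field <- function(x, y, Cv, unknown, h, layout, n) {
  Cmat <- matrix(NA_real_, length(x), length(y))
  Cmat[unknown] <- pmax(Cv, 0)
  structure(list(x = x, y = y, C = Cmat, h = h, layout = layout,
                 n_unknowns = n),
            class = "hd_field")
}

# fraction of the cell face (centered at distance h/2 from the node in
# direction (dx, dy), spanning h perpendicular to it) lying inside the
# reactor circle of radius R centered at the origin
.face_aperture <- function(px, py, dx, dy, h, R) {
  cx <- px + dx * h / 2; cy <- py + dy * h / 2
  # perpendicular unit vector
  ex <- -dy; ey <- dx
  p1 <- c(cx - ex * h / 2, cy - ey * h / 2)
  p2 <- c(cx + ex * h / 2, cy + ey * h / 2)
  in1 <- sum(p1^2) < R^2; in2 <- sum(p2^2) < R^2
  if (in1 && in2) return(1)
  if (!in1 && !in2) return(0)
  # single crossing: solve |p1 + t (p2 - p1)|^2 = R^2 for t in (0, 1)
  dxy <- p2 - p1
  a <- sum(dxy^2); b <- 2 * sum(p1 * dxy); cc <- sum(p1^2) - R^2
  disc <- max(b^2 - 4 * a * cc, 0)
  ts <- c((-b - sqrt(disc)) / (2 * a), (-b + sqrt(disc)) / (2 * a))
  t <- ts[ts > 0 & ts < 1][1]
  if (is.na(t)) return(if (in1 || in2) 1 else 0)
  if (in1) t else 1 - t
}

# fraction t in (0, 1] of the step from (px, py) along h*(dx, dy) at which
# the circle (cx, cy, rf) is crossed; clamped below to keep the
# Shortley-Weller stencil well conditioned
.theta_to_circle <- function(px, py, dx, dy, h, cx, cy, rf) {
  ox <- px - cx; oy <- py - cy
  a <- h^2
  b <- 2 * h * (ox * dx + oy * dy)
  cc <- ox^2 + oy^2 - rf^2
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(1)
  sq <- sqrt(disc)
  ts <- c((-b - sq) / (2 * a), (-b + sq) / (2 * a))
  ts <- ts[ts > 0]
  if (!length(ts)) return(1)
  max(min(min(ts), 1), 0.01)
}

#' Limited fraction of an explicit cross-section field
#'
#' Area fraction of the scaffold region (uniform-grid node weighting) where
#' the concentration is below the critical value.
#'
#' @param field An `hd_field` from [solve_field()].
#' @param C_critical Critical concentration (mol/m^3).
#' @return Fraction in `[0, 1]`.
#' @export
field_limited_fraction <- function(field, C_critical) {
  stopifnot(inherits(field, "hd_field"))
  v <- field$C[!is.na(field$C)]
  mean(v < C_critical)
}

#' Discrepancy between explicit-geometry and Krogh limited fractions
#'
#' Quantifies how far an explicit fiber-placement solution departs from the
#' Krogh-cylinder prediction at matched fiber density. The package's
#' validity check for the Krogh assumption compares this gap (for an evenly
#' spaced layout) against the spread of the explicit solution across random
#' placements.
#'
#' @param field An `hd_field`.
#' @param krogh_phi Limited fraction predicted by the Krogh model.
#' @param C_critical Critical concentration (mol/m^3).
#' @return List with `phi_grid`, `phi_krogh`, and `gap = |phi_grid -
#'   phi_krogh|`.
#' @export
krogh_discrepancy <- function(field, krogh_phi, C_critical) {
  phi_grid <- field_limited_fraction(field, C_critical)
  list(phi_grid = phi_grid, phi_krogh = krogh_phi,
       gap = abs(phi_grid - krogh_phi))
}
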