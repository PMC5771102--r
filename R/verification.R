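# Error functions on top of base pnorm (double precision throughout).
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

#' Parameters of the planar two-phase freezing (Neumann-Stefan) problem
#'
#' A half-space of liquid at `T_init` is suddenly cooled by holding the wall
#' `x = 0` at `T_wall` below the melting temperature `T_m`; a sharp freezing
#' front `X(t) = 2*lambda*sqrt(alpha_s*t)` advances into the liquid. This is
#' the classical analytic oracle for phase-change solvers.
#'
#' @param T_init initial (liquid) temperature, degC
#' @param T_wall wall temperature, degC
#' @param T_m melting/freezing temperature, degC
#' @param k_s,k_l solid/liquid thermal conductivities, W/m/K
#' @param C_s,C_l solid/liquid volumetric heat capacities, J/m^3/K
#' @param Q volumetric latent heat, J/m^3
#' @return an object of class `stefan_params`
#' @export
stefan_params <- function(T_init = 37, T_wall = -196, T_m = -4.5,
                          k_s = 2, k_l = 0.5,
                          C_s = 1.8e6, C_l = 3.6e6, Q = 250e6) {
  stopifnot(T_wall < T_m, T_m < T_init,
            k_s > 0, k_l > 0, C_s > 0, C_l > 0, Q >= 0)
  out <- list(T_init = T_init, T_wall = T_wall, T_m = T_m,
              k_s = k_s, k_l = k_l, C_s = C_s, C_l = C_l, Q = Q,
              alpha_s = k_s / C_s, alpha_l = k_l / C_l)
  class(out) <- "stefan_params"
  out
}

# Residual of the Neumann transcendental equation (root gives lambda).
stefan_residual <- function(lambda, sp) {
  nu <- sqrt(sp$alpha_s / sp$alpha_l)
  sp$k_s * (sp$T_m - sp$T_wall) * exp(-lambda^2) /
    (sqrt(pi * sp$alpha_s) * erf(lambda)) -
    sp$k_l * (sp$T_init - sp$T_m) * exp(-(nu * lambda)^2) /
    (sqrt(pi * sp$alpha_l) * erfc(nu * lambda)) -
    sp$Q * lambda * sqrt(sp$alpha_s)
}

#' Front coefficient of the Neumann-Stefan solution
#'
#' Solves the Neumann transcendental equation for the dimensionless front
#' coefficient `lambda` by bracketing bisection to an interval of width
#' `1e-10`; the front position is `X(t) = 2*lambda*sqrt(alpha_s*t)`.
#'
#' @param sp a [stefan_params()] object
#' @return `lambda` (dimensionless)
#' @export
#' @examples
#' neumann_stefan_lambda(stefan_params())
neumann_stefan_lambda <- function(sp) {
  stopifnot(inherits(sp, "stefan_params"))
  lo <- 1e-9
  hi <- 0.5
  flo <- stefan_residual(lo, sp)
  while (stefan_residual(hi, sp) > 0 && hi < 64) hi <- hi * 2
  if (flo <= 0 || stefan_residual(hi, sp) > 0)
    stop("parameter error: no sign change in the bisection bracket", call. = FALSE)
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (stefan_residual(mid, sp) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Temperature profile of the Neumann-Stefan solution
#'
#' Two-region erf profile: frozen solid for `x <= X(t)`, liquid beyond;
#' continuous and equal to `T_m` at the front.
#'
#' @param x distance from the cold wall, m (vectorized)
#' @param t time, s (scalar, > 0)
#' @param sp a [stefan_params()] object
#' @param lambda optional precomputed front coefficient
#' @return temperature, degC
#' @export
stefan_temperature <- function(x, t, sp, lambda = neumann_stefan_lambda(sp)) {
  stopifnot(t > 0, all(x >= 0))
  nu <- sqrt(sp$alpha_s / sp$alpha_l)
  eta_s <- x / (2 * sqrt(sp$alpha_s * t))
  eta_l <- x / (2 * sqrt(sp$alpha_l * t))
  solid <- sp$T_wall + (sp$T_m - sp$T_wall) * erf(eta_s) / erf(lambda)
  liquid <- sp$T_init -
    (sp$T_init - sp$T_m) * erfc(eta_l) / erfc(nu * lambda)
  ifelse(eta_s <= lambda, solid, liquid)
}

#' Semi-infinite single-phase conduction (erf) solution
#'
#' Half-space initially at `T0`, wall suddenly held at `Ts`:
#' `T(x, t) = Ts + (T0 - Ts) * erf(x / (2*sqrt(alpha*t)))`.
#'
#' @param x distance from the wall, m (vectorized)
#' @param t time, s (> 0)
#' @param T0 initial temperature, degC
#' @param Ts wall temperature, degC
#' @param alpha thermal diffusivity, m^2/s
#' @return temperature, degC
#' @export
semi_infinite_conduction <- function(x, t, T0, Ts, alpha) {
  stopifnot(t > 0, alpha > 0)
  Ts + (T0 - Ts) * erf(x / (2 * sqrt(alpha * t)))
}

# Hand-assemble a labeled_grid without going through the analytic geometry.
make_grid_raw <- function(labels, h, origin = c(0, 0, 0), geom = NULL) {
  counts <- vapply(LBL, function(code) sum(labels == code), integer(1))
  grid <- list(labels = labels, h = h, origin = origin, dims = dim(labels),
               counts = counts, volumes_cm3 = counts * h^3 / 1000, geom = geom)
  class(grid) <- "labeled_grid"
  grid
}

#' Deterministic unit-test fixtures
#'
#' Small self-contained geometries wired to appropriate boundary conditions:
#' * `single_cell` — one adiabatic TISSUE cell (closed-form ODE comparisons);
#' * `slab_1d` — an `n x 1 x 1` tissue slab whose first cell is a PROBE_TIP
#'   Dirichlet cell, so the cold wall sits on the face `x = h` (`wall_x`);
#' * `straight_tube` — a tissue box pierced by a straight axial lumen of
#'   diameter `D0` (flow and conjugate-transfer tests);
#' * `mini_bifurcation` — the full default geometry with a single coarse probe
#'   at `h = 5` mm (end-to-end smoke runs in seconds).
#'
#' @param name one of `"single_cell"`, `"slab_1d"`, `"straight_tube"`,
#'   `"mini_bifurcation"`
#' @param n slab cell count (`slab_1d` only)
#' @param h voxel size, mm (defaults per fixture)
#' @return list with the `grid`, a default `config` (props/bounds), and
#'   fixture-specific extras (e.g. `wall_x`, mm)
#' @export
make_fixture <- function(name, n = 100, h = NULL) {
  props <- material_properties()
  bounds <- boundary_spec()
  switch(name,
    single_cell = {
      h <- if (is.null(h)) 1 else h
      grid <- make_grid_raw(array(LBL[["TISSUE"]], c(1, 1, 1)), h)
      list(grid = grid, config = list(props = props, bounds = bounds))
    },
    slab_1d = {
      h <- if (is.null(h)) 0.5 else h
      lab <- array(LBL[["TISSUE"]], c(n, 1, 1))
      lab[1, 1, 1] <- LBL[["PROBE_TIP"]]
      grid <- make_grid_raw(lab, h)
      list(grid = grid, config = list(props = props, bounds = bounds),
           wall_x = h)
    },
    straight_tube = {
      h <- if (is.null(h)) 1 else h
      D0 <- 10; W <- 20; L <- 30
      nx <- round(W / h); nz <- round(L / h)
      origin <- c(-W / 2, -W / 2, -L)
      xc <- origin[1] + (seq_len(nx) - 0.5) * h
      zc <- origin[3] + (seq_len(nz) - 0.5) * h
      lab <- array(LBL[["TISSUE"]], c(nx, nx, nz))
      r2 <- outer(xc^2, xc^2, `+`)
      lum <- r2 <= (D0 / 2)^2
      for (k in seq_len(nz)) lab[, , k][lum] <- LBL[["LUMEN"]]
      grid <- make_grid_raw(lab, h, origin)
      list(grid = grid, config = list(props = props, bounds = bounds, D0 = D0))
    },
    mini_bifurcation = {
      h <- if (is.null(h)) 5 else h
      # synthetic smoke-test placement: the coarse probe is snapped onto a
      # cell center of the default h = 5 grid so its tip rasterizes
      geom <- build_geometry(bifurcation_params(),
                             probe_spec(Dp = 5, Lp = 22,
                                        tip_center = c(2.5, 0, -47.5)))
      grid <- voxelize(geom, h)
      list(grid = grid, config = list(props = props, bounds = bounds, V = 0.2))
    },
    stop("unknown fixture name: ", name, call. = FALSE)
  )
}
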