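field_array <- function(field) {
  if (inherits(field, "temperature_field")) field$T else field
}

#' Volume of tissue at or below a temperature threshold
#'
#' Counts whole TISSUE cells with `T <= T_thr` and applies a sub-cell
#' correction from every tissue-tissue face whose endpoint temperatures
#' straddle the threshold: along each axis, linear interpolation between the
#' two cell centers locates the iso-surface crossing (marching-style), giving
#' an exact column-wise 1-d measure; the three single-axis estimates are
#' averaged, which keeps the estimator isotropic and monotone in `T_thr` and
#' restores roughly O(h^2) convergence on smooth fields. Lumen and probe cells
#' never contribute.
#'
#' @param field a `temperature_field` or temperature array, degC
#' @param grid the matching [voxelize()] grid
#' @param T_thr threshold, degC (0 for the iceball, -40 for the lethal zone)
#' @param subcell apply the sub-cell face correction (set `FALSE` for plain
#'   cell counting, e.g. for sensitivity reporting)
#' @return volume, cm^3
#' @export
threshold_volume <- function(field, grid, T_thr, subcell = TRUE) {
  Tarr <- field_array(field)
  lab <- grid$labels
  d <- dim(lab)
  tis <- lab == LBL[["TISSUE"]]
  below <- tis & Tarr <= T_thr
  vol_cells <- sum(below)
  corr <- 0
  if (subcell) {
    for (ax in 1:3) {
      n <- d[ax]
      a <- slab(Tarr, ax, 1:(n - 1)); b <- slab(Tarr, ax, 2:n)
      ta <- slab(tis, ax, 1:(n - 1)); tb <- slab(tis, ax, 2:n)
      ba <- slab(below, ax, 1:(n - 1)); bb <- slab(below, ax, 2:n)
      m1 <- ta & tb & ba & !bb   # low side frozen
      if (any(m1)) corr <- corr + sum((T_thr - a[m1]) / (b[m1] - a[m1]) - 0.5)
      m2 <- ta & tb & !ba & bb   # high side frozen
      if (any(m2)) corr <- corr + sum((T_thr - b[m2]) / (a[m2] - b[m2]) - 0.5)
    }
  }
  (vol_cells + corr / 3) * grid$h^3 / 1000
}

# take slices idx along axis ax of a 3d array
slab <- function(x, ax, idx) {
  switch(ax, x[idx, , , drop = FALSE], x[, idx, , drop = FALSE],
         x[, , idx, drop = FALSE])
}

#' Total heat flux across the artery surface
#'
#' Sum over all lumen-tissue interface faces of the discrete conjugate flux
#' `kappa_face * (T_lumen - T_tissue) / h * h^2`, with the harmonic mean of
#' the blood conductivity and the (temperature-dependent) effective tissue
#' conductivity on the face. Positive when heat flows from blood into tissue.
#'
#' @param field a `temperature_field` or temperature array, degC
#' @param grid the matching grid
#' @param faces precomputed [interface_faces()] table
#' @param props a [material_properties()] object
#' @return total flux, W
#' @export
artery_surface_flux <- function(field, grid, faces, props) {
  Tarr <- field_array(field)
  Tl <- Tarr[faces$lumen]
  Tt <- Tarr[faces$tissue]
  kt <- effective_conductivity(Tt, props)
  kf <- 2 * props$kappa_b * kt / (props$kappa_b + kt)
  sum(kf * (Tl - Tt) * grid$h / 1000)
}

#' Minimum artery-wall (interface) temperature
#'
#' The artery wall has zero thickness, so the wall temperature is the
#' temperature of the lumen-tissue interface itself: on each face it is the
#' flux-continuous value between the two adjacent cell centers,
#' `(kappa_t T_tissue + kappa_b T_lumen) / (kappa_t + kappa_b)` with the
#' effective tissue conductivity evaluated at the tissue temperature. Sampling
#' the lumen cell centers instead would sit inside flowing blood and, at any
#' practical resolution, never register the wall cooling that drives
#' vessel-injury timing.
#'
#' @inheritParams artery_surface_flux
#' @return minimum wall temperature, degC
#' @export
min_wall_temperature <- function(field, grid, faces, props) {
  min(wall_face_temperature(field_array(field), faces, props))
}

wall_face_temperature <- function(Tarr, faces, props) {
  Tl <- Tarr[faces$lumen]
  Tt <- Tarr[faces$tissue]
  kt <- effective_conductivity(Tt, props)
  (kt * Tt + props$kappa_b * Tl) / (kt + props$kappa_b)
}

#' Treatment time before vessel-wall freezing risk
#'
#' First time at which the minimum artery-surface temperature crosses 0 degC,
#' linearly interpolated between samples; `Inf` ("exceeds horizon") when the
#' wall never reaches freezing within the horizon.
#'
#' @param time sample times, s (strictly increasing)
#' @param min_wall minimum wall temperatures at those times, degC
#' @param horizon freezing duration horizon, s
#' @return time, s, or `Inf`
#' @export
#' @examples
#' treatment_time(c(0, 8, 12), c(37, 5, -5))  # 10 s
treatment_time <- function(time, min_wall, horizon = 1200) {
  if (!length(time)) stop("input error: empty series", call. = FALSE)
  stopifnot(length(time) == length(min_wall), !is.unsorted(time, strictly = TRUE))
  keep <- time <= horizon + 1e-9
  time <- time[keep]; min_wall <- min_wall[keep]
  hit <- which(min_wall <= 0)
  if (!length(hit)) return(Inf)
  i <- hit[1]
  if (i == 1 || min_wall[i] == 0) return(time[i])
  time[i - 1] + (0 - min_wall[i - 1]) *
    (time[i] - time[i - 1]) / (min_wall[i] - min_wall[i - 1])
}

#' Temperature at a point, by trilinear interpolation
#'
#' Exact on linear fields and at cell centers; constant (nearest) continuation
#' within the half-cell rim of the domain box.
#'
#' @param field a `temperature_field` or temperature array, degC
#' @param grid the matching grid
#' @param point position, mm
#' @return temperature, degC
#' @export
sample_point_temperature <- function(field, grid, point) {
  Tarr <- field_array(field)
  d <- grid$dims
  g <- (point - grid$origin) / grid$h - 0.5
  if (any(g < -0.5) || any(g > d - 0.5))
    stop("input error: point outside the domain", call. = FALSE)
  g <- pmin(pmax(g, 0), d - 1)
  i0 <- pmin(floor(g), d - 2); i0 <- pmax(i0, 0)
  f <- g - i0
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wgt <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
    acc <- acc + wgt * Tarr[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
  }
  acc
}
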