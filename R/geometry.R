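# Region label codes used on the voxel grid (integer-coded for the C++ core).
LBL <- c(EXTERIOR = 0L, TISSUE = 1L, LUMEN = 2L, PROBE_TIP = 3L, PROBE_SHAFT = 4L)

#' Parameters of the symmetric arterial bifurcation and tissue cylinder
#'
#' A straight root vessel of diameter `D0` runs down the axis of a tissue
#' cylinder (diameter `Dt`, length `Lt`); at depth `L1` it splits into two
#' symmetric curved daughter vessels, each spanning a further vertical extent
#' `L2` so that the daughters exit through the bottom of the cylinder.
#' Daughter diameters follow the cube law (see [daughter_diameter()]).
#'
#' The bifurcation angle `phi` is, by default, the angle each daughter makes
#' with the root axis where it leaves the bifurcation point
#' (`phi_ref = "axis"`). Each daughter departs straight at that angle and
#' bends back to the vertical on a circular arc of radius `bend_radius`,
#' then runs straight down to the outlet — the "curved tube" shape of large
#' hepatic-type bifurcations. Set `phi_ref = "between"` to interpret `phi` as
#' the full angle between the two daughters instead (each at `phi/2` from the
#' axis). The axis-referenced reading is the package default because it is the
#' only one whose probe-to-vessel tissue gaps (`Ld sin(phi) - D1/2 - Dp/2`)
#' support vessel-wall freezing times of ~10 s at `Ld = 10` mm and over a
#' minute at `Ld = 15` mm while leaving the wall protected at `Ld >= 20` mm.
#'
#' Coordinates: the cylinder axis is the z axis, the root inlet plane is z = 0,
#' depth increases toward negative z (bifurcation point at `(0, 0, -L1)`), and
#' the bifurcation plane is the x-z plane.
#'
#' @param L1 root-vessel length from inlet to bifurcation point, mm
#' @param L2 vertical extent of the daughter vessels, mm
#' @param D0 root-vessel diameter, mm
#' @param phi bifurcation angle, degrees (see `phi_ref`)
#' @param Dt tissue-cylinder diameter, mm
#' @param Lt tissue-cylinder length, mm (must equal `L1 + L2`)
#' @param bend_radius radius, mm, of the circular arc that turns each daughter
#'   from its departure angle back to the vertical; `0` keeps the daughters
#'   straight all the way (they must then still fit inside the cylinder)
#' @param phi_ref `"axis"`: `phi` is each daughter's departure angle from the
#'   root axis (default); `"between"`: `phi` is the full angle between the two
#'   daughters
#' @return an object of class `bifurcation_params`
#' @export
bifurcation_params <- function(L1 = 20, L2 = 80, D0 = 10, phi = 60,
                               Dt = 120, Lt = 100, bend_radius = 40,
                               phi_ref = c("axis", "between")) {
  phi_ref <- match.arg(phi_ref)
  if (D0 <= 0 || L1 <= 0 || L2 <= 0 || Dt <= 0 || Lt <= 0)
    stop("all lengths must be positive", call. = FALSE)
  if (abs(L1 + L2 - Lt) > 1e-9)
    stop("tissue cylinder length Lt must equal L1 + L2", call. = FALSE)
  if (D0 >= Dt) stop("root diameter D0 must be smaller than Dt", call. = FALSE)
  if (phi <= 0 || phi >= 180) stop("phi must lie in (0, 180) degrees", call. = FALSE)
  if (bend_radius < 0) stop("bend_radius must be >= 0", call. = FALSE)
  alpha <- (if (phi_ref == "axis") phi else phi / 2) * pi / 180
  if (alpha >= pi / 2)
    stop("daughter departure angle must be below 90 degrees", call. = FALSE)
  if (bend_radius * sin(alpha) > L2)
    stop("bend_radius too large: arc exceeds the daughter vertical extent L2",
         call. = FALSE)
  out <- list(L1 = L1, L2 = L2, D0 = D0, D1 = daughter_diameter(D0),
              phi = phi, Dt = Dt, Lt = Lt, bend_radius = bend_radius,
              phi_ref = phi_ref, alpha = alpha)
  class(out) <- "bifurcation_params"
  out
}

#' Daughter-vessel diameter from the symmetric cube law
#'
#' For a symmetric bifurcation conserving Murray-type cube-law flow,
#' `2 * D1^3 = D0^3`, i.e. `D1 = 2^(-1/3) * D0`.
#'
#' @param D0 root-vessel diameter (any positive length unit)
#' @return daughter diameter in the same unit
#' @export
#' @examples
#' daughter_diameter(10)  # 7.94 mm
daughter_diameter <- function(D0) {
  if (any(!is.finite(D0)) || any(D0 <= 0))
    stop("root diameter D0 must be positive", call. = FALSE)
  2^(-1 / 3) * D0
}

#' Cryoprobe specification
#'
#' A cryoprobe is a thin cylinder with a cryogenically active distal tip of
#' length `Lp` (held at the probe temperature) and an adiabatic shaft running
#' from the tip to the outside of the tissue. By default the probe is inserted
#' horizontally along +y (normal to the bifurcation plane) with the midpoint
#' of its active tip on the cylinder axis at depth `L1 + Ld`, i.e. at distance
#' `Ld` below the bifurcation point.
#'
#' @param Dp probe diameter, mm
#' @param Lp active-tip length, mm
#' @param Ld distance from the active-tip midpoint to the bifurcation point,
#'   measured along the cylinder axis, mm; ignored when `tip_center` is given
#' @param axis unit insertion direction (the shaft extends from the tip along
#'   `+axis`)
#' @param tip_center optional explicit tip-midpoint position, mm
#' @return an object of class `probe_spec`
#' @export
probe_spec <- function(Dp = 4, Lp = 22, Ld = 30, axis = c(0, 1, 0),
                       tip_center = NULL) {
  if (Dp <= 0 || Lp <= 0) stop("Dp and Lp must be positive", call. = FALSE)
  if (is.null(tip_center) && Ld < 0) stop("Ld must be >= 0", call. = FALSE)
  axis <- as.numeric(axis)
  if (length(axis) != 3 || sum(axis^2) == 0)
    stop("axis must be a nonzero 3-vector", call. = FALSE)
  axis <- axis / sqrt(sum(axis^2))
  if (!is.null(tip_center)) {
    tip_center <- as.numeric(tip_center)
    if (length(tip_center) != 3 || any(!is.finite(tip_center)))
      stop("tip_center must be a finite 3-vector", call. = FALSE)
  }
  out <- list(Dp = Dp, Lp = Lp, Ld = Ld, axis = axis, tip_center = tip_center)
  class(out) <- "probe_spec"
  out
}

#' Standard three-probe layout
#'
#' Three identical probes with active-tip midpoints distributed uniformly
#' (polar angles 90, 210 and 330 degrees) on a horizontal circle of radius
#' `radius`, centered on the cylinder axis at distance `Ld` below the
#' bifurcation point. The probe axes are parallel to the cylinder axis (z):
#' with the daughters swinging 60 degrees out through the bifurcation plane, a
#' radius-20 mm circle of horizontally inserted probes would pierce them,
#' whereas axis-parallel probes surround the target with > 5 mm of lumen
#' clearance.
#'
#' @param Ld depth of the circle center below the bifurcation point, mm
#' @param radius circle radius, mm
#' @param Dp,Lp probe diameter and active-tip length, mm
#' @param L1 root-vessel length (locates the bifurcation point), mm
#' @return list of three [probe_spec()] objects
#' @export
three_probe_layout <- function(Ld = 30, radius = 20, Dp = 2, Lp = 20, L1 = 20) {
  zc <- -(L1 + Ld)
  lapply(c(90, 210, 330) * pi / 180, function(a) {
    probe_spec(Dp = Dp, Lp = Lp, Ld = Ld, axis = c(0, 0, 1),
               tip_center = c(radius * cos(a), radius * sin(a), zc))
  })
}

# Sample a daughter centerline as a polyline (rows = points, mm).
# side = +1 / -1 selects the x > 0 / x < 0 daughter. The daughter departs the
# bifurcation point at angle alpha from the axis and turns back to vertical on
# a circular arc of radius Rc, then drops straight to z = -Lt.
daughter_centerline <- function(params, side) {
  alpha <- params$alpha
  apex <- c(0, 0, -params$L1)
  Rc <- params$bend_radius
  pts <- matrix(apex, nrow = 1)
  z_used <- 0
  x_used <- 0
  if (Rc > 0) {
    # direction angle from vertical decreases alpha -> 0 along the arc
    th <- seq(alpha, 0, length.out = max(8, ceiling(alpha / (2 * pi / 180))))
    arc <- cbind(side * Rc * (cos(th) - cos(alpha)), 0,
                 -params$L1 - Rc * (sin(alpha) - sin(th)))
    pts <- rbind(pts, arc[-1, , drop = FALSE])
    z_used <- Rc * sin(alpha)
    x_used <- Rc * (1 - cos(alpha))
  }
  rem <- params$L2 - z_used
  if (rem > 0) {
    dirv <- if (Rc > 0) c(0, 0, -1) else c(side * sin(alpha), 0, -cos(alpha))
    pts <- rbind(pts, pts[nrow(pts), ] + dirv * rem / abs(dirv[3]))
  }
  pts
}

# Minimum distance from each row of P (n x 3) to segment A-B.
dist_point_segment <- function(P, A, B) {
  d <- B - A
  dd <- sum(d^2)
  rel <- sweep(P, 2, A)
  t <- if (dd == 0) rep(0, nrow(P)) else pmin(pmax(rel %*% d / dd, 0), 1)
  diff <- rel - outer(as.vector(t), d)
  sqrt(rowSums(diff^2))
}

# Minimum distance from rows of P to a polyline (matrix of points).
dist_point_polyline <- function(P, line) {
  dmin <- rep(Inf, nrow(P))
  for (s in seq_len(nrow(line) - 1))
    dmin <- pmin(dmin, dist_point_segment(P, line[s, ], line[s + 1, ]))
  dmin
}

# Minimum distance between two segments, by dense sampling of the first.
dist_segment_polyline <- function(A, B, line, n = 201) {
  t <- seq(0, 1, length.out = n)
  P <- outer(1 - t, A) + outer(t, B)
  min(dist_point_polyline(P, line))
}

#' Build the analytic cryosurgery geometry
#'
#' Assembles vessel centerlines and radii, the tissue cylinder and the probe
#' cylinders, and validates probe placement: every active tip must lie inside
#' the tissue cylinder, and probes may not substantively intersect the vessel
#' lumen. Grazing contact up to `max_overlap` mm of penetration is tolerated
#' with a warning: the tightest published single-probe placements put the probe
#' surface essentially in contact with the daughter-vessel wall.
#'
#' @param params a [bifurcation_params()] object
#' @param probes a single [probe_spec()] or a list of them
#' @param max_overlap maximum tolerated probe-lumen penetration depth, mm
#' @return an object of class `cryo_geometry`
#' @export
build_geometry <- function(params = bifurcation_params(), probes = list(),
                           max_overlap = 1.5) {
  stopifnot(inherits(params, "bifurcation_params"))
  if (inherits(probes, "probe_spec")) probes <- list(probes)
  centerlines <- list(
    root = matrix(c(0, 0, 0, 0, 0, -params$L1), nrow = 2, byrow = TRUE),
    daughter_pos = daughter_centerline(params, +1),
    daughter_neg = daughter_centerline(params, -1)
  )
  radii <- c(root = params$D0 / 2, daughter_pos = params$D1 / 2,
             daughter_neg = params$D1 / 2)
  for (b in c("daughter_pos", "daughter_neg")) {
    ends <- centerlines[[b]][nrow(centerlines[[b]]), ]
    if (sqrt(sum(ends[1:2]^2)) + radii[[b]] > params$Dt / 2)
      stop("daughter vessel exits the tissue cylinder laterally", call. = FALSE)
  }

  probes <- lapply(probes, function(p) {
    stopifnot(inherits(p, "probe_spec"))
    if (is.null(p$tip_center)) p$tip_center <- c(0, 0, -(params$L1 + p$Ld))
    a <- p$tip_center - p$axis * p$Lp / 2
    b <- p$tip_center + p$axis * p$Lp / 2
    for (endp in list(a, b)) {
      inside <- sqrt(sum(endp[1:2]^2)) + p$Dp / 2 <= params$Dt / 2 &&
        endp[3] >= -params$Lt && endp[3] <= 0
      if (!inside)
        stop("probe placement error: active tip outside the tissue cylinder",
             call. = FALSE)
    }
    pen <- vapply(names(centerlines), function(nm) {
      radii[[nm]] + p$Dp / 2 - dist_segment_polyline(a, b, centerlines[[nm]])
    }, numeric(1))
    if (max(pen) > max_overlap)
      stop(sprintf(
        "probe placement error: active tip intersects the lumen (penetration %.2f mm)",
        max(pen)), call. = FALSE)
    if (max(pen) > 0)
      warning(sprintf("probe tip grazes the lumen (penetration %.2f mm); probe labels take priority",
                      max(pen)), call. = FALSE)
    p$tip_a <- a; p$tip_b <- b
    p
  })

  out <- list(params = params, centerlines = centerlines, radii = radii,
              probes = probes)
  class(out) <- "cryo_geometry"
  out
}

#' @export
print.cryo_geometry <- function(x, ...) {
  p <- x$params
  cat(sprintf("Bifurcated-artery geometry: D0 = %g mm, D1 = %.2f mm, phi = %g deg\n",
              p$D0, p$D1, p$phi))
  cat(sprintf("  tissue cylinder %g x %g mm; bifurcation point at z = %g mm\n",
              p$Dt, p$Lt, -p$L1))
  cat(sprintf("  %d probe(s)\n", length(x$probes)))
  invisible(x)
}

#' Rasterize the analytic geometry to a labeled voxel grid
#'
#' Uniform Cartesian grid over the bounding box of the tissue cylinder; every
#' cell is labeled by a membership test of its center, with priority
#' PROBE_TIP > PROBE_SHAFT > LUMEN > TISSUE > EXTERIOR.
#'
#' @param geom a [build_geometry()] object
#' @param h voxel edge length, mm; must divide the cylinder length `Lt` and
#'   resolve every probe (`h <= Dp`)
#' @return an object of class `labeled_grid` with fields `labels`
#'   (integer array, codes in `cryovessel:::LBL`), `h` (mm), `origin` (mm,
#'   minimum corner), `dims`, and per-label cell `counts` and `volumes_cm3`
#' @export
voxelize <- function(geom, h = 2.5) {
  stopifnot(inherits(geom, "cryo_geometry"), h > 0)
  p <- geom$params
  for (pr in geom$probes) if (h > pr$Dp + 1e-9)
    stop("resolution error: h exceeds probe diameter Dp", call. = FALSE)
  nx <- ceiling(p$Dt / h - 1e-9); ny <- nx
  nz <- round(p$Lt / h)
  if (abs(nz * h - p$Lt) > 1e-6)
    stop("h must divide the tissue cylinder length Lt", call. = FALSE)
  if (nx < 2 || nz < 2)
    stop("resolution error: h too coarse for the domain", call. = FALSE)
  origin <- c(-nx * h / 2, -ny * h / 2, -nz * h)

  xc <- origin[1] + (seq_len(nx) - 0.5) * h
  yc <- origin[2] + (seq_len(ny) - 0.5) * h
  zc <- origin[3] + (seq_len(nz) - 0.5) * h
  P <- cbind(rep(xc, times = ny * nz),
             rep(rep(yc, each = nx), times = nz),
             rep(zc, each = nx * ny))
  n <- nrow(P)
  labels <- integer(n)  # EXTERIOR

  in_cyl <- P[, 1]^2 + P[, 2]^2 <= (p$Dt / 2)^2 & P[, 3] >= -p$Lt & P[, 3] <= 0
  labels[in_cyl] <- LBL[["TISSUE"]]

  # lumen: distance to each branch polyline, restricted to a bounding slab
  for (nm in names(geom$centerlines)) {
    line <- geom$centerlines[[nm]]
    r <- geom$radii[[nm]]
    box_lo <- apply(line, 2, min) - r - h
    box_hi <- apply(line, 2, max) + r + h
    cand <- which(in_cyl &
                  P[, 1] >= box_lo[1] & P[, 1] <= box_hi[1] &
                  P[, 2] >= box_lo[2] & P[, 2] <= box_hi[2] &
                  P[, 3] >= box_lo[3] & P[, 3] <= box_hi[3])
    if (!length(cand)) next
    d <- dist_point_polyline(P[cand, , drop = FALSE], line)
    labels[cand[d <= r]] <- LBL[["LUMEN"]]
  }

  # probes override lumen/tissue; shaft only where inside the tissue cylinder
  for (pr in geom$probes) {
    shaft_far <- pr$tip_b + pr$axis * (2 * p$Dt)  # clipped by the cylinder test
    for (part in list(list(a = pr$tip_b, b = shaft_far, code = LBL[["PROBE_SHAFT"]]),
                      list(a = pr$tip_a, b = pr$tip_b, code = LBL[["PROBE_TIP"]]))) {
      lo <- pmin(part$a, part$b) - pr$Dp / 2 - h
      hi <- pmax(part$a, part$b) + pr$Dp / 2 + h
      cand <- which(in_cyl &
                    P[, 1] >= lo[1] & P[, 1] <= hi[1] &
                    P[, 2] >= lo[2] & P[, 2] <= hi[2] &
                    P[, 3] >= lo[3] & P[, 3] <= hi[3])
      if (!length(cand)) next
      d <- dist_point_segment(P[cand, , drop = FALSE], part$a, part$b)
      labels[cand[d <= pr$Dp / 2]] <- part$code
    }
  }
  if (length(geom$probes) && !any(labels == LBL[["PROBE_TIP"]]))
    stop("resolution error: no PROBE_TIP cell produced at this h", call. = FALSE)

  labels <- array(labels, dim = c(nx, ny, nz))
  counts <- vapply(LBL, function(code) sum(labels == code), integer(1))
  grid <- list(labels = labels, h = h, origin = origin, dims = c(nx, ny, nz),
               counts = counts, volumes_cm3 = counts * h^3 / 1000,
               geom = geom)
  class(grid) <- "labeled_grid"
  grid
}

#' @export
print.labeled_grid <- function(x, ...) {
  cat(sprintf("Labeled voxel grid %d x %d x %d, h = %g mm\n",
              x$dims[1], x$dims[2], x$dims[3], x$h))
  v <- x$volumes_cm3
  for (nm in names(v)) if (v[[nm]] > 0)
    cat(sprintf("  %-11s %8d cells  %9.2f cm^3\n", nm, x$counts[[nm]], v[[nm]]))
  invisible(x)
}

#' Cell-center coordinates of a labeled grid
#'
#' @param grid a [voxelize()] grid
#' @return an `n x 3` matrix of cell-center positions, mm, in array order
#' @export
cell_centers <- function(grid) {
  d <- grid$dims; h <- grid$h; o <- grid$origin
  cbind(o[1] + (rep(seq_len(d[1]), times = d[2] * d[3]) - 0.5) * h,
        o[2] + (rep(rep(seq_len(d[2]), each = d[1]), times = d[3]) - 0.5) * h,
        o[3] + (rep(seq_len(d[3]), each = d[1] * d[2]) - 0.5) * h)
}

#' Faces separating the artery lumen from tissue
#'
#' Enumerates every grid face with a LUMEN cell on one side and a TISSUE cell
#' on the other — the discrete artery surface across which conjugate heat
#' exchange happens.
#'
#' @param grid a [voxelize()] grid with at least one LUMEN and one TISSUE cell
#' @return a data frame with linear cell indices `lumen`, `tissue`, the face
#'   normal `axis` (1 = x, 2 = y, 3 = z), `orientation` (+1 if the tissue cell
#'   sits on the +axis side of the lumen cell) and `area` (mm^2)
#' @export
interface_faces <- function(grid) {
  lab <- grid$labels
  d <- dim(lab)
  if (!any(lab == LBL[["LUMEN"]]) || !any(lab == LBL[["TISSUE"]]))
    stop("grid must contain both LUMEN and TISSUE cells", call. = FALSE)
  res <- list()
  strides <- c(1L, d[1], d[1] * d[2])
  for (ax in 1:3) {
    # linear indices of the low-side cell of every interior face along ax
    n <- d; n[ax] <- d[ax] - 1L
    ii <- rep(seq_len(n[1]), times = n[2] * n[3])
    jj <- rep(rep(seq_len(n[2]), each = n[1]), times = n[3])
    kk <- rep(seq_len(n[3]), each = n[1] * n[2])
    lo <- ii + (jj - 1L) * strides[2] + (kk - 1L) * strides[3]
    hi <- lo + strides[ax]
    a <- lab[lo]; b <- lab[hi]
    m1 <- a == LBL[["LUMEN"]] & b == LBL[["TISSUE"]]
    m2 <- a == LBL[["TISSUE"]] & b == LBL[["LUMEN"]]
    if (any(m1)) res[[length(res) + 1]] <-
      data.frame(lumen = lo[m1], tissue = hi[m1], axis = ax, orientation = 1L)
    if (any(m2)) res[[length(res) + 1]] <-
      data.frame(lumen = hi[m2], tissue = lo[m2], axis = ax, orientation = -1L)
  }
  out <- do.call(rbind, res)
  out <- out[order(out$axis, out$lumen), ]
  rownames(out) <- NULL
  out$area <- grid$h^2
  out
}
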