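#' Blood flow parameters
#'
#' @param V average inlet speed at the root vessel, m/s
#' @param mu dynamic viscosity of blood, Pa s
#' @param rho blood density, kg/m^3 (needed by the momentum equation; the
#'   energy equation uses volumetric capacities and never sees it)
#' @return an object of class `flow_params`
#' @export
flow_params <- function(V = 0.2, mu = 2.5e-3, rho = 1050) {
  stopifnot(V >= 0, mu > 0, rho > 0)
  out <- list(V = V, mu = mu, rho = rho)
  class(out) <- "flow_params"
  out
}

#' Parabolic (Poiseuille) inlet velocity profile
#'
#' `u(r) = 2 V (1 - (2 r / D0)^2)`: centerline speed `2V`, zero at the wall,
#' disc average `V`.
#'
#' @param r radial position, same length unit as `D0` (vectorized)
#' @param V average velocity, m/s
#' @param D0 vessel diameter
#' @return axial speed, m/s
#' @export
parabolic_inlet <- function(r, V, D0) {
  if (any(r < 0) || any(r > D0 / 2 + 1e-12))
    stop("outside-lumen error: r must lie in [0, D0/2]", call. = FALSE)
  2 * V * (1 - (2 * r / D0)^2)
}

# ---- staggered (MAC) grid helpers -----------------------------------------

# Face-type codes: 0 wall/irrelevant, 1 interior unknown, 2 inlet (prescribed),
# 3 outlet (free). Inlet = top z boundary over lumen; outlet = bottom.
classify_faces <- function(grid) {
  lab <- grid$labels
  d <- dim(lab)
  lum <- lab == LBL[["LUMEN"]]
  ut <- array(0L, d + c(1, 0, 0))
  vt <- array(0L, d + c(0, 1, 0))
  wt <- array(0L, d + c(0, 0, 1))
  ut[2:d[1], , ][lum[-d[1], , ] & lum[-1, , ]] <- 1L
  vt[, 2:d[2], ][lum[, -d[2], ] & lum[, -1, ]] <- 1L
  wt[, , 2:d[3]][lum[, , -d[3]] & lum[, , -1]] <- 1L
  wt[, , d[3] + 1][lum[, , d[3]]] <- 2L
  wt[, , 1][lum[, , 1]] <- 3L
  list(u = ut, v = vt, w = wt)
}

# linear indices of neighbors of linear index `id` in an array of dim `fd`,
# shifted by `sh` (3-vector); NA outside.
shift_index <- function(id, fd, sh) {
  k <- (id - 1L) %/% (fd[1] * fd[2])
  r <- (id - 1L) %% (fd[1] * fd[2])
  j <- r %/% fd[1]
  i <- r %% fd[1]
  i <- i + sh[1]; j <- j + sh[2]; k <- k + sh[3]
  ok <- i >= 0 & i < fd[1] & j >= 0 & j < fd[2] & k >= 0 & k < fd[3]
  out <- ifelse(ok, i + fd[1] * (j + fd[2] * k) + 1L, NA_integer_)
  as.integer(out)
}

# inlet face values for the w-array (negative: flow in -z), given V and D0
inlet_w_values <- function(grid, ftype, V, D0) {
  d <- grid$dims
  fd <- d + c(0, 0, 1)
  ids <- which(ftype$w == 2L)
  k <- (ids - 1L) %/% (fd[1] * fd[2])
  r <- (ids - 1L) %% (fd[1] * fd[2])
  j <- r %/% fd[1]
  i <- r %% fd[1]
  xc <- grid$origin[1] + (i + 0.5) * grid$h
  yc <- grid$origin[2] + (j + 0.5) * grid$h
  rr <- sqrt(xc^2 + yc^2)
  val <- -2 * V * pmax(0, 1 - (2 * rr / D0)^2)
  list(ids = ids, values = val)
}

# Poisson machinery over lumen cells for divergence-free projection:
# A phi = h^2 * div(u), Neumann on walls/inlet, ghost Dirichlet 0 at outlets.
# Lumen fragments not connected to any outlet (possible at very coarse h,
# where the thin daughters rasterize into disconnected pockets) would make
# the system singular; they are excluded here, and the projection zeroes all
# their face velocities (stagnant pockets).
lumen_poisson <- function(grid, ftype) {
  lab <- grid$labels
  d <- dim(lab)
  lum <- lab == LBL[["LUMEN"]]
  out_ids <- which(ftype$w == 3L)  # bottom w-face (i,j,1) == cell (i,j,1)
  strides <- c(1L, d[1], d[1] * d[2])
  # flood-fill the lumen from the outlet cells
  reached <- logical(length(lab))
  frontier <- out_ids[lum[out_ids]]
  reached[frontier] <- TRUE
  while (length(frontier)) {
    nxt <- integer(0)
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      nb <- shift_index(frontier, d, s * (ax == 1:3))
      nb <- nb[!is.na(nb)]
      nb <- nb[lum[nb] & !reached[nb]]
      reached[nb] <- TRUE
      nxt <- c(nxt, nb)
    }
    frontier <- unique(nxt)
  }
  if (!any(reached))
    stop("topology error: no lumen connected to an outlet", call. = FALSE)
  lum_ids <- which(reached)
  nc <- length(lum_ids)
  rowmap <- integer(length(lab))
  rowmap[lum_ids] <- seq_len(nc)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diagc <- numeric(nc)
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- shift_index(lum_ids, d, s * (ax == 1:3))
      valid <- !is.na(nb) & rowmap[ifelse(is.na(nb), 1L, nb)] > 0
      diagc[valid] <- diagc[valid] + 1
      ii <- c(ii, seq_len(nc)[valid]); jj <- c(jj, rowmap[nb[valid]])
      xx <- c(xx, rep(-1, sum(valid)))
    }
  }
  out_ids <- out_ids[reached[out_ids]]
  diagc[rowmap[out_ids]] <- diagc[rowmap[out_ids]] + 1
  A <- Matrix::sparseMatrix(i = c(seq_len(nc), ii), j = c(seq_len(nc), jj),
                            x = c(diagc, xx), dims = c(nc, nc))
  list(chol = Matrix::Cholesky(methods::as(A, "symmetricMatrix"), LDL = FALSE),
       lum_ids = lum_ids, rowmap = rowmap, out_ids = out_ids,
       keep = reached)
}

# discrete divergence * h over lumen cells (m/s)
lumen_divergence <- function(uu, vv, ww, pois, d) {
  du <- uu[-1, , ] - uu[-(d[1] + 1), , ]
  dv <- vv[, -1, ] - vv[, -(d[2] + 1), ]
  dw <- ww[, , -1] - ww[, , -(d[3] + 1)]
  (du + dv + dw)[pois$lum_ids]
}

# project face velocities to a discretely divergence-free field; inlet and
# wall faces are left untouched, interior and outlet faces are corrected.
project_divfree <- function(uu, vv, ww, grid, ftype, pois) {
  d <- grid$dims
  h <- grid$h / 1000
  keep <- pois$keep
  # flanking-cell indices for every interior face of each component
  face_cells <- function(ids, fd, ax) {
    k <- (ids - 1L) %/% (fd[1] * fd[2]); r <- (ids - 1L) %% (fd[1] * fd[2])
    j <- r %/% fd[1]; i <- r %% fd[1]
    lo <- cbind(i, j, k); lo[, ax] <- lo[, ax] - 1L
    list(lo = lo[, 1] + d[1] * (lo[, 2] + d[2] * lo[, 3]) + 1L,
         hi = i + d[1] * (j + d[2] * k) + 1L)
  }
  iu <- which(ftype$u == 1L); fu <- face_cells(iu, d + c(1, 0, 0), 1)
  iv <- which(ftype$v == 1L); fv <- face_cells(iv, d + c(0, 1, 0), 2)
  iw <- which(ftype$w == 1L); fw <- face_cells(iw, d + c(0, 0, 1), 3)
  oku <- keep[fu$lo] & keep[fu$hi]
  okv <- keep[fv$lo] & keep[fv$hi]
  okw <- keep[fw$lo] & keep[fw$hi]
  # close off faces of lumen pockets not connected to an outlet, and inlets
  # feeding such pockets, before enforcing the divergence constraint
  uu[iu[!oku]] <- 0; vv[iv[!okv]] <- 0; ww[iw[!okw]] <- 0
  inl_ids <- which(ftype$w == 2L)
  dead <- !keep[inl_ids - d[1] * d[2]]  # cell (i,j,nz) below the top face
  ww[inl_ids[dead]] <- 0

  # solve (n*phi_c - sum phi_nbr) = -h^2 * div(u), i.e. lap(phi) = div(u)
  rhs <- -lumen_divergence(uu, vv, ww, pois, d) * h
  phi <- as.numeric(Matrix::solve(pois$chol, rhs)) / h  # pre-divided by h
  phi_full <- numeric(prod(d))
  phi_full[pois$lum_ids] <- phi
  uu[iu[oku]] <- uu[iu[oku]] - (phi_full[fu$hi[oku]] - phi_full[fu$lo[oku]])
  vv[iv[okv]] <- vv[iv[okv]] - (phi_full[fv$hi[okv]] - phi_full[fv$lo[okv]])
  ww[iw[okw]] <- ww[iw[okw]] - (phi_full[fw$hi[okw]] - phi_full[fw$lo[okw]])
  # outlet faces: gradient against the ghost phi = 0 below the domain
  ww[pois$out_ids] <- ww[pois$out_ids] - phi_full[pois$out_ids]
  list(u = uu, v = vv, w = ww)
}

new_flow_field <- function(u, v, w, grid, V, mode, extra = list()) {
  out <- c(list(u = u, v = v, w = w, V = V, mode = mode, dims = grid$dims,
                h = grid$h), extra)
  class(out) <- "flow_field"
  out
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("Flow field (%s): V = %g m/s, max speed %.3g m/s\n",
              x$mode, x$V, max(abs(x$u), abs(x$v), abs(x$w))))
  if (!is.null(x$Re)) cat(sprintf("  Re = %.0f\n", x$Re))
  invisible(x)
}

#' Inlet and outlet volume fluxes of a flow field
#'
#' @param flow a `flow_field`
#' @param grid the matching [voxelize()] grid
#' @return list with `inlet`, `outlet` (m^3/s, positive magnitudes) and
#'   `outlet_by_side` (split across x < 0 / x > 0, for daughter-split checks)
#' @export
flow_fluxes <- function(flow, grid) {
  d <- grid$dims
  A <- (grid$h / 1000)^2
  ftype <- classify_faces(grid)
  win <- flow$w[, , d[3] + 1]
  wout <- flow$w[, , 1]
  inlet <- -sum(win[ftype$w[, , d[3] + 1] == 2L]) * A
  om <- ftype$w[, , 1] == 3L
  outlet <- -sum(wout[om]) * A
  xc <- grid$origin[1] + (seq_len(d[1]) - 0.5) * grid$h
  xs <- matrix(xc, d[1], d[2])
  neg <- om & xs < 0
  pos <- om & xs >= 0
  list(inlet = inlet, outlet = outlet,
       outlet_by_side = c(neg = -sum(wout[neg]) * A, pos = -sum(wout[pos]) * A))
}

#' Analytic flux-conserving blood flow
#'
#' Fast fallback for desk runs and tests: a Poiseuille profile is oriented
#' along the local centerline tangent of the nearest vessel branch (root
#' carries the full flux, each daughter half), walls are zeroed (no slip), the
#' inlet gets the exact parabolic profile, and the result is projected to be
#' discretely divergence-free in the lumen.
#'
#' @param geom a [build_geometry()] object
#' @param grid the [voxelize()] grid of `geom`
#' @param V average root inlet speed, m/s
#' @return a `flow_field`
#' @export
analytic_flow <- function(geom, grid, V) {
  d <- grid$dims
  h <- grid$h
  p <- geom$params
  ftype <- classify_faces(grid)
  u <- array(0, d + c(1, 0, 0))
  v <- array(0, d + c(0, 1, 0))
  w <- array(0, d + c(0, 0, 1))
  if (V > 0) {
    branches <- list(
      list(line = geom$centerlines$root, r = p$D0 / 2, vbar = V),
      list(line = geom$centerlines$daughter_pos, r = p$D1 / 2, vbar = V * 2^(-1 / 3)),
      list(line = geom$centerlines$daughter_neg, r = p$D1 / 2, vbar = V * 2^(-1 / 3)))
    fill <- function(ids, fd, offset, comp_axis) {
      if (!length(ids)) return(numeric(0))
      k <- (ids - 1L) %/% (fd[1] * fd[2]); r <- (ids - 1L) %% (fd[1] * fd[2])
      j <- r %/% fd[1]; i <- r %% fd[1]
      P <- cbind(grid$origin[1] + (i + offset[1]) * h,
                 grid$origin[2] + (j + offset[2]) * h,
                 grid$origin[3] + (k + offset[3]) * h)
      nb <- length(branches)
      sf <- matrix(Inf, nrow(P), nb)
      bv <- matrix(0, nrow(P), nb)
      for (q in seq_len(nb)) {
        b <- branches[[q]]
        line <- b$line
        dmin <- rep(Inf, nrow(P)); tx <- numeric(nrow(P))
        for (s in seq_len(nrow(line) - 1)) {
          dseg <- dist_point_segment(P, line[s, ], line[s + 1, ])
          dirv <- line[s + 1, ] - line[s, ]
          dirv <- dirv / sqrt(sum(dirv^2))
          upd <- dseg < dmin
          dmin[upd] <- dseg[upd]
          tx[upd] <- dirv[comp_axis]
        }
        sf[, q] <- dmin / b$r
        bv[, q] <- tx * 2 * b$vbar * pmax(0, 1 - pmin(sf[, q], 1)^2)
      }
      # nearest branch wins; exact ties (mirror plane) are averaged so the
      # field stays mirror-symmetric across the bifurcation plane
      best <- do.call(pmin, asplit(sf, 2))
      tie <- sweep(sf, 1, best, `-`) < 1e-9
      rowSums(bv * tie) / rowSums(tie)
    }
    iu <- which(ftype$u == 1L)
    u[iu] <- fill(iu, d + c(1, 0, 0), c(0, 0.5, 0.5), 1)
    iv <- which(ftype$v == 1L)
    v[iv] <- fill(iv, d + c(0, 1, 0), c(0.5, 0, 0.5), 2)
    iw <- which(ftype$w %in% c(1L, 3L))
    w[iw] <- fill(iw, d + c(0, 0, 1), c(0.5, 0.5, 0), 3)
    inl <- inlet_w_values(grid, ftype, V, p$D0)
    w[inl$ids] <- inl$values
    pois <- lumen_poisson(grid, ftype)
    pr <- project_divfree(u, v, w, grid, ftype, pois)
    u <- pr$u; v <- pr$v; w <- pr$w
  }
  fp <- flow_params(V = max(V, 0))
  Re <- fp$rho * V * (p$D0 / 1000) / fp$mu
  if (Re >= 2300)
    warning(sprintf("Re = %.0f is beyond the laminar regime assumed here", Re))
  new_flow_field(u, v, w, grid, V, "analytic", list(Re = Re))
}

# ---- steady Navier-Stokes solve (projection / pseudo-time marching) -------

# structure for one velocity component's momentum equation
mac_component <- function(ftype_arr, comp_axis, d, inlet = NULL) {
  fd <- dim(ftype_arr)
  ids <- which(ftype_arr == 1L)
  n <- length(ids)
  rowmap <- integer(prod(fd)); rowmap[ids] <- seq_len(n)
  nbr <- list(); typ <- list()
  dirs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  diagc <- rep(0, n)
  ii <- integer(0); jj <- integer(0)
  rhs_fix <- rep(0, n)   # prescribed (inlet) Dirichlet neighbor contributions
  for (q in 1:6) {
    nb <- shift_index(ids, fd, dirs[q, ])
    tq <- ifelse(is.na(nb), -1L, ftype_arr[ifelse(is.na(nb), 1L, nb)])
    nbr[[q]] <- nb; typ[[q]] <- tq
    normal <- ((q + 1) %/% 2) == comp_axis
    inter <- which(tq == 1L)
    diagc[inter] <- diagc[inter] + 1
    ii <- c(ii, inter); jj <- c(jj, rowmap[nb[inter]])
    wall <- which(tq == 0L)
    diagc[wall] <- diagc[wall] + if (normal) 1 else 2
    if (!is.null(inlet)) {
      pres <- which(tq == 2L)
      if (length(pres)) {
        diagc[pres] <- diagc[pres] + 1
        vals <- numeric(prod(fd)); vals[inlet$ids] <- inlet$values
        rhs_fix[pres] <- rhs_fix[pres] + vals[nb[pres]]
      }
    }
    # outlet (3) and missing (-1): zero-gradient, no contribution
  }
  list(ids = ids, n = n, rowmap = rowmap, nbr = nbr, typ = typ,
       diagc = diagc, off_i = ii, off_j = jj, rhs_fix = rhs_fix,
       comp_axis = comp_axis)
}

# upwind advection u.grad(q) for component `mc` given all three face arrays
mac_advection <- function(mc, uu, vv, ww, d, h) {
  arrs <- list(uu, vv, ww)
  own <- arrs[[mc$comp_axis]]
  q0 <- own[mc$ids]
  fd <- dim(own)
  kk <- (mc$ids - 1L) %/% (fd[1] * fd[2]); rr <- (mc$ids - 1L) %% (fd[1] * fd[2])
  jj <- rr %/% fd[1]; ii <- rr %% fd[1]
  # transverse velocities averaged to this face
  vel <- vector("list", 3)
  vel[[mc$comp_axis]] <- q0
  for (b in setdiff(1:3, mc$comp_axis)) {
    barr <- arrs[[b]]
    bd <- dim(barr)
    # the two cells flanking this face along comp_axis; each contributes the
    # b-faces on both sides: 4 faces total
    cells <- cbind(ii, jj, kk)
    cells_lo <- cells; cells_lo[, mc$comp_axis] <- cells_lo[, mc$comp_axis] - 1L
    gv <- numeric(length(q0))
    for (cc in list(cells_lo, cells)) {
      for (s in 0:1) {
        f <- cc; f[, b] <- f[, b] + s
        lin <- f[, 1] + bd[1] * (f[, 2] + bd[2] * f[, 3]) + 1L
        ok <- f[, 1] >= 0 & f[, 1] < bd[1] & f[, 2] >= 0 & f[, 2] < bd[2] &
          f[, 3] >= 0 & f[, 3] < bd[3]
        gv <- gv + ifelse(ok, barr[pmax(lin, 1L)], 0) * 0.25
      }
    }
    vel[[b]] <- gv
  }
  adv <- numeric(length(q0))
  for (ax in 1:3) {
    qm <- 2L * ax - 1L; qp <- 2L * ax
    normal <- ax == mc$comp_axis
    getval <- function(q) {
      nb <- mc$nbr[[q]]; tq <- mc$typ[[q]]
      miss <- is.na(nb)
      val <- numeric(length(q0))
      val[miss] <- q0[miss]                       # zero-gradient off-domain
      val[!miss] <- own[nb[!miss]]
      if (!normal) val[tq == 0L] <- -q0[tq == 0L] # tangential wall mirror
      val
    }
    vm <- getval(qm); vp <- getval(qp)
    a <- vel[[ax]]
    adv <- adv + a * ifelse(a > 0, (q0 - vm), (vp - q0)) / h
  }
  adv
}

#' Steady laminar blood flow by pseudo-transient projection
#'
#' Incompressible Navier-Stokes on the staggered voxel grid: explicit
#' first-order upwind advection, implicit viscous diffusion, and an exact
#' pressure projection (sparse Cholesky) every pseudo-time step, marched to a
#' steady state. No-slip stair-step walls, parabolic inlet, zero reference
#' pressure at both outlets.
#'
#' @param grid a [voxelize()] grid containing a connected lumen with an inlet
#'   at the top boundary and outlet(s) at the bottom boundary
#' @param params a [flow_params()] object
#' @param D0 inlet diameter, mm (taken from the grid's geometry when present)
#' @param tol scaled steady-state tolerance: iteration stops when the maximum
#'   velocity change per step falls below `tol * V`
#' @param max_iter pseudo-time iteration cap
#' @param init optional initial `flow_field` (defaults to zero; for full
#'   bifurcation geometries [analytic_flow()] is a much better start)
#' @param cfl advective CFL number of the pseudo-time step
#' @param quiet suppress progress messages
#' @return a `flow_field` with residual history and Reynolds number
#' @export
solve_steady_flow <- function(grid, params = flow_params(), D0 = NULL,
                              tol = 1e-6, max_iter = 10000, init = NULL,
                              cfl = 0.3, quiet = TRUE) {
  stopifnot(inherits(params, "flow_params"))
  d <- grid$dims
  h <- grid$h / 1000
  if (is.null(D0)) {
    if (is.null(grid$geom)) stop("D0 required when the grid has no geometry")
    D0 <- grid$geom$params$D0
  }
  V <- params$V
  ftype <- classify_faces(grid)
  if (!any(ftype$w == 2L)) stop("topology error: lumen has no inlet", call. = FALSE)
  if (!any(ftype$w == 3L)) stop("topology error: lumen has no outlet", call. = FALSE)
  Re <- params$rho * V * (D0 / 1000) / params$mu
  if (Re >= 2300)
    warning(sprintf("Re = %.0f is beyond the laminar regime assumed here", Re))
  u <- array(0, d + c(1, 0, 0))
  v <- array(0, d + c(0, 1, 0))
  w <- array(0, d + c(0, 0, 1))
  if (V == 0)
    return(new_flow_field(u, v, w, grid, V, "solved",
                          list(Re = 0, iterations = 0, residual = 0)))
  if (!is.null(init)) { u[] <- init$u; v[] <- init$v; w[] <- init$w }
  inl <- inlet_w_values(grid, ftype, V, D0)
  w[inl$ids] <- inl$values
  pois <- lumen_poisson(grid, ftype)
  nu <- params$mu / params$rho
  dt <- cfl * h / (2.5 * V)
  lam <- dt * nu / h^2

  mcs <- list(mac_component(ftype$u, 1, d),
              mac_component(ftype$v, 2, d),
              mac_component(ftype$w, 3, d, inlet = inl))
  facs <- lapply(mcs, function(mc) {
    A <- Matrix::sparseMatrix(
      i = c(seq_len(mc$n), mc$off_i), j = c(seq_len(mc$n), mc$off_j),
      x = c(1 + lam * mc$diagc, rep(-lam, length(mc$off_i))),
      dims = c(mc$n, mc$n))
    Matrix::Cholesky(methods::as(A, "symmetricMatrix"), LDL = FALSE)
  })

  res <- Inf
  hist <- numeric(0)
  iter <- 0
  while (iter < max_iter && res > tol * V) {
    iter <- iter + 1
    arrs <- list(u, v, w)
    new_arrs <- arrs
    for (cA in 1:3) {
      mc <- mcs[[cA]]
      if (!mc$n) next
      q0 <- arrs[[cA]][mc$ids]
      adv <- mac_advection(mc, u, v, w, d, h)
      rhs <- q0 - dt * adv + lam * mc$rhs_fix
      sol <- as.numeric(Matrix::solve(facs[[cA]], rhs))
      new_arrs[[cA]][mc$ids] <- sol
    }
    u <- new_arrs[[1]]; v <- new_arrs[[2]]; w <- new_arrs[[3]]
    # outlet: zero-gradient from the cell face above, then projection
    if (length(pois$out_ids))
      w[pois$out_ids] <- w[, , 2][pois$out_ids]
    pr <- project_divfree(u, v, w, grid, ftype, pois)
    res <- max(abs(pr$u - arrs[[1]]), abs(pr$v - arrs[[2]]),
               abs(pr$w - arrs[[3]]))
    u <- pr$u; v <- pr$v; w <- pr$w
    if (!quiet && iter %% 200 == 0)
      message(sprintf("  flow iter %d: residual %.3g", iter, res / V))
    if (iter %% 50 == 0) hist <- c(hist, res / V)
  }
  if (res > tol * V)
    stop(sprintf(
      "solver failure: flow not converged in %d iterations (residual %.3g)",
      max_iter, res / V), call. = FALSE)
  new_flow_field(u, v, w, grid, V, "solved",
                 list(Re = Re, iterations = iter, residual = res / V,
                      residual_history = hist))
}

#' Cell-centered velocity vectors of a flow field
#'
#' @param flow a `flow_field`
#' @param grid the matching grid
#' @return an `n x 3` matrix of cell-center velocities, m/s
#' @export
cell_velocity <- function(flow, grid) {
  d <- grid$dims
  cbind(as.vector((flow$u[-1, , ] + flow$u[-(d[1] + 1), , ]) / 2),
        as.vector((flow$v[, -1, ] + flow$v[, -(d[2] + 1), ]) / 2),
        as.vector((flow$w[, , -1] + flow$w[, , -(d[3] + 1)]) / 2))
}
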