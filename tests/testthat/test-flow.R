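test_that("parabolic inlet profile has the right shape and average", {
  expect_equal(parabolic_inlet(0, 0.2, 0.01), 0.4)        # centerline 2V
  expect_equal(parabolic_inlet(0.005, 0.2, 0.01), 0)      # wall
  expect_error(parabolic_inlet(0.006, 0.2, 0.01), "outside-lumen")
  # area average over the disc equals V: int 2V(1-(2r/D)^2) 2 pi r dr / area
  f <- function(r) parabolic_inlet(r, 0.2, 0.01) * 2 * pi * r
  avg <- stats::integrate(f, 0, 0.005, rel.tol = 1e-10)$value / (pi * 0.005^2)
  expect_equal(avg, 0.2, tolerance = 1e-9)
})

test_that("analytic flow conserves flux and respects the geometry", {
  geom <- build_geometry(bifurcation_params(), probe_spec(Ld = 30))
  grid <- cached("grid_h2.5_Ld30", voxelize(geom, 2.5))
  fl <- analytic_flow(geom, grid, 0.2)
  fx <- flow_fluxes(fl, grid)
  # projection makes inlet and outlet flux equal to machine tolerance
  expect_lt(abs(fx$inlet - fx$outlet) / fx$inlet, 1e-12)
  # symmetric daughters carry half the flux each
  expect_equal(unname(fx$outlet_by_side[1] / fx$outlet), 0.5, tolerance = 1e-9)
  # discrete divergence vanishes in every lumen cell
  ftype <- cryovessel:::classify_faces(grid)
  pois <- cryovessel:::lumen_poisson(grid, ftype)
  dv <- cryovessel:::lumen_divergence(fl$u, fl$v, fl$w, pois, grid$dims)
  expect_lt(max(abs(dv)) / 0.2, 1e-12)
  # root region reproduces the parabolic inlet exactly at the inlet faces
  inl <- cryovessel:::inlet_w_values(grid, ftype, 0.2, 10)
  expect_equal(fl$w[inl$ids], inl$values)
  # no flow outside the lumen, none through the walls
  expect_true(all(fl$u[ftype$u == 0L] == 0))
  expect_true(all(fl$v[ftype$v == 0L] == 0))
  expect_true(all(fl$w[ftype$w == 0L] == 0))
  # far-field daughter mean speed (flux / analytic area) = V * 2^(-1/3)
  vbar_target <- 0.2 * 2^(-1 / 3)
  area <- pi * (daughter_diameter(10) / 2 / 1000)^2
  expect_equal(unname(fx$outlet_by_side[1]) / area, vbar_target,
               tolerance = 0.1)
  # V = 0 gives the zero field
  f0 <- analytic_flow(geom, grid, 0)
  expect_equal(max(abs(f0$u), abs(f0$v), abs(f0$w)), 0)
})

test_that("solved flow recovers Poiseuille in a straight tube", {
  fx <- make_fixture("straight_tube", h = 1)
  fl <- cached("tube_flow_h1", solve_steady_flow(fx$grid, flow_params(V = 0.2),
                                                 D0 = 10, tol = 1e-6))
  d <- fx$grid$dims
  # developed profile at mid-height vs the exact parabola, flux-normalized
  kmid <- round(d[3] / 2)
  wmid <- fl$w[, , kmid]
  lum <- fx$grid$labels[, , kmid] == 2L
  cc <- cell_centers(fx$grid)
  xy <- matrix(cc[1:(d[1] * d[2]), 1:2], ncol = 2)
  r <- sqrt(rowSums(xy^2))[as.vector(lum)]
  wnum <- -wmid[lum]
  A <- (fx$grid$h / 1000)^2
  Vbar <- sum(wnum) * A / (pi * 0.005^2)
  wexact <- 2 * Vbar * pmax(0, 1 - (r / 5)^2)
  relL2 <- sqrt(mean((wnum - wexact)^2)) / (2 * Vbar)
  expect_lt(relL2, 0.05)
  # global mass balance below 1e-6 relative
  fxs <- flow_fluxes(fl, fx$grid)
  expect_lt(abs(fxs$inlet - fxs$outlet) / fxs$inlet, 1e-6)
  expect_lt(fl$Re, 2300)
})

test_that("solved bifurcation flow splits 50/50 and shows the apex features", {
  geom <- build_geometry(bifurcation_params(), list())
  grid <- voxelize(geom, 2.5)
  fl <- cached("bif_flow_h2.5",
               solve_steady_flow(grid, flow_params(V = 0.2),
                                 init = analytic_flow(geom, grid, 0.2),
                                 tol = 1e-6))
  fx <- flow_fluxes(fl, grid)
  expect_lt(abs(fx$inlet - fx$outlet) / fx$inlet, 1e-6)
  split <- fx$outlet_by_side / fx$outlet
  expect_lt(abs(split[[1]] - 0.5), 0.01)
  expect_lt(abs(split[[2]] - 0.5), 0.01)
  expect_equal(fl$Re, 1050 * 0.2 * 0.01 / 2.5e-3, tolerance = 1e-9)  # 840
  # the solved field inherits the geometry's mirror symmetry (x -> -x flips u)
  d <- grid$dims
  expect_lt(max(abs(fl$w - fl$w[d[1]:1, , ])), 1e-4 * 0.2)
  expect_lt(max(abs(fl$u + fl$u[(d[1] + 1):1, , ])), 1e-4 * 0.2)
  vel <- cell_velocity(fl, grid)
  speed <- array(sqrt(rowSums(vel^2)), grid$dims)
  cc <- cell_centers(grid)
  lum <- grid$labels == 2L
  X <- array(cc[, 1], grid$dims)
  Y <- array(cc[, 2], grid$dims)
  Z <- array(cc[, 3], grid$dims)
  # a low-speed region sits adjacent to the bifurcation apex (the dividing
  # streamline stagnates on the carina) while the root mean speed is V
  apex <- lum & abs(X) < 5 & abs(Y) < 5 & Z > -20 & Z < -15
  expect_lt(min(speed[apex]), 0.5 * 0.2)
  # downstream of the apex the daughter profile is skewed toward the inner
  # wall: cells on the axis side of the daughter centerline run faster
  zl <- -25
  xc_line <- 40 * (sqrt(1 - (sin(pi / 3) - (-20 - zl) / 40)^2) - cos(pi / 3))
  sl <- lum & abs(Z - zl) < 1.26 & X > 0 & abs(Y) < 6
  expect_gt(mean(speed[sl & X < xc_line]), mean(speed[sl & X > xc_line]))
})

test_that("flow solver reports failures", {
  fx <- make_fixture("straight_tube", h = 2)
  expect_error(solve_steady_flow(fx$grid, flow_params(V = 0.2), D0 = 10,
                                 max_iter = 3), "not converged")
  # no-lumen grid has no inlet
  lab <- array(cryovessel:::LBL[["TISSUE"]], c(4, 4, 4))
  g <- cryovessel:::make_grid_raw(lab, 2)
  expect_error(solve_steady_flow(g, flow_params(), D0 = 10), "inlet")
})
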