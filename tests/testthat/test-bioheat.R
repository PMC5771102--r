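props0 <- material_properties(omega_cb = 0, Qm = 0)

test_that("uniform body-temperature field is a near-steady state", {
  # no probe, no flow: perfusion vanishes at T = Tcb, the only drift is the
  # metabolic source, bounded by Qm * dt / C = 1.2e-5 degC per 0.1 s step
  fx <- make_fixture("straight_tube", h = 2)
  props <- material_properties()
  field <- temperature_field(array(37, dim(fx$grid$labels)), 0)
  out <- advance(field, NULL, fx$grid, props, boundary_spec(), 0.1)
  drift <- max(abs(out$T - 37))
  # the only drift is metabolic, Qm*dt/C ~ 1.2e-5 degC (resolved exactly by
  # the single-cell test below; here it may sit below the linear tolerance)
  expect_lt(drift, 2 * 420 * 0.1 / 3.6e6)
})

test_that("single adiabatic cell follows the closed-form source balance", {
  fx <- make_fixture("single_cell")
  props <- material_properties()
  field <- temperature_field(array(30, c(1, 1, 1)), 0)
  out <- advance(field, NULL, fx$grid, props, boundary_spec(), 0.5)
  # implicit balance: C (T' - T0)/dt = omega Cb (Tcb - T') + Qm
  a <- props$omega_cb * props$Cb
  Texp <- (props$Ct * 30 / 0.5 + a * 37 + 420) / (props$Ct / 0.5 + a)
  expect_equal(out$T[1, 1, 1], Texp, tolerance = 1e-9)
})

test_that("transient conduction matches the semi-infinite erf solution", {
  # all-frozen temperature range isolates the diffusion operator
  fx <- make_fixture("slab_1d", n = 120, h = 0.5)
  bounds <- boundary_spec(T_probe = -150)
  field <- run_slab_to(fx$grid, props0, bounds, tend = 3, T_init = -50)
  x <- (seq_len(120) - 1.5) * 0.5e-3
  alpha <- props0$kappa_f / props0$Cf
  Tan <- semi_infinite_conduction(x[2:120], 3, -50, -150, alpha)
  err <- sqrt(mean((field$T[2:120, 1, 1] - Tan)^2)) / 100
  expect_lt(err, 0.02)
})

test_that("implicit upwind steps obey the discrete maximum principle", {
  set.seed(11)
  fx <- make_fixture("straight_tube", h = 2)
  geom <- build_geometry(bifurcation_params(), list())
  # random initial fields between probe and body temperature
  for (rep in 1:3) {
    Tarr <- array(stats::runif(prod(fx$grid$dims), -196, 37), fx$grid$dims)
    field <- temperature_field(Tarr, 0)
    out <- advance(field, NULL, fx$grid, material_properties(), boundary_spec(),
                   0.5)
    qm_bound <- 420 * 0.5 / 1.8e6
    expect_lt(max(out$T), max(Tarr, 37) + qm_bound + 1e-6)
    expect_gt(min(out$T), min(Tarr, -196) - 1e-6)
  }
})

test_that("energy is conserved to the enthalpy budget", {
  # adiabatic tissue box with a nonuniform initial state spanning the phase
  # transition; total enthalpy change must equal the integrated sources
  lab <- array(cryovessel:::LBL[["TISSUE"]], c(12, 12, 12))
  grid <- cryovessel:::make_grid_raw(lab, 2, origin = c(0, 0, 0))
  props <- material_properties()   # perfusion + metabolism active
  cc <- cell_centers(grid)
  Tarr <- array(-40 + 3 * cc[, 3], grid$dims)  # -40 .. 29 degC
  field <- temperature_field(Tarr, 0)
  Vm3 <- (grid$h / 1000)^3
  H0 <- sum(tissue_enthalpy(field$T, props)) * Vm3
  Qsum <- 0
  for (s in 1:20) {
    field <- advance(field, NULL, grid, props, boundary_spec(), 0.5)
    dg <- attr(field, "diagnostics")
    Qsum <- Qsum + 0.5 * (dg$Q_perfusion + dg$Q_metabolic + dg$Q_probe +
                            dg$Q_boundary)
  }
  H1 <- sum(tissue_enthalpy(field$T, props)) * Vm3
  expect_lt(abs((H1 - H0) - Qsum) / abs(Qsum), 0.005)
})

test_that("warm blood flowing through a cold tube carries heat downstream", {
  fx <- make_fixture("straight_tube", h = 2)
  grid <- fx$grid
  geom <- build_geometry(bifurcation_params(), list())  # only for profile
  # build a plug analytic field directly on the fixture tube
  ftype <- cryovessel:::classify_faces(grid)
  w <- array(0, grid$dims + c(0, 0, 1))
  inl <- cryovessel:::inlet_w_values(grid, ftype, 0.1, 10)
  w[inl$ids] <- inl$values
  w[ftype$w %in% c(1L, 3L)] <- -0.1
  u <- array(0, grid$dims + c(1, 0, 0)); v <- array(0, grid$dims + c(0, 1, 0))
  pois <- cryovessel:::lumen_poisson(grid, ftype)
  pr <- cryovessel:::project_divfree(u, v, w, grid, ftype, pois)
  flow <- cryovessel:::new_flow_field(pr$u, pr$v, pr$w, grid, 0.1, "analytic")
  field <- temperature_field(array(0, grid$dims), 0)
  props <- material_properties(omega_cb = 0, Qm = 0)
  for (i in 1:40) field <- advance(field, flow, grid, props,
                                   boundary_spec(T_inlet = 37), 0.05)
  lum <- grid$labels == 2L
  # lumen warms from the inlet end; deepest cells stay coolest
  Tl <- field$T
  zc <- array(cell_centers(grid)[, 3], grid$dims)
  expect_gt(mean(Tl[lum & zc > -6]), mean(Tl[lum & zc < -24]))
  expect_gt(max(Tl[lum]), 25)
  # tissue adjacent to the lumen is warmed through the conjugate interface
  faces <- interface_faces(grid)
  expect_gt(max(Tl[faces$tissue]), 0.5)
})

test_that("V = 0 flow leaves the field to pure conduction symmetry", {
  fx <- make_fixture("straight_tube", h = 2)
  geom <- build_geometry(bifurcation_params(), list())
  flow0 <- analytic_flow(geom, voxelize(geom, 5), 0)
  expect_equal(max(abs(flow0$u), abs(flow0$v), abs(flow0$w)), 0)
})

test_that("advance reports failures and diagnostics", {
  fx <- make_fixture("single_cell")
  field <- temperature_field(array(37, c(1, 1, 1)), 0)
  out <- advance(field, NULL, fx$grid, material_properties(), boundary_spec(),
                 0.1)
  dg <- attr(out, "diagnostics")
  expect_true(dg$converged)
  expect_true(is.finite(dg$Q_perfusion))
  expect_error(advance(field, NULL, fx$grid, material_properties(),
                       boundary_spec(), -1), "dt > 0")
})
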