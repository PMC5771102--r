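# Session-level cache so several test files can share expensive simulations.
.case_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .case_cache))
    assign(key, force(expr), envir = .case_cache)
  get(key, envir = .case_cache)
}

# Desk-scale single-probe freezing case: h = 2 mm (the 4 mm probe rasterizes
# at exactly its own width there), time-step scale 20 (changes 20-min volumes
# by < 0.1%), analytic flow, metrics at the end time only (the wall series is
# tracked every step regardless). The problem size used for all 20-minute
# table checks.
desk_case <- function(Ld, V, end_time = 1200, ...) {
  cached(sprintf("desk_Ld%g_V%g_t%g", Ld, V, end_time), {
    cryo_simulate(probes = probe_spec(Ld = Ld), V = V, h = 2,
                  dt_scale = 20, end_time = end_time,
                  metric_interval = end_time, ...)
  })
}

# Vessel-injury timing case: unscaled fine schedule until the wall freezes.
wall_case <- function(Ld, V, h = 2, end_time = 200) {
  cached(sprintf("wall_Ld%g_V%g_h%g", Ld, V, h), {
    run_simulation(cryo_config(probes = probe_spec(Ld = Ld), V = V, h = h,
                               dt_scale = 1, end_time = end_time,
                               stop_when_wall_frozen = TRUE))
  })
}

# Freezing-front error of the conjugate solver against the sharp-front
# Neumann-Stefan oracle on the 1-d slab, over three refinement levels
# (h = 2, 1, 0.5 mm with proportional time-step scales).
stefan_front_errors <- function() {
  cached("stefan_errs", {
    sp <- stefan_params()
    lam <- neumann_stefan_lambda(sp)
    tend <- 600
    X <- 2 * lam * sqrt(sp$alpha_s * tend)
    props <- material_properties(omega_cb = 0, Qm = 0)
    bounds <- boundary_spec()
    vapply(list(c(60, 2, 10), c(120, 1, 5), c(240, 0.5, 2.5)), function(cfg) {
      fx <- make_fixture("slab_1d", n = cfg[1], h = cfg[2])
      field <- run_slab_to(fx$grid, props, bounds, tend, dt_scale = cfg[3])
      abs(slab_front(field, fx$grid) - X) / X
    }, numeric(1))
  })
}

run_slab_to <- function(grid, props, bounds, tend, dt_scale = 1, flow = NULL,
                        T_init = 37, opts = cryovessel:::default_step_opts()) {
  field <- temperature_field(array(T_init, dim(grid$labels)), 0)
  t <- 0
  while (t < tend - 1e-12) {
    dt <- min(time_step(t, dt_scale), tend - t)
    field <- advance(field, flow, grid, props, bounds, dt, opts)
    t <- field$time
  }
  field
}

# interpolated position of the T = T_iso isotherm along a 1-d slab profile
slab_front <- function(field, grid, T_iso = -4.5) {
  n <- dim(field$T)[1]
  xs <- (seq_len(n) - 1.5) * grid$h * 1e-3  # m from the Dirichlet wall face
  Tn <- field$T[, 1, 1]
  i <- which(Tn[-n] <= T_iso & Tn[-1] > T_iso)[1]
  xs[i] + (T_iso - Tn[i]) * (xs[i + 1] - xs[i]) / (Tn[i + 1] - Tn[i])
}
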