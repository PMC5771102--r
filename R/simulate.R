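#' Construct a temperature field
#'
#' @param T temperature array matching the grid dims, degC
#' @param time simulated time, s
#' @return an object of class `temperature_field`
#' @export
temperature_field <- function(T, time = 0) {
  out <- list(T = T, time = time)
  class(out) <- "temperature_field"
  out
}

default_step_opts <- function(advection_order = 1, picard_tol = 1e-3,
                              picard_max = 50, relax = 0.8,
                              lin_tol = 1e-6, lin_max = 3000) {
  list(picard_tol = picard_tol, picard_max = picard_max, relax = relax,
       lin_tol = lin_tol, lin_max = lin_max,
       advection_order = as.integer(advection_order))
}

#' Advance the conjugate temperature field by one implicit step
#'
#' One backward-Euler step of the coupled system: the Pennes equation with
#' effective phase-change properties in TISSUE cells and advection-diffusion
#' with the frozen steady flow in LUMEN cells, flux-continuous across the
#' artery surface (harmonic-mean face conductivity). Dirichlet probe
#' temperature on PROBE_TIP faces, zero flux on shaft and outer shell,
#' inlet temperature where the flow enters, zero gradient where it leaves.
#' The nonlinearity (apparent heat capacity, conductivity, perfusion switch)
#' is resolved by Picard iteration with an enthalpy-consistent chord capacity.
#'
#' @param field a [temperature_field()]
#' @param flow a `flow_field` or `NULL` (no flow: pure conduction)
#' @param grid the [voxelize()] grid
#' @param props a [material_properties()] object
#' @param bounds a [boundary_spec()] object
#' @param dt time step, s
#' @param opts solver controls, see `cryovessel:::default_step_opts`
#' @param plan precomputed stepping plan from [heat_plan()]; built on the fly
#'   when omitted (build it once when advancing many steps)
#' @return the advanced `temperature_field`, with step diagnostics (Picard
#'   iterations, boundary/source powers in W) in attribute `"diagnostics"`
#' @export
advance <- function(field, flow, grid, props, bounds, dt,
                    opts = default_step_opts(), plan = NULL) {
  stopifnot(dt > 0, inherits(props, "material_properties"),
            inherits(bounds, "boundary_spec"))
  if (is.null(plan)) plan <- heat_plan(grid, flow)
  res <- cpp_heat_step(plan, as.numeric(field$T), grid$h / 1000, dt,
                       unclass(props), unclass(bounds), opts)
  out <- temperature_field(array(res$T, grid$dims), field$time + dt)
  attr(out, "diagnostics") <- res[c("picard", "max_change", "converged",
                                    "lin_iters", "Q_probe", "Q_boundary",
                                    "Q_perfusion", "Q_metabolic")]
  out
}

#' Precompute the conjugate-step topology for a grid and flow field
#'
#' Active-cell numbering, neighbor tables and outward face velocities are
#' fixed for a whole run; building them once saves a third of the stepping
#' cost.
#'
#' @param grid a [voxelize()] grid
#' @param flow a `flow_field` or `NULL` for no flow
#' @return an opaque plan list consumed by [advance()]
#' @export
heat_plan <- function(grid, flow = NULL) {
  d <- grid$dims
  if (is.null(flow)) {
    u <- numeric((d[1] + 1) * d[2] * d[3])
    v <- numeric(d[1] * (d[2] + 1) * d[3])
    w <- numeric(d[1] * d[2] * (d[3] + 1))
  } else {
    u <- as.numeric(flow$u); v <- as.numeric(flow$v); w <- as.numeric(flow$w)
  }
  cpp_heat_plan(as.integer(grid$labels), as.integer(d), u, v, w)
}

#' Assemble a full simulation configuration
#'
#' @param params a [bifurcation_params()] object
#' @param probes a [probe_spec()] or list of them (may be empty)
#' @param h voxel size, mm
#' @param V average root inlet speed, m/s
#' @param flow `"analytic"` (fast desk mode) or `"solved"` (projection
#'   Navier-Stokes)
#' @param dt_scale multiplier on the nonuniform time-step schedule
#' @param end_time freezing duration, s
#' @param metric_interval metric sampling cadence, s of simulated time
#' @param checkpoint_times times at which to keep full temperature fields, s
#' @param props,bounds material and boundary specifications
#' @param advection_order 1 (upwind) or 2 (deferred-correction linear upwind)
#' @param sample_point position whose temperature is tracked, mm (default:
#'   on the cylinder axis, 12 mm from the first probe's centerline)
#' @param max_overlap probe-placement tolerance, mm (see [build_geometry()])
#' @param fine_until duration over which the time-step scale is forced to 1, s
#'   (resolves short vessel-injury treatment times in coarse runs)
#' @param stop_when_wall_frozen end the run as soon as the minimum artery-wall
#'   temperature reaches 0 degC
#' @return a `cryo_config` list
#' @export
cryo_config <- function(params = bifurcation_params(),
                        probes = list(probe_spec()),
                        h = 2.5, V = 0.2, flow = c("analytic", "solved"),
                        dt_scale = 10, end_time = 1200, metric_interval = 1,
                        checkpoint_times = numeric(0),
                        props = material_properties(),
                        bounds = boundary_spec(),
                        advection_order = 1, sample_point = NULL,
                        max_overlap = 1.5, fine_until = 0,
                        stop_when_wall_frozen = FALSE) {
  flow <- match.arg(flow)
  if (inherits(probes, "probe_spec")) probes <- list(probes)
  cfg <- list(params = params, probes = probes, h = h, V = V, flow = flow,
              dt_scale = dt_scale, end_time = end_time,
              metric_interval = metric_interval,
              checkpoint_times = checkpoint_times, props = props,
              bounds = bounds, advection_order = advection_order,
              sample_point = sample_point, max_overlap = max_overlap,
              fine_until = fine_until,
              stop_when_wall_frozen = stop_when_wall_frozen)
  class(cfg) <- "cryo_config"
  cfg
}

#' Run a cryosurgery freezing simulation
#'
#' End-to-end pipeline: build the analytic geometry, voxelize it, obtain the
#' steady blood flow (held fixed during freezing), then march the conjugate
#' temperature field from a uniform 37 degC initial state through the
#' nonuniform time-step schedule, recording the metric series (iceball and
#' lethal volumes, artery-surface heat flux, minimum wall temperature, sample
#' point temperature) and optional field checkpoints.
#'
#' @param config a [cryo_config()] list
#' @param quiet suppress progress messages
#' @return an object of class `cryosim`
#' @export
run_simulation <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "cryo_config"))
  t_start <- proc.time()[["elapsed"]]
  geom <- build_geometry(config$params, config$probes,
                         max_overlap = config$max_overlap)
  grid <- voxelize(geom, config$h)
  fp <- flow_params(V = config$V)
  flow <- if (config$V == 0) {
    analytic_flow(geom, grid, 0)
  } else if (config$flow == "analytic") {
    analytic_flow(geom, grid, config$V)
  } else {
    solve_steady_flow(grid, fp, init = analytic_flow(geom, grid, config$V),
                      quiet = quiet)
  }
  faces <- if (any(grid$labels == LBL[["LUMEN"]]) &&
               any(grid$labels == LBL[["TISSUE"]]))
    interface_faces(grid) else NULL
  min_wall <- function(field) {
    if (is.null(faces)) return(NA_real_)
    min(wall_face_temperature(field$T, faces, config$props))
  }
  sp <- config$sample_point
  if (is.null(sp) && length(geom$probes))
    sp <- geom$probes[[1]]$tip_center + c(0, 0, 12)
  opts <- default_step_opts(advection_order = config$advection_order)
  plan <- heat_plan(grid, flow)

  field <- temperature_field(array(config$bounds$T_inlet, grid$dims), 0)
  take_metrics <- function(field) {
    data.frame(
      time = field$time,
      iceball_volume = threshold_volume(field, grid, 0),
      lethal_volume = threshold_volume(field, grid, -40),
      artery_surface_flux = if (!is.null(faces))
        artery_surface_flux(field, grid, faces, config$props) else NA_real_,
      min_wall_temperature = min_wall(field),
      sample_point_temperature = if (!is.null(sp))
        sample_point_temperature(field, grid, sp) else NA_real_)
  }
  metrics <- list(take_metrics(field))
  wall_t <- 0
  wall_T <- metrics[[1]]$min_wall_temperature
  checkpoints <- list()
  picard_total <- 0L; lin_total <- 0L; nsteps <- 0L
  stops <- sort(unique(c(config$checkpoint_times,
                         seq(0, config$end_time, by = config$metric_interval),
                         config$end_time)))
  stops <- stops[stops > 1e-12]
  t <- 0
  while (t < config$end_time - 1e-9) {
    scale <- if (t < (config$fine_until %||% 0)) 1 else config$dt_scale
    dt <- time_step(t, scale)
    nxt <- stops[stops > t + 1e-9][1]
    dt <- min(dt, nxt - t)
    field <- advance(field, flow, grid, config$props, config$bounds, dt, opts,
                     plan = plan)
    t <- field$time
    dg <- attr(field, "diagnostics")
    picard_total <- picard_total + dg$picard
    lin_total <- lin_total + dg$lin_iters
    nsteps <- nsteps + 1L
    if (!is.null(faces)) {
      wall_t <- c(wall_t, t)
      wall_T <- c(wall_T, min_wall(field))
    }
    if (any(abs(config$checkpoint_times - t) < 1e-9))
      checkpoints[[sprintf("t=%gs", t)]] <- field
    if (min(abs(nxt - t), abs(t - config$end_time)) < 1e-9)
      metrics[[length(metrics) + 1]] <- take_metrics(field)
    if (!quiet && nsteps %% 100 == 0)
      message(sprintf("  t = %.1f s (%d steps)", t, nsteps))
    if (isTRUE(config$stop_when_wall_frozen) && !is.null(faces) &&
        wall_T[length(wall_T)] <= 0) {
      metrics[[length(metrics) + 1]] <- take_metrics(field)
      break
    }
  }
  metrics <- do.call(rbind, metrics)
  metrics <- metrics[!duplicated(metrics$time), ]
  ttime <- if (!is.null(faces))
    treatment_time(wall_t, wall_T, horizon = config$end_time) else NA_real_
  out <- list(
    metrics = metrics, config = config, grid = grid, flow = flow,
    faces = faces, final_field = field, checkpoints = checkpoints,
    wall_series = if (!is.null(faces))
      data.frame(time = wall_t, min_wall_temperature = wall_T),
    treatment_time = ttime,
    log = list(steps = nsteps, picard_total = picard_total,
               lin_iters_total = lin_total,
               elapsed_s = proc.time()[["elapsed"]] - t_start))
  class(out) <- "cryosim"
  out
}

#' Simulate cryosurgical freezing (convenience front end)
#'
#' Builds a [cryo_config()] from the arguments and calls [run_simulation()].
#'
#' @param ... passed to [cryo_config()]
#' @param quiet suppress progress messages
#' @return a `cryosim` object
#' @export
#' @examples
#' \donttest{
#' sim <- cryo_simulate(probes = probe_spec(Ld = 30), h = 2, end_time = 60,
#'                      dt_scale = 10)
#' sim
#' plot(sim)
#' }
cryo_simulate <- function(..., quiet = TRUE) {
  run_simulation(cryo_config(...), quiet = quiet)
}

#' @export
print.cryosim <- function(x, ...) {
  m <- x$metrics[nrow(x$metrics), ]
  cat(sprintf("Cryosurgery simulation: %d probe(s), V = %g m/s, t = %g s\n",
              length(x$config$probes), x$config$V, m$time))
  cat(sprintf("  grid h = %g mm (%s flow), %d steps\n",
              x$config$h, x$flow$mode, x$log$steps))
  cat(sprintf("  iceball volume  %7.2f cm^3 (T <= 0 degC)\n", m$iceball_volume))
  cat(sprintf("  lethal volume   %7.2f cm^3 (T <= -40 degC)\n", m$lethal_volume))
  if (is.finite(m$min_wall_temperature))
    cat(sprintf("  min artery-wall temperature %.2f degC\n",
                m$min_wall_temperature))
  if (!is.na(x$treatment_time))
    cat(sprintf("  treatment time (wall reaches 0 degC): %s\n",
                if (is.finite(x$treatment_time))
                  sprintf("%.2f s", x$treatment_time) else "exceeds horizon"))
  invisible(x)
}

#' @export
summary.cryosim <- function(object, ...) {
  print(object)
  cat(sprintf("  artery-surface heat flux at end: %.2f W\n",
              object$metrics$artery_surface_flux[nrow(object$metrics)]))
  cat(sprintf("  Picard iterations: %d total; linear iterations: %d; %.1f s wall time\n",
              object$log$picard_total, object$log$lin_iters_total,
              object$log$elapsed_s))
  invisible(object)
}

#' @export
plot.cryosim <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  m <- x$metrics
  graphics::plot(m$time / 60, m$iceball_volume, type = "l", lwd = 2,
                 xlab = "time [min]", ylab = "volume [cm^3]",
                 main = "Frozen volumes")
  graphics::lines(m$time / 60, m$lethal_volume, lwd = 2, lty = 2)
  graphics::legend("topleft", c("iceball (0 degC)", "lethal (-40 degC)"),
                   lty = 1:2, lwd = 2, bty = "n")
  if (!is.null(x$wall_series)) {
    graphics::plot(x$wall_series$time / 60, x$wall_series$min_wall_temperature,
                   type = "l", lwd = 2, xlab = "time [min]",
                   ylab = "min wall temperature [degC]",
                   main = "Artery wall")
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}
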