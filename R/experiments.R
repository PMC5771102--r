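# Desk fidelity uses h = 2 mm: the standard 4 mm probe then rasterizes at
# exactly its own width (cell faces aligned with the probe surface), which the
# vessel-wall metrics are sensitive to; at 2.5 mm the probe is a cell too fat.
fidelity_settings <- function(fidelity = c("desk", "convergence")) {
  fidelity <- match.arg(fidelity)
  if (fidelity == "desk") list(h = 2, dt_scale = 10, flow = "analytic")
  else list(h = 1, dt_scale = 1, flow = "solved")
}

#' Run a single configured cryosurgery case
#'
#' Geometry, flow, simulation and metrics, fully deterministic given the
#' configuration; optionally writes the metric series (CSV) and a JSON summary
#' embedding the resolved configuration.
#'
#' @param config a [cryo_config()] list
#' @param out_dir optional output directory for `metrics.csv`, `summary.json`
#' @param quiet suppress progress messages
#' @return a `cryosim` object
#' @export
run_case <- function(config, out_dir = NULL, quiet = TRUE) {
  sim <- run_simulation(config, quiet = quiet)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(sim$metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    m <- sim$metrics[nrow(sim$metrics), ]
    jsonlite::write_json(
      list(final = as.list(m), treatment_time_s = sim$treatment_time,
           config = config_to_list(config)),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE, null = "null")
    writeLines(c(
      sprintf("steps: %d", sim$log$steps),
      sprintf("picard iterations: %d", sim$log$picard_total),
      sprintf("linear iterations: %d", sim$log$lin_iters_total),
      sprintf("flow mode: %s%s", sim$flow$mode,
              if (!is.null(sim$flow$Re)) sprintf(" (Re = %.0f)", sim$flow$Re)
              else ""),
      sprintf("wall time: %.1f s", sim$log$elapsed_s)),
      file.path(out_dir, "run-log.txt"))
  }
  sim
}

#' Parameter sweep over probe distance or inlet velocity
#'
#' Reproduces the single-probe parameter studies: freezing for `end_time`
#' seconds at each value of the varying parameter, with everything else fixed.
#'
#' @param parameter `"Ld"` (probe-tip distance below the bifurcation, mm) or
#'   `"V"` (root inlet average velocity, m/s)
#' @param values parameter values (non-empty)
#' @param Ld,V the fixed value of the non-varying parameter
#' @param Dp,Lp probe diameter and active-tip length, mm
#' @param end_time freezing duration, s
#' @param fidelity `"desk"` (h = 2.5 mm, time-step scale 10, analytic flow) or
#'   `"convergence"` (h = 1 mm, scale 1, solved flow)
#' @param out_dir optional output directory (per-case subdirectories)
#' @param quiet suppress progress messages
#' @param ... overrides passed to [cryo_config()] (e.g. `h`, `dt_scale`)
#' @return data frame with one row per case: final iceball/lethal volumes
#'   (cm^3), artery-surface flux (W), minimum wall temperature (degC) and
#'   treatment time (s); the `cryosim` objects are attached as attribute
#'   `"sims"`
#' @export
run_sweep <- function(parameter = c("Ld", "V"), values, Ld = 30, V = 0.2,
                      Dp = 4, Lp = 22, end_time = 1200, fidelity = "desk",
                      out_dir = NULL, quiet = TRUE, ...) {
  parameter <- match.arg(parameter)
  if (!length(values)) stop("value list must be non-empty", call. = FALSE)
  fs <- fidelity_settings(fidelity)
  rows <- list()
  sims <- list()
  for (val in values) {
    ld <- if (parameter == "Ld") val else Ld
    vv <- if (parameter == "V") val else V
    args <- list(probes = probe_spec(Dp = Dp, Lp = Lp, Ld = ld), V = vv,
                 h = fs$h, dt_scale = fs$dt_scale, flow = fs$flow,
                 end_time = end_time)
    dots <- list(...)
    args[names(dots)] <- dots
    cfg <- do.call(cryo_config, args)
    sim <- run_case(cfg, out_dir = if (!is.null(out_dir))
      file.path(out_dir, sprintf("%s_%g", parameter, val)), quiet = quiet)
    m <- sim$metrics[nrow(sim$metrics), ]
    rows[[length(rows) + 1]] <- data.frame(
      Ld = ld, V = vv, iceball_volume = m$iceball_volume,
      lethal_volume = m$lethal_volume,
      artery_surface_flux = m$artery_surface_flux,
      min_wall_temperature = m$min_wall_temperature,
      treatment_time = sim$treatment_time)
    sims[[sprintf("%s=%g", parameter, val)]] <- sim
  }
  out <- do.call(rbind, rows)
  attr(out, "sims") <- sims
  out
}

#' Treatment-time matrix over probe distance and inlet velocity
#'
#' For every (Ld, V) combination, the time at which the minimum artery-surface
#' temperature first reaches 0 degC (`Inf` = exceeds the horizon). Runs stop
#' as soon as the wall freezes; short treatment times are resolved by forcing
#' the unscaled fine time-step schedule over the first `fine_until` seconds.
#'
#' @param Ld_values probe distances, mm
#' @param V_values inlet velocities, m/s
#' @param horizon freezing-duration horizon, s (20 min default)
#' @param fidelity,quiet,... see [run_sweep()]
#' @param fine_until duration over which the time-step scale is forced to 1, s
#' @return matrix of treatment times, s (rows = V, columns = Ld)
#' @export
run_table3 <- function(Ld_values = c(10, 15, 20, 30, 40),
                       V_values = c(0.01, 0.05, 0.1, 0.2, 0.3),
                       horizon = 1200, fidelity = "desk", fine_until = 120,
                       quiet = TRUE, ...) {
  stopifnot(length(Ld_values) > 0, length(V_values) > 0)
  fs <- fidelity_settings(fidelity)
  tt <- matrix(NA_real_, length(V_values), length(Ld_values),
               dimnames = list(sprintf("V=%g", V_values),
                               sprintf("Ld=%g", Ld_values)))
  if (horizon <= 0) { tt[] <- Inf; return(tt) }
  for (a in seq_along(V_values)) for (b in seq_along(Ld_values)) {
    args <- list(probes = probe_spec(Ld = Ld_values[b]), V = V_values[a],
                 h = fs$h, dt_scale = fs$dt_scale, flow = fs$flow,
                 end_time = horizon, fine_until = fine_until,
                 stop_when_wall_frozen = TRUE)
    dots <- list(...)
    args[names(dots)] <- dots
    cfg <- do.call(cryo_config, args)
    sim <- run_simulation(cfg, quiet = quiet)
    tt[a, b] <- sim$treatment_time
  }
  tt
}

#' Three-probe freezing run
#'
#' Three probes distributed uniformly on a circle in the bifurcation plane,
#' centered on the cylinder axis below the bifurcation point, axes parallel
#' to y (see [three_probe_layout()]); checkpoints keep the full temperature
#' field for iceball-morphology inspection.
#'
#' @param Ld circle-center depth below the bifurcation point, mm
#' @param radius circle radius, mm
#' @param Dp,Lp probe diameter and active-tip length, mm
#' @param V root inlet velocity, m/s
#' @param end_time freezing duration, s (25 min default)
#' @param h voxel size, mm; must genuinely resolve `Dp` (the default 2 mm
#'   probes need h <= 1.25 mm — on coarser grids their axes fall between cell
#'   centers and no tip cell is produced)
#' @param checkpoint_times checkpoint times, s
#' @param quiet,... see [run_sweep()]
#' @return a `cryosim` object
#' @export
run_three_probe <- function(Ld = 30, radius = 20, Dp = 2, Lp = 20, V = 0.2,
                            end_time = 1500, h = 1.25,
                            checkpoint_times = c(300, 900, 1500),
                            quiet = TRUE, ...) {
  cfg <- cryo_config(probes = three_probe_layout(Ld = Ld, radius = radius,
                                                 Dp = Dp, Lp = Lp),
                     V = V, h = h, end_time = end_time,
                     checkpoint_times = checkpoint_times, ...)
  run_simulation(cfg, quiet = quiet)
}

#' Count connected frozen components
#'
#' Number of 6-connected components of the tissue region with `T <= T_thr`
#' (distinct iceballs).
#'
#' @param field a `temperature_field` or temperature array
#' @param grid the matching grid
#' @param T_thr threshold, degC
#' @return integer component count
#' @export
iceball_components <- function(field, grid, T_thr = 0) {
  Tarr <- field_array(field)
  d <- grid$dims
  mask <- grid$labels == LBL[["TISSUE"]] & Tarr <= T_thr
  ids <- which(mask)
  if (!length(ids)) return(0L)
  comp <- 0L
  strides <- c(1L, d[1], d[1] * d[2])
  remaining <- logical(length(mask)); remaining[ids] <- TRUE
  while (any(remaining)) {
    comp <- comp + 1L
    frontier <- which(remaining)[1]
    remaining[frontier] <- FALSE
    while (length(frontier)) {
      nxt <- integer(0)
      for (ax in 1:3) {
        pos <- arrayInd(frontier, d)
        for (s in c(-1L, 1L)) {
          ok <- pos[, ax] + s >= 1 & pos[, ax] + s <= d[ax]
          cand <- frontier[ok] + s * strides[ax]
          cand <- cand[remaining[cand]]
          remaining[cand] <- FALSE
          nxt <- c(nxt, cand)
        }
      }
      frontier <- unique(nxt)
    }
  }
  comp
}
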