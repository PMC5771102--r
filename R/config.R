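`%||%` <- function(a, b) if (is.null(a)) b else a

# strip classes / drop closures so a config round-trips through JSON
config_to_list <- function(config) {
  list(
    params = unclass(config$params),
    probes = lapply(config$probes, unclass),
    h = config$h, V = config$V, flow = config$flow,
    dt_scale = config$dt_scale, end_time = config$end_time,
    metric_interval = config$metric_interval,
    checkpoint_times = config$checkpoint_times,
    props = local({
      p <- unclass(config$props)
      # back to the MJ-based units the constructor takes
      p$Ct <- p$Ct / 1e6; p$Cf <- p$Cf / 1e6; p$Cb <- p$Cb / 1e6
      p$Qf <- p$Qf / 1e6
      p
    }),
    bounds = unclass(config$bounds),
    advection_order = config$advection_order,
    sample_point = config$sample_point,
    max_overlap = config$max_overlap,
    fine_until = config$fine_until %||% 0,
    stop_when_wall_frozen = isTRUE(config$stop_when_wall_frozen))
}

#' Write a simulation configuration to JSON
#'
#' @param config a [cryo_config()] list
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config_to_list(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a simulation configuration from JSON
#'
#' Keys mirror the [cryo_config()], [bifurcation_params()], [probe_spec()],
#' [material_properties()] and [boundary_spec()] arguments; lengths in mm,
#' velocities in m/s, temperatures in degC.
#'
#' @param path JSON file path
#' @return a `cryo_config` list
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- do.call(bifurcation_params,
                    x$params[intersect(names(x$params),
                                       c("L1", "L2", "D0", "phi", "Dt", "Lt",
                                         "bend_radius", "phi_ref"))])
  probes <- lapply(seq_len(NROW(x$probes)), function(i) {
    p <- if (is.data.frame(x$probes)) as.list(x$probes[i, ]) else x$probes[[i]]
    p <- lapply(p, function(v) if (is.list(v)) v[[1]] else v)  # list-columns
    drop <- vapply(p, function(v) is.null(v) || all(is.na(unlist(v))),
                   logical(1))
    p <- p[!drop]
    do.call(probe_spec, p[intersect(names(p),
                                    c("Dp", "Lp", "Ld", "axis", "tip_center"))])
  })
  props <- do.call(material_properties,
                   x$props[c("Ct", "Cf", "Cb", "Qf", "kappa_f", "kappa_t",
                             "kappa_b", "omega_cb", "Qm", "Tu", "Tl", "Tcb")])
  bounds <- boundary_spec(T_inlet = x$bounds$T_inlet,
                          T_probe = x$bounds$T_probe)
  cryo_config(params = params, probes = probes, h = x$h, V = x$V,
              flow = x$flow, dt_scale = x$dt_scale, end_time = x$end_time,
              metric_interval = x$metric_interval %||% 1,
              checkpoint_times = as.numeric(unlist(x$checkpoint_times)),
              props = props, bounds = bounds,
              advection_order = x$advection_order %||% 1,
              sample_point = x$sample_point,
              max_overlap = x$max_overlap %||% 1.5,
              fine_until = x$fine_until %||% 0,
              stop_when_wall_frozen = isTRUE(x$stop_when_wall_frozen))
}
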