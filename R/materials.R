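#' Thermophysical material properties for tissue and blood
#'
#' Bundles the constants of the effective heat capacity (apparent heat
#' capacity) formulation of freezing tissue together with the blood and
#' perfusion parameters of the Pennes bioheat equation. Defaults are the
#' standard liver-tissue values used throughout the package.
#'
#' The tissue phase transition is smeared over the band `[Tl, Tu]`; the latent
#' heat `Qf` is released across that band via an inflated heat capacity (see
#' [effective_heat_capacity()]). Perfusion and metabolic heating act only in
#' unfrozen tissue (`T > Tu`).
#'
#' @param Ct unfrozen tissue volumetric heat capacity, MJ/m^3/K
#' @param Cf frozen tissue volumetric heat capacity, MJ/m^3/K
#' @param Cb blood volumetric heat capacity, MJ/m^3/K
#' @param Qf volumetric latent heat of the tissue phase change, MJ/m^3
#' @param kappa_f frozen tissue thermal conductivity, W/m/K
#' @param kappa_t unfrozen tissue thermal conductivity, W/m/K
#' @param kappa_b blood thermal conductivity, W/m/K
#' @param omega_cb blood perfusion rate, 1/s
#' @param Qm metabolic volumetric heat generation rate, W/m^3
#' @param Tu upper phase-transition temperature, degC
#' @param Tl lower phase-transition temperature, degC
#' @param Tcb temperature of perfusing capillary blood, degC
#' @return an object of class `material_properties` (a named list; capacities
#'   and latent heat are stored in SI J/m^3/K and J/m^3)
#' @export
#' @examples
#' props <- material_properties()
#' effective_heat_capacity(c(-20, -4.5, 37), props) / 1e6   # MJ/m^3/K
material_properties <- function(Ct = 3.6, Cf = 1.8, Cb = 3.6, Qf = 250,
                                kappa_f = 2, kappa_t = 0.5, kappa_b = 0.5,
                                omega_cb = 5e-4, Qm = 420,
                                Tu = -1, Tl = -8, Tcb = 37) {
  stopifnot(Tl < Tu, Ct > 0, Cf > 0, Cb > 0, Qf > 0,
            kappa_f > 0, kappa_t > 0, kappa_b > 0, omega_cb >= 0)
  props <- list(
    Ct = Ct * 1e6, Cf = Cf * 1e6, Cb = Cb * 1e6, Qf = Qf * 1e6,
    kappa_f = kappa_f, kappa_t = kappa_t, kappa_b = kappa_b,
    omega_cb = omega_cb, Qm = Qm, Tu = Tu, Tl = Tl, Tcb = Tcb
  )
  class(props) <- "material_properties"
  props
}

#' @export
print.material_properties <- function(x, ...) {
  cat("Material properties (tissue + blood):\n")
  cat(sprintf("  C_t = %.3g, C_f = %.3g, C_b = %.3g MJ/m^3K; Q_f = %.3g MJ/m^3\n",
              x$Ct / 1e6, x$Cf / 1e6, x$Cb / 1e6, x$Qf / 1e6))
  cat(sprintf("  kappa_t = %.3g, kappa_f = %.3g, kappa_b = %.3g W/mK\n",
              x$kappa_t, x$kappa_f, x$kappa_b))
  cat(sprintf("  perfusion %.3g /s at T_cb = %g degC, Q_m = %.3g W/m^3\n",
              x$omega_cb, x$Tcb, x$Qm))
  cat(sprintf("  phase transition band [%g, %g] degC\n", x$Tl, x$Tu))
  invisible(x)
}

#' Effective (apparent) volumetric heat capacity of freezing tissue
#'
#' Piecewise capacity: `Cf` below the band, `Ct` above it, and within
#' `[Tl, Tu]` the linear blend of the two plus the latent-heat contribution
#' `Qf / (Tu - Tl)`, so that integrating the capacity across the band releases
#' exactly the latent heat plus the sensible part.
#'
#' @param T temperature(s), degC
#' @param props a [material_properties()] object
#' @return effective capacity, J/m^3/K (vectorized over `T`)
#' @export
effective_heat_capacity <- function(T, props) {
  dT <- props$Tu - props$Tl
  mid <- props$Qf / dT + props$Cf + (props$Ct - props$Cf) * (T - props$Tl) / dT
  ifelse(T < props$Tl, props$Cf, ifelse(T > props$Tu, props$Ct, mid))
}

#' Effective thermal conductivity of freezing tissue
#'
#' `kappa_f` below the transition band, `kappa_t` above it, linear blend
#' inside.
#'
#' @inheritParams effective_heat_capacity
#' @return conductivity, W/m/K (vectorized over `T`)
#' @export
effective_conductivity <- function(T, props) {
  dT <- props$Tu - props$Tl
  mid <- props$kappa_f + (props$kappa_t - props$kappa_f) * (T - props$Tl) / dT
  ifelse(T < props$Tl, props$kappa_f, ifelse(T > props$Tu, props$kappa_t, mid))
}

#' Effective Pennes source terms (perfusion and metabolism)
#'
#' Both the capillary-perfusion heat `omega_cb * Cb * (Tcb - T)` and the
#' metabolic heat `Qm` are switched off in frozen and transitional tissue
#' (`T <= Tu`): blood supply and metabolism cease once freezing begins.
#'
#' @inheritParams effective_heat_capacity
#' @return a list with components `perfusion` and `metabolic`, both W/m^3
#' @export
effective_sources <- function(T, props) {
  on <- T > props$Tu
  list(perfusion = ifelse(on, props$omega_cb * props$Cb * (props$Tcb - T), 0),
       metabolic = ifelse(on, props$Qm, 0))
}

#' Volumetric enthalpy consistent with the effective heat capacity
#'
#' Integral of [effective_heat_capacity()] from `Tl`, in closed form. Used by
#' the solver's chord (secant) capacity linearization, which keeps latent heat
#' exactly conserved even when a cell crosses the whole transition band within
#' one time step, and by the energy-conservation checks.
#'
#' @inheritParams effective_heat_capacity
#' @return enthalpy relative to `Tl`, J/m^3
#' @export
tissue_enthalpy <- function(T, props) {
  dT <- props$Tu - props$Tl
  x <- T - props$Tl
  Hband <- (props$Qf / dT + props$Cf) * pmin(pmax(x, 0), dT) +
    (props$Ct - props$Cf) * pmin(pmax(x, 0), dT)^2 / (2 * dT)
  Htop <- Hband + ifelse(x > dT, props$Ct * (x - dT), 0)
  ifelse(x < 0, props$Cf * x, Htop)
}

#' Thermal boundary conditions of a cryosurgery run
#'
#' @param T_inlet blood temperature at the root-artery inlet, degC
#' @param T_probe cryoprobe active-tip temperature, degC (liquid nitrogen
#'   default)
#' @param shell `"adiabatic"` outer tissue boundary (the only supported mode)
#' @param outlet `"zero-gradient"` daughter-vessel thermal outlet (the only
#'   supported mode)
#' @return an object of class `boundary_spec`
#' @export
boundary_spec <- function(T_inlet = 37, T_probe = -196,
                          shell = "adiabatic", outlet = "zero-gradient") {
  shell <- match.arg(shell, "adiabatic")
  outlet <- match.arg(outlet, "zero-gradient")
  out <- list(T_inlet = T_inlet, T_probe = T_probe,
              shell = shell, outlet = outlet)
  class(out) <- "boundary_spec"
  out
}

#' Nonuniform time-step schedule
#'
#' Small steps resolve the violent early transient next to the probe tip
#' (37 to -196 degC within seconds); steps grow as the iceball growth slows.
#' Base schedule: 0.005 s for t < 1 s, 0.01 s for 1 <= t <= 5 s, 0.05 s for
#' 5 < t <= 100 s, 0.1 s beyond, multiplied by `scale` for coarse desk runs.
#'
#' @param t current simulated time, s
#' @param scale multiplier >= 1 applied uniformly to the base schedule
#' @return time step, s (vectorized over `t`)
#' @export
#' @examples
#' time_step(c(0.5, 3, 50, 200))
time_step <- function(t, scale = 1) {
  stopifnot(all(t >= 0), scale >= 1)
  base <- ifelse(t < 1, 0.005,
          ifelse(t <= 5, 0.01,
          ifelse(t <= 100, 0.05, 0.1)))
  base * scale
}
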