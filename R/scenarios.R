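#' Smooth load ramp
#'
#' `amplitude * (t/Ts - sin(2 pi t/Ts) / (2 pi))` for `t < Ts` and
#' `amplitude` thereafter: zero value and zero slope at `t = 0`, amplitude
#' with zero slope at `t = Ts` (C1-smooth arrival), so the quasi-static
#' assumption is never violated by a load jerk.
#'
#' @param t time in s (vectorized, non-negative).
#' @param program list with `amplitude` and `Ts` (ramp duration, s); see
#'   [cantilever_scenario()] for the stock programs.
#' @return Ramped value(s), same unit as `amplitude`.
#' @export
load_ramp <- function(t, program) {
  if (any(t < 0)) stop("negative time")
  s <- t / program$Ts
  ifelse(t >= program$Ts, program$amplitude,
         program$amplitude * (s - sin(2 * pi * s) / (2 * pi)))
}

.default_geometry <- function() list(Lx = 0.075, Ly = 0.025)

#' Cantilever plate bending scenario
#'
#' The 75 x 25 mm rectangular specimen clamped on its left short edge
#' (both displacement components zero) with a uniform tangential (shear)
#' traction on the right edge, ramped by [load_ramp()] to
#' `tau0 = 1.25e5 N/m` over `Ts = 60480 s`.  The orthotropy axes start
#' parallel to the specimen sides (`psi = 0`).
#'
#' @param nx,ny element counts (defaults 30 x 10).
#' @param degree,nq spline degree and quadrature order.
#' @param material a [moduli_set()] (default [default_moduli()]).
#' @param stimulus stimulus parameter list (default
#'   [default_stimulus_params()]).
#' @param evolution an [evolution_params()].
#' @param tau0 traction amplitude in N/m.
#' @param Ts ramp duration in s.
#' @return Object of class `bone_scenario`.
#' @export
cantilever_scenario <- function(nx = 30, ny = 10, degree = 2, nq = 3,
                                material = default_moduli(),
                                stimulus = default_stimulus_params(),
                                evolution = evolution_params(),
                                tau0 = 1.25e5, Ts = 60480) {
  scen <- list(
    name = "cantilever",
    geometry = .default_geometry(),
    mesh = list(nx = nx, ny = ny, degree = degree, nq = nq),
    material = material,
    stimulus = stimulus,
    evolution = evolution,
    load = list(mode = "traction", amplitude = tau0, Ts = Ts),
    bcs = list(dirichlet = list(left = "both"),
               traction_edge = "right", traction_dir = c(0, -1)),
    pins = NULL)
  scen$evolution$psi0 <- 0
  class(scen) <- "bone_scenario"
  scen
}

#' Three-point flexure scenario (half domain)
#'
#' Symmetric three-point bending of a 150 x 25 mm specimen modeled on its
#' right half (the 75 x 25 mm rectangle): symmetry condition `u1 = 0` on
#' the left (midline) edge, one fixed support pin tangent under the lower
#' face at half the 137.5 mm span (x = 68.75 mm), and a loading pin tangent
#' above the upper face at the midline, descending by [load_ramp()] to
#' `u0 = 2 mm`.  Both pins are frictionless penalty barriers.
#'
#' @inheritParams cantilever_scenario
#' @param u0 loading-pin displacement amplitude in m.
#' @param span full support span in m (support pin sits at `span / 2`).
#' @param pin_radius pin radius in m (unreported upstream; default 5 mm).
#' @param k_pen penalty stiffness in Pa/m (default 1e3 x the largest
#'   modulus per meter).
#' @return Object of class `bone_scenario`.
#' @export
three_point_scenario <- function(nx = 30, ny = 10, degree = 2, nq = 3,
                                 material = default_moduli(),
                                 stimulus = default_stimulus_params(),
                                 evolution = evolution_params(),
                                 u0 = 2e-3, Ts = 60480, span = 0.1375,
                                 pin_radius = 5e-3, k_pen = NULL) {
  geom <- .default_geometry()
  if (is.null(k_pen)) {
    pmax_mod <- max(material$K, material$mu, abs(material$beta1),
                    abs(material$beta2))
    k_pen <- 1e3 * pmax_mod
  }
  pins <- list(
    support = list(center = c(span / 2, -pin_radius), radius = pin_radius,
                   k_pen = k_pen, edge = "bottom"),
    loading = list(center = c(0, geom$Ly + pin_radius), radius = pin_radius,
                   k_pen = k_pen, edge = "top"))
  scen <- list(
    name = "three_point",
    geometry = geom,
    mesh = list(nx = nx, ny = ny, degree = degree, nq = nq),
    material = material,
    stimulus = stimulus,
    evolution = evolution,
    load = list(mode = "pin", amplitude = u0, Ts = Ts, pin = "loading"),
    bcs = list(dirichlet = list(left = "x"),
               traction_edge = NULL, traction_dir = NULL),
    pins = pins)
  scen$evolution$psi0 <- 0
  class(scen) <- "bone_scenario"
  scen
}

#' @export
print.bone_scenario <- function(x, ...) {
  cat(sprintf("<bone_scenario> %s: %.3g x %.3g m, %d x %d elements, ",
              x$name, x$geometry$Lx, x$geometry$Ly, x$mesh$nx, x$mesh$ny))
  cat(sprintf("load %s amplitude %.4g, Ts = %.4g s\n",
              x$load$mode, x$load$amplitude, x$load$Ts))
  invisible(x)
}

#' Serialize a scenario configuration to JSON
#'
#' Plain-text hierarchical configuration; [read_scenario()] restores it
#' bit-identically (all numbers written at full precision).
#'
#' @param scen a `bone_scenario`.
#' @param path output file path.
#' @export
write_scenario <- function(scen, path) {
  x <- unclass(scen)
  x$material <- unclass(x$material)
  x$stimulus <- lapply(x$stimulus, unclass)
  x$evolution <- unclass(x$evolution)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a scenario configuration from JSON
#'
#' @param path file written by [write_scenario()].
#' @return A `bone_scenario` (material admissibility re-checked on load).
#' @export
read_scenario <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$material <- do.call(moduli_set, c(as.list(x$material),
                                      list(check = TRUE)))
  x$stimulus <- lapply(x$stimulus, function(sp)
    do.call(stimulus_params, as.list(sp)))
  x$evolution$c_p <- as.list(x$evolution$c_p)
  x$evolution$tau_p <- as.list(x$evolution$tau_p)
  class(x$evolution) <- "evolution_params"
  if (!is.null(x$pins)) {
    x$pins <- lapply(x$pins, function(pin) {
      pin$center <- as.numeric(pin$center)
      pin
    })
  }
  if (!is.null(x$bcs$traction_dir))
    x$bcs$traction_dir <- as.numeric(x$bcs$traction_dir)
  class(x) <- "bone_scenario"
  x
}

#' Scenario defaults in printed-table units
#'
#' Collects every standard calibration value of a scenario in the units the
#' source tables print them (GPa for the first-gradient moduli, N for the
#' second-gradient and diffusion stiffnesses, Pa/Pa s for the evolution
#' coefficients), for string-level fidelity checks against the reference
#' fixture shipped in `inst/extdata/default_parameters.json`.
#'
#' @param scen a `bone_scenario`.
#' @return Nested named list of numbers in printed units.
#' @export
scenario_parameter_table <- function(scen) {
  m <- scen$material
  ev <- scen$evolution
  st <- scen$stimulus
  list(
    material_GPa = list(K = m$K / 1e9, mu = m$mu / 1e9,
                        alpha1 = m$alpha1 / 1e9, alpha2 = m$alpha2 / 1e9,
                        mu1 = m$mu1 / 1e9, mu2 = m$mu2 / 1e9,
                        beta1 = m$beta1 / 1e9, beta2 = m$beta2 / 1e9,
                        beta3 = m$beta3 / 1e9),
    second_gradient_N = list(Ks1 = m$Ks1, Ks2 = m$Ks2,
                             Kb1 = m$Kb1, Kb2 = m$Kb2),
    reorientation = list(c_gamma = ev$c_gamma * ev$scaled,
                         tau_gamma = ev$tau_gamma),
    stiffness_evolution = list(
      c_mu = ev$c_p$mu * ev$scaled, tau_mu = ev$tau_p$mu,
      S0_mu = st$mu$S0,
      c_beta1 = ev$c_p$beta1 * ev$scaled, tau_beta1 = ev$tau_p$beta1,
      S0_beta1 = st$beta1$S0,
      c_beta2 = ev$c_p$beta2 * ev$scaled, tau_beta2 = ev$tau_p$beta2,
      S0_beta2 = st$beta2$S0),
    stimulus_diffusion = list(
      d_mu = st$mu$d, kappa_mu = st$mu$kappa, R_mu = st$mu$R,
      d_beta1 = st$beta1$d, kappa_beta1 = st$beta1$kappa,
      R_beta1 = st$beta1$R,
      d_beta2 = st$beta2$d, kappa_beta2 = st$beta2$kappa,
      R_beta2 = st$beta2$R),
    loading = list(geometry_m = c(scen$geometry$Lx, scen$geometry$Ly),
                   amplitude = scen$load$amplitude, Ts = scen$load$Ts))
}
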