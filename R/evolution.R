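#' Remodeling evolution parameters
#'
#' Viscosities and gains of the orientation and stiffness gradient flows.
#' Defaults are the standard calibration: orientation viscosity
#' `c_gamma = 6.048e5 Pa s` with restoring coefficient
#' `tau_gamma = 1e-3 Pa` (time constant `c_gamma / tau_gamma = 6.048e8 s`,
#' i.e. the restoring term is negligible against the energy torque), and for
#' each evolving modulus viscosity `c_p = 6.048e12 Pa s` with gain
#' `tau_p = 1e4 Pa`.
#'
#' `chi` switches the direct energy-share feedback in the modulus equation
#' (`chi = 0`: purely stimulus-driven, the default and the homeostatic
#' reading; `chi = 1`: the literal variational reading that also injects
#' the energy share).  `floor_frac` bounds every evolving modulus from below
#' at that fraction of its initial value so ellipticity survives sustained
#' resorption.  `scaled` divides `c_gamma` and all `c_p` for desk-scale
#' demonstration runs.
#'
#' @param c_gamma,tau_gamma orientation viscosity (Pa s) and restoring
#'   coefficient (Pa).
#' @param c_p,tau_p named lists (`mu`, `beta1`, `beta2`) of viscosities
#'   (Pa s) and gains (Pa).
#' @param chi 0 or 1 (see above).
#' @param floor_frac modulus floor as a fraction of the initial value.
#' @param dt staggered time step in s.
#' @param horizon total simulated time in s.
#' @param scaled time-scaling divisor applied to `c_gamma` and `c_p`.
#' @return Object of class `evolution_params`.
#' @export
evolution_params <- function(c_gamma = 6.048e5, tau_gamma = 1e-3,
                             c_p = list(mu = 6.048e12, beta1 = 6.048e12,
                                        beta2 = 6.048e12),
                             tau_p = list(mu = 1e4, beta1 = 1e4,
                                          beta2 = 1e4),
                             chi = 0, floor_frac = 0.01,
                             dt = 60480 / 100, horizon = 10 * 60480,
                             scaled = 1) {
  stopifnot(c_gamma > 0, tau_gamma >= 0, chi %in% c(0, 1),
            floor_frac > 0, floor_frac < 1, dt > 0, horizon > 0,
            scaled >= 1)
  stopifnot(all(unlist(c_p) > 0), all(unlist(tau_p) >= 0))
  structure(list(c_gamma = c_gamma / scaled, tau_gamma = tau_gamma,
                 c_p = lapply(c_p, function(v) v / scaled), tau_p = tau_p,
                 chi = chi, floor_frac = floor_frac, dt = dt,
                 horizon = horizon, scaled = scaled),
            class = "evolution_params")
}

#' Orientation evolution rate
#'
#' Strong form of the orientation gradient flow: the misalignment obeys
#' `c_gamma dgamma/dt = dw_m/dpsi - tau_gamma gamma`; within a staggered
#' step at frozen macro-rotation, `dpsi/dt = -dgamma/dt`, i.e. a gradient
#' descent on the stored energy up to the (tiny) restoring term.
#'
#' @param torque configurational torque `dw_m/dpsi` (Pa), vectorized.
#' @param gamma misalignment angle (rad), vectorized.
#' @param params an [evolution_params()].
#' @return `dpsi/dt` in rad/s.
#' @export
orientation_rate <- function(torque, gamma, params) {
  (params$tau_gamma * gamma - torque) / params$c_gamma
}

#' Stiffness evolution rate
#'
#' `dp/dt = (tau_p (S - S0) - chi U) / c_p`: growth above the homeostatic
#' stimulus, resorption below it.  Clamping at the modulus floor is applied
#' by the integrator, not here.
#'
#' @param S current stimulus (Pa), vectorized.
#' @param sparams the [stimulus_params()] of this modulus (for `S0`).
#' @param params an [evolution_params()].
#' @param which one of `"mu"`, `"beta1"`, `"beta2"`.
#' @param U_share energy share (Pa), used only when `chi = 1`.
#' @return `dp/dt` in Pa/s.
#' @export
modulus_rate <- function(S, sparams, params, which = "mu", U_share = 0) {
  (params$tau_p[[which]] * (S - sparams$S0) - params$chi * U_share) /
    params$c_p[[which]]
}

# Sub-step the orientation gradient flow at frozen strain state.  Each
# quadrature point integrates its own scalar ODE over dt with an
# L-stable damped (backward-Euler / Newton) update
#   dpsi = dts * rate / (1 + dts * k),   k = d(-rate)/dpsi >= 0,
# sub-steps capped at |dpsi| <= cap rad.  Non-stiff points reduce to
# explicit Euler (dts * k << 1); stiff points relax to the torque-free
# state within their own remaining time budget.
.relax_orientation <- function(e, h, psi, p, mu, b1, b2, theta, params, dt,
                               cap = 0.1, max_sub = 200L) {
  n <- length(psi)
  rem <- rep(dt, n)
  de <- 1e-5
  for (it in seq_len(max_sub)) {
    act <- rem > 0
    if (!any(act)) break
    tq <- .torque_qp(e, h, psi, p, mu, b1, b2)
    gamma <- .wrap_half(theta - psi)
    rate <- orientation_rate(tq, gamma, params)
    dtq <- (.torque_qp(e, h, psi + de, p, mu, b1, b2) -
              .torque_qp(e, h, psi - de, p, mu, b1, b2)) / (2 * de)
    krate <- pmax((dtq + params$tau_gamma) / params$c_gamma, 0)
    step <- rem * rate / (1 + rem * krate)
    dts <- rem
    over <- abs(step) > cap
    if (any(over)) {
      dts[over] <- cap / (abs(rate[over]) - cap * krate[over])
      step[over] <- dts[over] * rate[over] /
        (1 + dts[over] * krate[over])
    }
    psi[act] <- psi[act] + step[act]
    rem[act] <- rem[act] - dts[act]
    if (max(abs(step[act])) < 1e-12) break
  }
  psi
}

# Initialize the mutable simulation state for a scenario (mesh, fields at
# quadrature points, stimulus systems, cached boundary data).
.init_state <- function(scen) {
  mesh <- build_mesh(scen$geometry$Lx, scen$geometry$Ly,
                     scen$mesh$nx, scen$mesh$ny,
                     degree = scen$mesh$degree, nq = scen$mesh$nq)
  p <- scen$material
  n <- mesh$nqp
  ev <- scen$evolution
  sys <- lapply(scen$stimulus, function(sp) stimulus_system(mesh, sp, ev$dt))
  fixed <- .dirichlet_dofs(mesh, scen$bcs$dirichlet)
  Funit <- if (!is.null(scen$bcs$traction_edge))
    assemble_load(mesh, stats::setNames(list(scen$bcs$traction_dir),
                                        scen$bcs$traction_edge))
  else numeric(mesh$ndof)
  list(mesh = mesh, p = p, time = 0, d = numeric(mesh$ndof),
       psi = rep(scen$evolution$psi0 %||% 0, n),
       mu = rep(p$mu, n), beta1 = rep(p$beta1, n), beta2 = rep(p$beta2, n),
       mu0 = p$mu, beta1_0 = p$beta1, beta2_0 = p$beta2,
       S = lapply(scen$stimulus, function(sp) numeric(mesh$ncp)),
       sys = sys, fixed = fixed, Funit = Funit,
       log = list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One staggered remodeling step
#'
#' Advances the coupled state by `dt`: (1) evaluate the load program at
#' `t + dt`; (2) solve the quasi-static equilibrium at frozen orientation
#' and moduli (with pin contact if the scenario has pins); (3) evaluate the
#' energy shares and take one implicit step of each stimulus field;
#' (4) relax the orientation gradient flow over `dt` at frozen strain
#' (internally sub-stepped so no sub-update exceeds 0.1 rad) and advance
#' the evolving moduli explicitly, clamped at their floor; (5) advance
#' time.  Deterministic given the configuration.
#'
#' @param state state list from a previous step or from `run_coupled`'s
#'   initializer.
#' @param scen a scenario configuration ([cantilever_scenario()] or
#'   [three_point_scenario()]).
#' @param dt time step in s; must equal the step the stimulus systems were
#'   factorized with.
#' @return The updated state.  Diagnostics of the step are in
#'   `state$last_step`.
#' @export
evolve_step <- function(state, scen, dt = scen$evolution$dt) {
  if (dt <= 0) stop("dt must be positive")
  if (abs(dt - state$sys[[1]]$dt) > 1e-9 * dt)
    stop("dt must match the stimulus system factorization")
  mesh <- state$mesh
  ev <- scen$evolution
  p <- state$p
  tnew <- state$time + dt
  amp <- load_ramp(tnew, scen$load)
  pins <- scen$pins
  if (!is.null(pins) && scen$load$mode == "pin") {
    pins[[scen$load$pin]]$offset <- c(0, -amp)
  }
  F <- if (scen$load$mode == "traction") amp * state$Funit
  else numeric(mesh$ndof)
  K <- assemble_stiffness(mesh, state$psi, p, state$mu, state$beta1,
                          state$beta2)
  sol <- solve_equilibrium(mesh, K, F, state$fixed, 0, pins = pins,
                           d0 = state$d)
  f <- .qp_fields(mesh, sol$d)
  sh <- .shares_qp(f$e, state$psi, state$mu, state$beta1, state$beta2)
  for (nm in names(state$S)) {
    state$S[[nm]] <- stimulus_step(state$S[[nm]], sh[[nm]],
                                   state$sys[[nm]], mesh)
  }
  psi_new <- .relax_orientation(f$e, f$h, state$psi, p, state$mu,
                                state$beta1, state$beta2, f$theta, ev, dt)
  floors <- ev$floor_frac * c(state$mu0, state$beta1_0, state$beta2_0)
  Sqp <- lapply(state$S, function(S) as.vector(mesh$N %*% S))
  state$mu <- pmax(floors[1], state$mu + dt *
    modulus_rate(Sqp$mu, scen$stimulus$mu, ev, "mu", sh$mu))
  state$beta1 <- pmax(floors[2], state$beta1 + dt *
    modulus_rate(Sqp$beta1, scen$stimulus$beta1, ev, "beta1", sh$beta1))
  state$beta2 <- pmax(floors[3], state$beta2 + dt *
    modulus_rate(Sqp$beta2, scen$stimulus$beta2, ev, "beta2", sh$beta2))
  state$psi <- psi_new
  state$d <- sol$d
  state$time <- tnew
  state$last_step <- list(load = amp, contact_iterations = sol$iterations,
                          converged = sol$converged,
                          energy = stored_energy(mesh, sol$d, psi_new, p,
                                                 state$mu, state$beta1,
                                                 state$beta2))
  state
}

#' Steady-state test between two snapshots
#'
#' True when the relative quadrature-weighted L2 change per unit time of
#' the orientation field and of every evolving modulus falls below `tol`
#' (default 1e-8 per second).  The caller is responsible for requiring
#' consecutive positives (the driver uses three).
#'
#' @param prev,cur two state lists sharing a mesh.
#' @param tol rate tolerance in 1/s.
#' @return List with logical `steady` and the named `rates` (1/s).
#' @export
steady_state_check <- function(prev, cur, tol = 1e-8) {
  dt <- cur$time - prev$time
  if (dt <= 0) stop("snapshots must be time ordered")
  w <- cur$mesh$w
  rel_rate <- function(a, b) {
    num <- sqrt(sum(w * (b - a)^2))
    den <- sqrt(sum(w * b^2)) + 1e-300
    num / den / dt
  }
  rates <- c(psi = rel_rate(prev$psi, cur$psi),
             mu = rel_rate(prev$mu, cur$mu),
             beta1 = rel_rate(prev$beta1, cur$beta1),
             beta2 = rel_rate(prev$beta2, cur$beta2))
  # psi rate normalized by pi/4 rather than the field norm (psi may be 0)
  num <- sqrt(sum(w * (cur$psi - prev$psi)^2))
  den <- max(sqrt(sum(w * cur$psi^2)), sqrt(sum(w)) * pi / 4)
  rates["psi"] <- num / den / dt
  list(steady = all(rates < tol), rates = rates)
}

#' Run the coupled remodeling simulation
#'
#' Drives [evolve_step()] from `t = 0` to the configured horizon, recording
#' snapshots on a fixed cadence and stopping early once
#' [steady_state_check()] passes on three consecutive snapshot pairs.
#'
#' @param scen a scenario configuration.
#' @param snapshot_every record every this-many steps (default 10).
#' @param steady_tol steady-state rate tolerance (1/s).
#' @param verbose print one line per snapshot.
#' @return Object of class `bone_trajectory`: list with `scenario`, `mesh`,
#'   `snapshots` (each holding `time`, `d`, `psi`, `mu`, `beta1`, `beta2`,
#'   `S`, `energy`), `steady_time` (`NA` if the horizon was exhausted
#'   first) and `final` (the final full state).
#' @export
run_coupled <- function(scen, snapshot_every = 10L, steady_tol = 1e-8,
                        verbose = FALSE) {
  state <- .init_state(scen)
  ev <- scen$evolution
  nstep <- ceiling(ev$horizon / ev$dt)
  snaps <- list()
  take <- function(st) list(time = st$time, d = st$d, psi = st$psi,
                            mu = st$mu, beta1 = st$beta1, beta2 = st$beta2,
                            S = st$S,
                            energy = st$last_step$energy %||% NA_real_)
  snaps[[1]] <- take(state)
  prev_state <- state
  consec <- 0L
  steady_time <- NA_real_
  for (k in seq_len(nstep)) {
    state <- evolve_step(state, scen, ev$dt)
    if (k %% snapshot_every == 0L || k == nstep) {
      chk <- steady_state_check(prev_state, state, tol = steady_tol)
      snaps[[length(snaps) + 1L]] <- take(state)
      if (verbose)
        message(sprintf("t = %.4g s  energy = %.6g  max rate = %.3g /s",
                        state$time, state$last_step$energy,
                        max(chk$rates)))
      consec <- if (chk$steady) consec + 1L else 0L
      prev_state <- state
      if (consec >= 3L) { steady_time <- state$time; break }
    }
  }
  structure(list(scenario = scen, mesh = state$mesh, snapshots = snaps,
                 steady_time = steady_time, final = state),
            class = "bone_trajectory")
}

#' @export
print.bone_trajectory <- function(x, ...) {
  ns <- length(x$snapshots)
  tf <- x$snapshots[[ns]]$time
  cat(sprintf("<bone_trajectory> %s: %d snapshots to t = %.4g s%s\n",
              x$scenario$name, ns, tf,
              if (is.na(x$steady_time)) " (horizon reached)"
              else sprintf(" (steady at %.4g s)", x$steady_time)))
  invisible(x)
}
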