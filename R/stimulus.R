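#' Parameters of one stimulus field
#'
#' Coefficients of the reaction--diffusion balance
#' `d dS/dt = div(kappa grad S) + r - R S` for the stimulus attached to one
#' evolving modulus, plus the homeostatic reference `S0` used by the
#' remodeling action.  The printed calibration values are adopted verbatim;
#' their unit bookkeeping follows the source tables (d in Pa s, kappa in N,
#' R in Pa, S0 in Pa).
#'
#' @param d damping coefficient (> 0), Pa s.
#' @param kappa diffusion coefficient (>= 0), N.
#' @param R absorption coefficient (>= 0), Pa.
#' @param S0 homeostatic reference stimulus, Pa.
#' @return Object of class `stimulus_params`.
#' @export
stimulus_params <- function(d, kappa, R, S0) {
  stopifnot(d > 0, kappa >= 0, R >= 0)
  structure(list(d = d, kappa = kappa, R = R, S0 = S0),
            class = "stimulus_params")
}

#' Default stimulus calibrations for the three evolving moduli
#'
#' @return Named list (`mu`, `beta1`, `beta2`) of [stimulus_params()].
#' @export
default_stimulus_params <- function() {
  list(mu = stimulus_params(d = 3.024e6, kappa = 1e-4, R = 0.35e2,
                            S0 = 3660),
       beta1 = stimulus_params(d = 6.048e6, kappa = 1e-4, R = 0.35e2,
                               S0 = 1484.8),
       beta2 = stimulus_params(d = 6.048e6, kappa = 1e-4, R = 0.35e2,
                               S0 = 734.29))
}

#' Discrete operators and factorization for one stimulus field
#'
#' Precomputes the mass and diffusion matrices on the (C0-sufficient)
#' spline basis and the Cholesky factor of the backward-Euler system
#' `(d/dt) M + kappa Kd + R M` with natural (no-flux) boundary conditions.
#'
#' @param mesh a [build_mesh()] object.
#' @param params a [stimulus_params()].
#' @param dt time step in s (> 0).
#' @return Object of class `stimulus_system`.
#' @export
stimulus_system <- function(mesh, params, dt) {
  if (dt <= 0) stop("dt must be positive")
  M <- Matrix::crossprod(mesh$N, mesh$w * mesh$N)
  Kd <- Matrix::crossprod(mesh$Dx, mesh$w * mesh$Dx) +
    Matrix::crossprod(mesh$Dy, mesh$w * mesh$Dy)
  A <- (params$d / dt) * M + params$kappa * Kd + params$R * M
  fact <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
  structure(list(params = params, dt = dt, M = M, Kd = Kd, fact = fact,
                 mesh_ncp = mesh$ncp),
            class = "stimulus_system")
}

#' One implicit step of the stimulus reaction--diffusion equation
#'
#' Backward-Euler update of the coefficient vector: solves
#' `((d/dt) M + kappa Kd + R M) S+ = (d/dt) M S + P' (w r)` where `r` is
#' the energy-share source sampled at quadrature points.  No-flux boundary
#' conditions are the natural ones of the weak form.
#'
#' @param S coefficient vector of the current stimulus field.
#' @param r_qp source values at the mesh quadrature points (Pa).
#' @param sys a [stimulus_system()] (fixes `dt` and the coefficients).
#' @param mesh the mesh the system was built on.
#' @return Updated coefficient vector.
#' @export
stimulus_step <- function(S, r_qp, sys, mesh) {
  if (length(S) != sys$mesh_ncp)
    stop("stimulus field size does not match the mesh")
  r_qp <- rep_len(r_qp, mesh$nqp)
  rhs <- (sys$params$d / sys$dt) * as.vector(sys$M %*% S) +
    as.vector(Matrix::crossprod(mesh$N, mesh$w * r_qp))
  as.vector(Matrix::solve(sys$fact, rhs))
}

#' Stimulus source fields from an equilibrium solution
#'
#' Evaluates the per-modulus energy shares pointwise at the quadrature
#' points of the current equilibrium displacement; the proportionality
#' constant between energy share and source is one.
#'
#' @param mesh a [build_mesh()] object.
#' @param d displacement coefficient vector of the converged equilibrium.
#' @param psi_qp orientation per quadrature point.
#' @param p a [moduli_set()].
#' @param mu_qp,beta1_qp,beta2_qp evolving moduli per quadrature point.
#' @return List of quadrature-point source vectors `mu`, `beta1`, `beta2`
#'   (Pa).
#' @export
source_field <- function(mesh, d, psi_qp, p, mu_qp = p$mu,
                         beta1_qp = p$beta1, beta2_qp = p$beta2) {
  f <- .qp_fields(mesh, d)
  sh <- .shares_qp(f$e, rep_len(psi_qp, mesh$nqp), mu_qp, beta1_qp, beta2_qp)
  list(mu = sh$mu, beta1 = sh$beta1, beta2 = sh$beta2)
}

# Integral of a stimulus coefficient field over the domain.
.stimulus_mass <- function(sys, S) sum(as.vector(sys$M %*% S))
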