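#' Assemble the first- plus second-gradient stiffness matrix
#'
#' Builds the sparse symmetric operator of the equilibrium weak form
#' `int (dw1/dE : dE(v) + dw2/dD2u : D2v) dA` at frozen orientation and
#' moduli.  Both fields may vary per quadrature point (heterogeneous,
#' evolving material).
#'
#' @param mesh a [build_mesh()] object.
#' @param psi_qp orientation angle per quadrature point (scalar recycles).
#' @param p a [moduli_set()] holding the non-evolving coefficients.
#' @param mu_qp,beta1_qp,beta2_qp evolving moduli per quadrature point
#'   (default: the homogeneous values in `p`).
#' @return Sparse symmetric stiffness matrix (`ndof` x `ndof`).
#' @export
assemble_stiffness <- function(mesh, psi_qp, p,
                               mu_qp = p$mu, beta1_qp = p$beta1,
                               beta2_qp = p$beta2) {
  n <- mesh$nqp
  psi_qp <- rep_len(psi_qp, n)
  Cv <- .voigt_C(psi_qp, p, mu_qp, beta1_qp, beta2_qp)
  xv <- as.vector(aperm(Cv, c(3, 2, 1)))           # per qp: row-major 3x3
  xv <- xv * rep(mesh$w, each = 9L)
  Cb1 <- Matrix::sparseMatrix(i = mesh$idx3$i, j = mesh$idx3$j, x = xv,
                              dims = c(3L * n, 3L * n))
  K <- Matrix::crossprod(mesh$B1g, Cb1 %*% mesh$B1g)
  any_sg <- (p$Ks1 > 0 || p$Ks2 > 0 || p$Kb1 > 0 || p$Kb2 > 0)
  if (any_sg) {
    if (is.null(mesh$B2g))
      stop("second-gradient stiffnesses need a mesh of degree >= 2")
    C2 <- .C2_qp(psi_qp, p)
    xv2 <- as.vector(aperm(C2, c(3, 2, 1))) * rep(mesh$w, each = 36L)
    Cb2 <- Matrix::sparseMatrix(i = mesh$idx6$i, j = mesh$idx6$j, x = xv2,
                                dims = c(6L * n, 6L * n))
    K <- K + Matrix::crossprod(mesh$B2g, Cb2 %*% mesh$B2g)
  }
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
}

#' Consistent load vector for edge tractions and double forces
#'
#' `int f . v dl` on the named edges, plus the optional double-force term
#' `int Fd . (grad v . n) dl` (zero by default; the stock scenarios apply
#' none).
#'
#' @param mesh a [build_mesh()] object.
#' @param tractions named list: `edge = c(fx, fy)` line densities in N/m.
#' @param double_forces named list: `edge = c(Fx, Fy)` in N (per unit
#'   thickness), conjugate to the outward normal derivative of the virtual
#'   displacement.
#' @return Load vector of length `ndof`.
#' @export
assemble_load <- function(mesh, tractions = list(), double_forces = list()) {
  F <- numeric(mesh$ndof)
  ncp <- mesh$ncp
  for (nm in names(tractions)) {
    ed <- mesh$edges[[nm]]
    f <- tractions[[nm]]
    v <- as.vector(Matrix::crossprod(ed$N, ed$w))
    F[seq_len(ncp)] <- F[seq_len(ncp)] + f[1] * v
    F[ncp + seq_len(ncp)] <- F[ncp + seq_len(ncp)] + f[2] * v
  }
  for (nm in names(double_forces)) {
    ed <- mesh$edges[[nm]]
    fd <- double_forces[[nm]]
    v <- as.vector(Matrix::crossprod(ed$Dn, ed$w))
    F[seq_len(ncp)] <- F[seq_len(ncp)] + fd[1] * v
    F[ncp + seq_len(ncp)] <- F[ncp + seq_len(ncp)] + fd[2] * v
  }
  F
}

# Dirichlet dof indices for fixing displacement components on edges.
# comps: "both", "x" (u1) or "y" (u2).
.dirichlet_dofs <- function(mesh, spec) {
  dofs <- integer(0)
  for (nm in names(spec)) {
    cps <- .edge_cps(mesh, nm)
    comp <- spec[[nm]]
    if (comp %in% c("x", "both")) dofs <- c(dofs, cps)
    if (comp %in% c("y", "both")) dofs <- c(dofs, mesh$ncp + cps)
  }
  sort(unique(dofs))
}

#' Solve the constrained linear equilibrium problem
#'
#' Eliminates the constrained coefficients and solves the remaining sparse
#' SPD system with a direct (Cholesky) factorization.
#'
#' @param K stiffness matrix from [assemble_stiffness()].
#' @param F load vector.
#' @param fixed integer dof indices held at prescribed values.
#' @param fixed_values values for the fixed dofs (default 0).
#' @return Full displacement coefficient vector (length `ndof`).
#' @export
solve_static <- function(K, F, fixed, fixed_values = 0) {
  ndof <- length(F)
  if (length(fixed) == 0L)
    stop("insufficient boundary conditions: no constrained dofs")
  free <- setdiff(seq_len(ndof), fixed)
  d <- numeric(ndof)
  d[fixed] <- rep_len(fixed_values, length(fixed))
  rhs <- F[free] - as.vector(K[free, fixed, drop = FALSE] %*% d[fixed])
  Kff <- Matrix::forceSymmetric(K[free, free])
  sol <- tryCatch(Matrix::solve(Matrix::Cholesky(Kff, LDL = FALSE), rhs),
                  error = function(e)
                    stop("singular system after constraints: ",
                         conditionMessage(e)))
  d[free] <- as.vector(sol)
  d
}

# Displacement components at the quadrature points of a named edge.
.edge_disp <- function(mesh, edge, d) {
  ncp <- mesh$ncp
  ed <- mesh$edges[[edge]]
  list(u1 = as.vector(ed$N %*% d[seq_len(ncp)]),
       u2 = as.vector(ed$N %*% d[ncp + seq_len(ncp)]),
       x = ed$x, y = ed$y, w = ed$w, N = ed$N)
}

#' Frictionless penalty contact with rigid circular pins
#'
#' For every boundary quadrature point of the pin's face that penetrates the
#' pin disk (penetration `g = radius - |x + u - center| > 0`, or sits exactly
#' tangent), a normal penalty force `k_pen * g` acts along the outward pin
#' normal; no tangential force is transmitted.  Returns the residual force
#' vector and the tangent (stiffness) contribution of the current
#' configuration.
#'
#' @param mesh a [build_mesh()] object.
#' @param pins list of pins; each a list with `center` (length-2, m),
#'   `radius` (m), `k_pen` (Pa/m), `edge` (`"bottom"` or `"top"`), and
#'   optionally `offset` (length-2 rigid displacement of the pin center).
#' @param d displacement coefficient vector.
#' @return List with `force` (length `ndof`), `tangent` (sparse `ndof` x
#'   `ndof`), `max_penetration` (m) and `active` (total active points).
#' @export
contact_penalty <- function(mesh, pins, d) {
  ncp <- mesh$ncp
  ndof <- mesh$ndof
  Fc <- numeric(ndof)
  Kc <- NULL
  gmax <- 0
  nact <- 0L
  for (pin in pins) {
    off <- if (is.null(pin$offset)) c(0, 0) else pin$offset
    ctr <- pin$center + off
    ue <- .edge_disp(mesh, pin$edge, d)
    px <- ue$x + ue$u1 - ctr[1]
    py <- ue$y + ue$u2 - ctr[2]
    dist <- sqrt(px^2 + py^2)
    g <- pin$radius - dist
    act <- which(g >= 0 & dist > 0)
    if (length(act) == 0L) next
    nact <- nact + length(act)
    gmax <- max(gmax, g[act])
    n1 <- px[act] / dist[act]
    n2 <- py[act] / dist[act]
    wk <- ue$w[act] * pin$k_pen
    Na <- ue$N[act, , drop = FALSE]
    f1 <- as.vector(Matrix::crossprod(Na, wk * g[act] * n1))
    f2 <- as.vector(Matrix::crossprod(Na, wk * g[act] * n2))
    Fc[seq_len(ncp)] <- Fc[seq_len(ncp)] + f1
    Fc[ncp + seq_len(ncp)] <- Fc[ncp + seq_len(ncp)] + f2
    K11 <- Matrix::crossprod(Na, (wk * n1 * n1) * Na)
    K12 <- Matrix::crossprod(Na, (wk * n1 * n2) * Na)
    K22 <- Matrix::crossprod(Na, (wk * n2 * n2) * Na)
    Kp <- rbind(cbind(K11, K12), cbind(Matrix::t(K12), K22))
    Kc <- if (is.null(Kc)) Kp else Kc + Kp
  }
  if (is.null(Kc))
    Kc <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                               x = numeric(0), dims = c(ndof, ndof))
  list(force = Fc, tangent = Kc, max_penetration = gmax, active = nact)
}

#' Quasi-static equilibrium with optional pin contact
#'
#' Direct solve without pins; with pins, Newton-type iteration on the
#' penalty contact residual until the active set stabilizes and the update
#' stalls.
#'
#' @param mesh a [build_mesh()] object.
#' @param K assembled stiffness.
#' @param F external load vector.
#' @param fixed,fixed_values Dirichlet data (see [solve_static()]).
#' @param pins optional pin list (see [contact_penalty()]).
#' @param tol relative update tolerance for the contact iteration.
#' @param maxit maximum contact iterations.
#' @param d0 starting displacement guess.
#' @return List with `d` (coefficients), `iterations`, `converged`,
#'   `contact` (last [contact_penalty()] report or `NULL`).
#' @export
solve_equilibrium <- function(mesh, K, F, fixed, fixed_values = 0,
                              pins = NULL, tol = 1e-8, maxit = 60L,
                              d0 = NULL) {
  if (is.null(pins) || length(pins) == 0L) {
    d <- solve_static(K, F, fixed, fixed_values)
    return(list(d = d, iterations = 1L, converged = TRUE, contact = NULL))
  }
  d <- if (is.null(d0)) numeric(mesh$ndof) else d0
  prev_active <- -1L
  # tiny grounding springs: regularize the rigid mode that exists until the
  # support contact engages; negligible against engaged penalty forces
  stab <- 1e-8 * mean(abs(Matrix::diag(K)))
  Kstab <- stab * Matrix::Diagonal(mesh$ndof)
  step_cap <- 0.1 * min(mesh$Lx, mesh$Ly)
  for (it in seq_len(maxit)) {
    ct <- contact_penalty(mesh, pins, d)
    # residual of K d = F + f_c(d); Newton with tangent K + Kc
    r <- F + ct$force - as.vector(K %*% d) - stab * d
    Kt <- K + ct$tangent + Kstab
    dd <- numeric(mesh$ndof)
    free <- setdiff(seq_len(mesh$ndof), fixed)
    # enforce increments compatible with fixed values
    dfix <- rep_len(fixed_values, length(fixed)) - d[fixed]
    dd[fixed] <- dfix
    rhs <- r[free] - as.vector(Kt[free, fixed, drop = FALSE] %*% dfix)
    Ktff <- Matrix::forceSymmetric(Kt[free, free])
    dd[free] <- as.vector(Matrix::solve(Matrix::Cholesky(Ktff, LDL = FALSE),
                                        rhs))
    capped <- max(abs(dd)) > step_cap
    if (capped) dd <- dd * (step_cap / max(abs(dd)))
    d <- d + dd
    scale <- max(1e-300, max(abs(d)))
    if (!capped && ct$active == prev_active &&
        max(abs(dd)) <= tol * scale) {
      return(list(d = d, iterations = it, converged = TRUE, contact = ct))
    }
    prev_active <- ct$active
  }
  warning("contact iteration did not converge in ", maxit, " iterations")
  list(d = d, iterations = maxit, converged = FALSE,
       contact = contact_penalty(mesh, pins, d))
}

# Quadrature-point fields derived from a displacement coefficient vector:
# Voigt strain e (3 x nqp), Hessian h (6 x nqp), displacement gradient and
# polar rotation angle theta.
.qp_fields <- function(mesh, d) {
  ncp <- mesh$ncp
  d1 <- d[seq_len(ncp)]
  d2 <- d[ncp + seq_len(ncp)]
  u1x <- as.vector(mesh$Dx %*% d1); u1y <- as.vector(mesh$Dy %*% d1)
  u2x <- as.vector(mesh$Dx %*% d2); u2y <- as.vector(mesh$Dy %*% d2)
  e <- rbind(u1x, u2y, u1y + u2x)
  h <- if (!is.null(mesh$B2g))
    rbind(as.vector(mesh$Dxx %*% d1), as.vector(mesh$Dyy %*% d1),
          as.vector(mesh$Dxy %*% d1), as.vector(mesh$Dxx %*% d2),
          as.vector(mesh$Dyy %*% d2), as.vector(mesh$Dxy %*% d2))
  else matrix(0, 6, mesh$nqp)
  theta <- atan2(u2x - u1y, 2 + u1x + u2y)
  list(e = e, h = h, theta = theta,
       grad = rbind(u1x, u1y, u2x, u2y))
}

#' Strain field of a displacement state at the quadrature points
#'
#' Voigt strains `(E11, E22, 2 E12)` sampled at the mesh quadrature points,
#' the common currency of the postprocessing diagnostics
#' (e.g. [angle_difference_field()]).
#'
#' @param mesh a [build_mesh()] object.
#' @param d displacement coefficient vector.
#' @return 3 x `nqp` matrix.
#' @export
strain_at_qp <- function(mesh, d) .qp_fields(mesh, d)$e

#' Stored strain energy of a displacement state
#'
#' Integrates `w1 + w2` over the domain with the mesh quadrature.
#'
#' @param mesh a [build_mesh()] object.
#' @param d displacement coefficient vector.
#' @param psi_qp orientation per quadrature point.
#' @param p a [moduli_set()].
#' @param mu_qp,beta1_qp,beta2_qp evolving moduli per quadrature point.
#' @return Total energy in J (per unit thickness: N).
#' @export
stored_energy <- function(mesh, d, psi_qp, p, mu_qp = p$mu,
                          beta1_qp = p$beta1, beta2_qp = p$beta2) {
  f <- .qp_fields(mesh, d)
  w1 <- .w1_qp(f$e, psi_qp, p, mu_qp, beta1_qp, beta2_qp)
  w2 <- .w2_qp(f$h, rep_len(psi_qp, mesh$nqp), p)
  sum(mesh$w * (w1 + w2))
}
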