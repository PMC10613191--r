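#' Orthotropy invariants of a 2D strain
#'
#' The strain invariants that carry the material symmetry: `J1 = tr E`,
#' `J2 = tr E^2`, `J4 = A1.E A1`, `J5 = A1.E^2 A1`, `J6 = A2.E A2`,
#' `J7 = A2.E^2 A2`.  Because `(A1, A2)` is an orthonormal basis of the
#' plane, `J4 + J6 = J1` and `J5 + J7 = J2` identically.
#'
#' @param E symmetric 2x2 strain matrix.
#' @param psi orientation angle of `A1` (radians).
#' @return Named list `J1, J2, J4, J5, J6, J7`.
#' @export
strain_invariants <- function(E, psi) {
  stopifnot(is.matrix(E), all(dim(E) == 2L))
  if (max(abs(E - t(E))) > 1e-12 * max(1, max(abs(E))))
    stop("strain must be symmetric")
  A <- structural_vectors(psi)
  E2 <- E %*% E
  list(J1 = sum(diag(E)), J2 = sum(diag(E2)),
       J4 = drop(A$A1 %*% E %*% A$A1), J5 = drop(A$A1 %*% E2 %*% A$A1),
       J6 = drop(A$A2 %*% E %*% A$A2), J7 = drop(A$A2 %*% E2 %*% A$A2))
}

#' First-gradient orthotropic energy density
#'
#' `w1 = K/2 J1^2 + mu (J2 - J1^2/2) + (alpha1 J4 + alpha2 J6) J1 +
#'  2 mu1 J5 + 2 mu2 J7 + beta1/2 J4^2 + beta2/2 J6^2 + beta3 J4 J6`
#' (Pa, per unit area on a unit-thickness slab).
#'
#' @param inv invariant list as returned by [strain_invariants()].
#' @param p a [moduli_set()].
#' @return Energy density in Pa.
#' @export
energy_w1 <- function(inv, p) {
  with(inv,
       0.5 * p$K * J1^2 + p$mu * (J2 - 0.5 * J1^2) +
         (p$alpha1 * J4 + p$alpha2 * J6) * J1 +
         2 * p$mu1 * J5 + 2 * p$mu2 * J7 +
         0.5 * p$beta1 * J4^2 + 0.5 * p$beta2 * J6^2 + p$beta3 * J4 * J6)
}

#' Second-gradient measures from a displacement Hessian
#'
#' Small-strain linearization of the fiber stretch-gradient and geodesic
#' bending measures: with `v_i = D2u : (A_i x A_i)` (the second directional
#' derivative of the displacement along fiber `i`), the tangential
#' stretch-gradient scalars are `s_i = A_i . v_i` and the bending scalars
#' `b_i = N_i . v_i`, with normals fixed as `N1 = A2`, `N2 = -A1`.  All four
#' vanish for affine displacements.
#'
#' @param hess_u numeric array `dim = c(2, 2, 2)`; `hess_u[k, p, q]` is
#'   `d^2 u_k / dx_p dx_q` (must be symmetric in `p, q`).
#' @param psi orientation angle (radians).
#' @return Named list `s1, s2, b1, b2` (1/m).
#' @export
second_gradient_measures <- function(hess_u, psi) {
  stopifnot(is.array(hess_u), all(dim(hess_u) == c(2L, 2L, 2L)))
  if (max(abs(hess_u[, 1, 2] - hess_u[, 2, 1])) >
      1e-12 * max(1, max(abs(hess_u))))
    stop("Hessian must be symmetric in its differentiation indices")
  h <- .hess_to_h(hess_u)
  m <- .sg_measures_qp(h, psi)
  list(s1 = m$s1[1], s2 = m$s2[1], b1 = m$b1[1], b2 = m$b2[1])
}

#' Second-gradient energy density
#'
#' `w2 = (Ks1 s1^2 + Ks2 s2^2)/2 + (Kb1 b1^2 + Kb2 b2^2)/2`, reported per
#' unit area under the unit-thickness convention.
#'
#' @param sg measure list from [second_gradient_measures()].
#' @param p a [moduli_set()].
#' @return Energy density in Pa (N/m^2 per unit thickness).
#' @export
energy_w2 <- function(sg, p) {
  0.5 * (p$Ks1 * sg$s1^2 + p$Ks2 * sg$s2^2 +
           p$Kb1 * sg$b1^2 + p$Kb2 * sg$b2^2)
}

#' Stress, hyperstress and orientation torque
#'
#' Closed-form derivatives of the stored energy `w1 + w2`:
#' the symmetric Cauchy-type stress `dw1/dE`, the third-order hyperstress
#' `dw2/dD2u`, and the configurational torque `d(w1+w2)/dpsi` at fixed
#' strain and Hessian (the driver of the orientation gradient flow).
#'
#' The hyperstress is returned as an array `P[k, p, q]` symmetric in
#' `(p, q)`, normalized so that `sum(P * dH) = dw2` for symmetric
#' increments `dH`.
#'
#' @param E symmetric 2x2 strain.
#' @param hess_u displacement Hessian array `c(2,2,2)` (symmetric in the
#'   last two indices); may be `NULL` for zero.
#' @param psi orientation angle (radians).
#' @param p a [moduli_set()].
#' @return List with `stress` (2x2, Pa), `hyperstress` (2x2x2, Pa m) and
#'   `torque` (Pa).
#' @export
stress_and_torque <- function(E, hess_u, psi, p) {
  e <- .E_to_voigt(E)
  pv <- .p_qp(p, 1L)
  Cm <- .voigt_C(psi, p, pv$mu, pv$beta1, pv$beta2)
  sv <- c(Cm[1, 1, 1] * e[1] + Cm[1, 1, 2] * e[2] + Cm[1, 1, 3] * e[3],
          Cm[1, 2, 1] * e[1] + Cm[1, 2, 2] * e[2] + Cm[1, 2, 3] * e[3],
          Cm[1, 3, 1] * e[1] + Cm[1, 3, 2] * e[2] + Cm[1, 3, 3] * e[3])
  stress <- matrix(c(sv[1], sv[3], sv[3], sv[2]), 2, 2)
  if (is.null(hess_u)) hess_u <- array(0, c(2, 2, 2))
  h <- .hess_to_h(hess_u)
  C2 <- .C2_qp(psi, p)[1, , ]
  m <- drop(C2 %*% h)
  P <- array(0, c(2, 2, 2))
  P[1, 1, 1] <- m[1]; P[1, 2, 2] <- m[2]; P[1, 1, 2] <- P[1, 2, 1] <- m[3] / 2
  P[2, 1, 1] <- m[4]; P[2, 2, 2] <- m[5]; P[2, 1, 2] <- P[2, 2, 1] <- m[6] / 2
  tq <- .torque_qp(matrix(e, 3, 1), matrix(h, 6, 1), psi, p,
                   pv$mu, pv$beta1, pv$beta2)
  list(stress = stress, hyperstress = P, torque = tq[1])
}

#' Per-modulus energy shares (stimulus sources)
#'
#' The portions of the first-gradient energy attached to the evolving
#' moduli, used verbatim (unit proportionality) as stimulus source terms:
#' `U_mu = mu (J2 - J1^2/2)`, `U_beta1 = beta1 J4^2 / 2`,
#' `U_beta2 = beta2 J6^2 / 2`.  Each is non-negative for admissible moduli.
#'
#' @param E symmetric 2x2 strain.
#' @param psi orientation angle (radians).
#' @param p a [moduli_set()].
#' @return Named list `mu`, `beta1`, `beta2` (Pa).
#' @export
energy_shares <- function(E, psi, p) {
  e <- .E_to_voigt(E)
  sh <- .shares_qp(matrix(e, 3, 1), psi, p$mu, p$beta1, p$beta2)
  list(mu = sh$mu[1], beta1 = sh$beta1[1], beta2 = sh$beta2[1])
}

## ---------------------------------------------------------------------------
## Vectorized quadrature-point kernels.
##
## Conventions: strains in Voigt form e = (E11, E22, 2*E12) stored as columns
## of a 3 x n matrix; displacement Hessians as columns of a 6 x n matrix
## h = (u1,11, u1,22, u1,12, u2,11, u2,22, u2,12); psi, mu, beta1, beta2 as
## length-n vectors (scalars recycle).

.E_to_voigt <- function(E) {
  stopifnot(is.matrix(E), all(dim(E) == 2L))
  if (max(abs(E - t(E))) > 1e-12 * max(1, max(abs(E))))
    stop("strain must be symmetric")
  c(E[1, 1], E[2, 2], 2 * E[1, 2])
}

.hess_to_h <- function(hess_u) {
  c(hess_u[1, 1, 1], hess_u[1, 2, 2], hess_u[1, 1, 2],
    hess_u[2, 1, 1], hess_u[2, 2, 2], hess_u[2, 1, 2])
}

# broadcast evolving moduli to length n
.p_qp <- function(p, n) {
  list(mu = rep_len(p$mu, n), beta1 = rep_len(p$beta1, n),
       beta2 = rep_len(p$beta2, n))
}

# Material-frame (psi = 0) Voigt stiffness entries; C13 = C23 = 0.
.C0_entries <- function(p, mu, beta1, beta2) {
  list(a = p$K + mu + 2 * p$alpha1 + 4 * p$mu1 + beta1,        # C11
       b = p$K - mu + p$alpha1 + p$alpha2 + p$beta3,           # C12
       d = p$K + mu + 2 * p$alpha2 + 4 * p$mu2 + beta2,        # C22
       f = mu + p$mu1 + p$mu2)                                 # C33
}

# Voigt strain rotation into the material frame, ebar = T e.
.T_entries <- function(psi) {
  c_ <- cos(psi); s_ <- sin(psi)
  c2 <- c_^2; s2 <- s_^2; cs <- c_ * s_
  list(T11 = c2, T12 = s2, T13 = cs,
       T21 = s2, T22 = c2, T23 = -cs,
       T31 = -2 * cs, T32 = 2 * cs, T33 = c2 - s2)
}

# Rotated Voigt stiffness C(psi) = T' C0 T as an (n, 3, 3) array.
.voigt_C <- function(psi, p, mu, beta1, beta2) {
  n <- max(length(psi), length(mu))
  psi <- rep_len(psi, n)
  C0 <- .C0_entries(p, rep_len(mu, n), rep_len(beta1, n), rep_len(beta2, n))
  Tm <- .T_entries(psi)
  Tc <- list(c(Tm$T11, Tm$T21, Tm$T31), c(Tm$T12, Tm$T22, Tm$T32),
             c(Tm$T13, Tm$T23, Tm$T33))
  dim1 <- function(v) matrix(v, n, 3)   # columns = rows of T
  Tc <- lapply(Tc, dim1)
  out <- array(0, c(n, 3, 3))
  for (i in 1:3) for (j in i:3) {
    v <- C0$a * Tc[[i]][, 1] * Tc[[j]][, 1] +
      C0$b * (Tc[[i]][, 1] * Tc[[j]][, 2] + Tc[[i]][, 2] * Tc[[j]][, 1]) +
      C0$d * Tc[[i]][, 2] * Tc[[j]][, 2] +
      C0$f * Tc[[i]][, 3] * Tc[[j]][, 3]
    out[, i, j] <- v
    out[, j, i] <- v
  }
  out
}

# First-gradient energy density at qps.
.w1_qp <- function(e, psi, p, mu, beta1, beta2) {
  n <- ncol(e)
  Tm <- .T_entries(rep_len(psi, n))
  e1 <- Tm$T11 * e[1, ] + Tm$T12 * e[2, ] + Tm$T13 * e[3, ]
  e2 <- Tm$T21 * e[1, ] + Tm$T22 * e[2, ] + Tm$T23 * e[3, ]
  e3 <- Tm$T31 * e[1, ] + Tm$T32 * e[2, ] + Tm$T33 * e[3, ]
  C0 <- .C0_entries(p, rep_len(mu, n), rep_len(beta1, n), rep_len(beta2, n))
  0.5 * (C0$a * e1^2 + 2 * C0$b * e1 * e2 + C0$d * e2^2 + C0$f * e3^2)
}

# Energy shares at qps (J4, J6 are the material-frame normal strains).
.shares_qp <- function(e, psi, mu, beta1, beta2) {
  n <- ncol(e)
  Tm <- .T_entries(rep_len(psi, n))
  J4 <- Tm$T11 * e[1, ] + Tm$T12 * e[2, ] + Tm$T13 * e[3, ]
  J6 <- Tm$T21 * e[1, ] + Tm$T22 * e[2, ] + Tm$T23 * e[3, ]
  dev <- 0.5 * ((e[1, ] - e[2, ])^2 + e[3, ]^2)   # J2 - J1^2/2
  list(mu = rep_len(mu, n) * dev,
       beta1 = 0.5 * rep_len(beta1, n) * J4^2,
       beta2 = 0.5 * rep_len(beta2, n) * J6^2,
       J4 = J4, J6 = J6)
}

# Stretch-gradient / bending measures at qps (h is 6 x n).
.sg_measures_qp <- function(h, psi) {
  if (is.null(dim(h))) h <- matrix(h, 6, 1)
  n <- ncol(h)
  psi <- rep_len(psi, n)
  c_ <- cos(psi); s_ <- sin(psi)
  q1 <- rbind(c_^2, s_^2, 2 * c_ * s_)
  q2 <- rbind(s_^2, c_^2, -2 * c_ * s_)
  P1 <- colSums(q1 * h[1:3, , drop = FALSE])
  P2 <- colSums(q1 * h[4:6, , drop = FALSE])
  R1 <- colSums(q2 * h[1:3, , drop = FALSE])
  R2 <- colSums(q2 * h[4:6, , drop = FALSE])
  list(s1 = c_ * P1 + s_ * P2,
       b1 = -s_ * P1 + c_ * P2,            # N1 = A2
       s2 = -s_ * R1 + c_ * R2,
       b2 = -(c_ * R1 + s_ * R2))          # N2 = -A1
}

.w2_qp <- function(h, psi, p) {
  m <- .sg_measures_qp(h, psi)
  0.5 * (p$Ks1 * m$s1^2 + p$Ks2 * m$s2^2 + p$Kb1 * m$b1^2 + p$Kb2 * m$b2^2)
}

# Second-gradient Voigt stiffness as an (n, 6, 6) array:
# C2 = sum_m K_m g_m g_m' with g the measure rows in h-coordinates.
.C2_qp <- function(psi, p) {
  n <- length(psi)
  c_ <- cos(psi); s_ <- sin(psi)
  q1 <- cbind(c_^2, s_^2, 2 * c_ * s_)
  q2 <- cbind(s_^2, c_^2, -2 * c_ * s_)
  G <- list(cbind(c_ * q1, s_ * q1),        # s1
            cbind(-s_ * q2, c_ * q2),       # s2
            cbind(-s_ * q1, c_ * q1),       # b1
            cbind(-c_ * q2, -s_ * q2))      # b2
  Km <- c(p$Ks1, p$Ks2, p$Kb1, p$Kb2)
  out <- array(0, c(n, 6, 6))
  for (i in 1:6) for (j in i:6) {
    v <- numeric(n)
    for (m in 1:4) v <- v + Km[m] * G[[m]][, i] * G[[m]][, j]
    out[, i, j] <- v
    out[, j, i] <- v
  }
  out
}

# Orientation torque d(w1 + w2)/dpsi at qps.
.torque_qp <- function(e, h, psi, p, mu, beta1, beta2) {
  n <- ncol(e)
  psi <- rep_len(psi, n)
  Tm <- .T_entries(psi)
  e1 <- Tm$T11 * e[1, ] + Tm$T12 * e[2, ] + Tm$T13 * e[3, ]
  e2 <- Tm$T21 * e[1, ] + Tm$T22 * e[2, ] + Tm$T23 * e[3, ]
  e3 <- Tm$T31 * e[1, ] + Tm$T32 * e[2, ] + Tm$T33 * e[3, ]
  C0 <- .C0_entries(p, rep_len(mu, n), rep_len(beta1, n), rep_len(beta2, n))
  sb1 <- C0$a * e1 + C0$b * e2
  sb2 <- C0$b * e1 + C0$d * e2
  sb3 <- C0$f * e3
  s2p <- sin(2 * psi); c2p <- cos(2 * psi)
  de1 <- -s2p * e[1, ] + s2p * e[2, ] + c2p * e[3, ]
  de2 <- -de1
  de3 <- -2 * c2p * e[1, ] + 2 * c2p * e[2, ] - 2 * s2p * e[3, ]
  tq1 <- sb1 * de1 + sb2 * de2 + sb3 * de3
  if (is.null(h)) return(tq1)
  if (is.null(dim(h))) h <- matrix(h, 6, 1)
  c_ <- cos(psi); s_ <- sin(psi)
  q1 <- rbind(c_^2, s_^2, 2 * c_ * s_)
  q2 <- rbind(s_^2, c_^2, -2 * c_ * s_)
  dq1 <- rbind(-s2p, s2p, 2 * c2p)
  dq2 <- rbind(s2p, -s2p, -2 * c2p)
  h1 <- h[1:3, , drop = FALSE]; h2 <- h[4:6, , drop = FALSE]
  P1 <- colSums(q1 * h1); P2 <- colSums(q1 * h2)
  R1 <- colSums(q2 * h1); R2 <- colSums(q2 * h2)
  dP1 <- colSums(dq1 * h1); dP2 <- colSums(dq1 * h2)
  dR1 <- colSums(dq2 * h1); dR2 <- colSums(dq2 * h2)
  s1 <- c_ * P1 + s_ * P2
  b1 <- -s_ * P1 + c_ * P2
  s2 <- -s_ * R1 + c_ * R2
  b2 <- -(c_ * R1 + s_ * R2)
  ds1 <- -s_ * P1 + c_ * P2 + c_ * dP1 + s_ * dP2
  db1 <- -c_ * P1 - s_ * P2 - s_ * dP1 + c_ * dP2
  ds2 <- -c_ * R1 - s_ * R2 - s_ * dR1 + c_ * dR2
  db2 <- -(-s_ * R1 + c_ * R2 + c_ * dR1 + s_ * dR2)
  tq1 + p$Ks1 * s1 * ds1 + p$Ks2 * s2 * ds2 +
    p$Kb1 * b1 * db1 + p$Kb2 * b2 * db2
}
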