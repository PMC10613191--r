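#' Material symmetry directions from the orientation angle
#'
#' The orthotropy axes are `A1 = (cos psi, sin psi)` and its
#' counter-clockwise normal `A2 = (-sin psi, cos psi)`.  The energy is
#' quadratic in both, so `psi` only matters modulo pi.
#'
#' @param psi orientation angle in radians (finite scalar).
#' @return List with unit vectors `A1`, `A2`.
#' @export
structural_vectors <- function(psi) {
  stopifnot(is.finite(psi))
  c_ <- cos(psi); s_ <- sin(psi)
  list(A1 = c(c_, s_), A2 = c(-s_, c_))
}

#' Linearized strain from a displacement gradient
#'
#' @param grad_u 2x2 matrix, the displacement gradient `d u_i / d x_j`.
#' @return Symmetric 2x2 strain `E = (grad_u + t(grad_u)) / 2`.
#' @export
small_strain <- function(grad_u) {
  stopifnot(is.matrix(grad_u), all(dim(grad_u) == 2L))
  (grad_u + t(grad_u)) / 2
}

#' Rotation angle of the 2D polar decomposition
#'
#' For `F = R(theta) U` with `U` symmetric positive definite, the rotation
#' angle is recovered exactly as `atan2(F21 - F12, F11 + F22)`.
#'
#' @param F 2x2 deformation gradient with positive determinant.
#' @return Angle `theta` in radians in `(-pi, pi]`.
#' @export
polar_angle <- function(F) {
  stopifnot(is.matrix(F), all(dim(F) == 2L))
  if (det(F) <= 0)
    stop("degenerate deformation: det(F) <= 0")
  atan2(F[2, 1] - F[1, 2], F[1, 1] + F[2, 2])
}

# wrap an angle to (-pi/2, pi/2]
.wrap_half <- function(a) {
  a <- (a + pi / 2) %% pi
  a <- ifelse(a == 0, pi, a)
  a - pi / 2
}

#' Misalignment between macro-rotation and material symmetry axes
#'
#' Two evaluations of the misalignment `gamma`: the exact definition
#' `gamma = theta - psi` with `theta` the polar-decomposition rotation of
#' `F`, and the small-strain approximation `gamma ~ arctan(G21 / G11)` with
#' `G = t(Q(psi)) F` (valid because the stretch tends to the identity).
#' Both are wrapped to `(-pi/2, pi/2]`; the discrepancy between them is
#' `O(|E|)`.
#'
#' @param F 2x2 deformation gradient, `det(F) > 0`.
#' @param psi current orientation angle (radians).
#' @return List with `exact`, `approx` (radians).
#' @export
misalignment <- function(F, psi) {
  th <- polar_angle(F)
  Q <- matrix(c(cos(psi), sin(psi), -sin(psi), cos(psi)), 2, 2)
  G <- t(Q) %*% F
  list(exact = .wrap_half(th - psi),
       approx = .wrap_half(atan2(G[2, 1], G[1, 1])))
}

#' Major principal strain direction
#'
#' Angle of the eigenvector belonging to the larger eigenvalue of a
#' symmetric 2x2 strain, `0.5 * atan2(2 E12, E11 - E22)`, wrapped to
#' `[0, pi)`.  When the eigenvalues coincide within `tol` (relative to the
#' spectral magnitude) every direction is principal and the result is
#' flagged indeterminate.
#'
#' @param E symmetric 2x2 strain.
#' @param tol relative eigenvalue-gap tolerance for the indeterminate flag.
#' @return List with `angle` (radians in `[0, pi)`) and logical
#'   `indeterminate`.
#' @export
principal_strain_angle <- function(E, tol = 1e-12) {
  stopifnot(is.matrix(E), all(dim(E) == 2L))
  if (max(abs(E - t(E))) > 1e-12 * max(1, max(abs(E))))
    stop("strain must be symmetric")
  gap <- sqrt((E[1, 1] - E[2, 2])^2 + 4 * E[1, 2]^2)
  scale <- max(abs(E[1, 1]), abs(E[2, 2]), abs(E[1, 2]), .Machine$double.xmin)
  ang <- 0.5 * atan2(2 * E[1, 2], E[1, 1] - E[2, 2])
  list(angle = ang %% pi, indeterminate = gap <= tol * scale)
}

# Vectorized principal angle + eigen gap over quadrature-point strain
# arrays e = (E11, E22, 2 E12) stored as columns of a 3-row matrix.
.principal_angle_qp <- function(e) {
  d <- e[1, ] - e[2, ]
  g <- e[3, ]                      # 2*E12
  ang <- 0.5 * atan2(g, d)
  lam_gap <- sqrt(d^2 + g^2)       # |lambda1 - lambda2|
  lam_max <- pmax(abs((e[1, ] + e[2, ] + lam_gap) / 2),
                  abs((e[1, ] + e[2, ] - lam_gap) / 2))
  list(angle = ang %% pi, gap = lam_gap, lam_max = lam_max)
}
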