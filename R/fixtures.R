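#' Synthetic strain states for testing
#'
#' Random symmetric 2D strains in Voigt form, drawn componentwise uniform
#' in `[-scale, scale]` (engineering shear included).  Used by the property
#' tests; uses the session RNG, so set a seed for reproducibility.
#'
#' @param n number of states.
#' @param scale strain magnitude (default 1e-3, the physiological regime).
#' @return 3 x n matrix with rows `(E11, E22, 2 E12)`.
#' @export
random_strain_states <- function(n, scale = 1e-3) {
  matrix(stats::runif(3 * n, -scale, scale), 3, n)
}

#' Synthetic displacement-Hessian states for testing
#'
#' Random second-derivative states `(u1,11, u1,22, u1,12, u2,11, u2,22,
#' u2,12)` uniform in `[-scale, scale]`.
#'
#' @param n number of states.
#' @param scale curvature magnitude in 1/m.
#' @return 6 x n matrix.
#' @export
random_hessian_states <- function(n, scale = 1) {
  matrix(stats::runif(6 * n, -scale, scale), 6, n)
}

#' Spline coefficients of an affine displacement field
#'
#' Exact (linear-precision) coefficients such that the interpolated field
#' equals `u(x) = a + B x` everywhere on the mesh: each component's
#' coefficients are the affine function evaluated at the Greville
#' abscissae.
#'
#' @param mesh a [build_mesh()] object.
#' @param a length-2 translation (m).
#' @param B 2x2 displacement-gradient matrix.
#' @return Coefficient vector of length `ndof`.
#' @export
affine_coeffs <- function(mesh, a, B) {
  gx <- rep(mesh$grev_x, times = mesh$ncpy)
  gy <- rep(mesh$grev_y, each = mesh$ncpx)
  c(a[1] + B[1, 1] * gx + B[1, 2] * gy,
    a[2] + B[2, 1] * gx + B[2, 2] * gy)
}

#' Spline coefficients of a quadratic displacement field
#'
#' Exact coefficients (degree-2 mesh) reproducing
#' `u_k(x, y) = c_k + g_k . (x, y) + 0.5 (x, y)' H_k (x, y)` via the
#' polar-form (blossom) of each component.  Lets unit tests prescribe
#' manufactured fields with constant Hessian.
#'
#' @param mesh a degree-2 [build_mesh()] object.
#' @param H1,H2 symmetric 2x2 Hessians of the two components (1/m).
#' @param g1,g2 gradients (length 2).
#' @param c1,c2 constants (m).
#' @return Coefficient vector of length `ndof`.
#' @export
quadratic_coeffs <- function(mesh, H1 = matrix(0, 2, 2),
                             H2 = matrix(0, 2, 2),
                             g1 = c(0, 0), g2 = c(0, 0),
                             c1 = 0, c2 = 0) {
  f1 <- function(x, y) c1 + g1[1] * x + g1[2] * y +
    0.5 * (H1[1, 1] * x^2 + 2 * H1[1, 2] * x * y + H1[2, 2] * y^2)
  f2 <- function(x, y) c2 + g2[1] * x + g2[2] * y +
    0.5 * (H2[1, 1] * x^2 + 2 * H2[1, 2] * x * y + H2[2, 2] * y^2)
  c(.poly_coeffs(mesh, f1), .poly_coeffs(mesh, f2))
}
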