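#' Orthotropic material parameter set
#'
#' Container for the thirteen material coefficients of the orthotropic
#' first- plus second-gradient strain energy: the isotropic pair (bulk-like
#' `K`, shear `mu`), the dilatation--fiber couplings `alpha1`, `alpha2`, the
#' fiber shear moduli `mu1`, `mu2`, the fiber stretch stiffnesses `beta1`,
#' `beta2`, their coupling `beta3` (all in Pa), and the four second-gradient
#' stiffnesses: tangential stretch-gradient `Ks1`, `Ks2` and bending `Kb1`,
#' `Kb2` (in N).
#'
#' At construction the 3x3 quadratic form of the first-gradient energy on
#' `(E11, E22, E12)` at zero orientation is checked for positive
#' definiteness (Sylvester / eigenvalue check); inadmissible sets are
#' rejected.  In a remodeling simulation only `mu`, `beta1` and `beta2`
#' evolve; the remaining coefficients stay at their construction values.
#'
#' @param K,mu,alpha1,alpha2,mu1,mu2,beta1,beta2,beta3 first-gradient
#'   moduli in Pa.
#' @param Ks1,Ks2,Kb1,Kb2 second-gradient stiffnesses in N (may be zero).
#' @param check logical; run the admissibility check (default `TRUE`).
#' @return An object of class `moduli_set` (named list of the 13 values).
#' @seealso [default_moduli()], [admissibility()]
#' @export
moduli_set <- function(K, mu, alpha1, alpha2, mu1, mu2,
                       beta1, beta2, beta3,
                       Ks1 = 0, Ks2 = 0, Kb1 = 0, Kb2 = 0,
                       check = TRUE) {
  p <- list(K = K, mu = mu, alpha1 = alpha1, alpha2 = alpha2,
            mu1 = mu1, mu2 = mu2, beta1 = beta1, beta2 = beta2,
            beta3 = beta3, Ks1 = Ks1, Ks2 = Ks2, Kb1 = Kb1, Kb2 = Kb2)
  stopifnot(all(vapply(p, function(v) is.numeric(v) && length(v) == 1L &&
                         is.finite(v), logical(1))))
  if (K <= 0 || mu <= 0)
    stop("K and mu must be strictly positive")
  if (any(c(Ks1, Ks2, Kb1, Kb2) < 0))
    stop("second-gradient stiffnesses must be non-negative")
  class(p) <- "moduli_set"
  if (check) {
    adm <- admissibility(p)
    if (!adm$positive_definite)
      stop("inadmissible moduli: first-gradient quadratic form is not ",
           "positive definite (eigenvalues ",
           paste(signif(adm$eigenvalues, 4), collapse = ", "), ")")
  }
  p
}

#' Default material calibration
#'
#' The package's standard trabecular-bone calibration: first-gradient moduli
#' (printed in GPa in the source tables, stored here in Pa) and equal
#' second-gradient stiffnesses of 1.5 N.
#'
#' @return A [moduli_set()].
#' @export
default_moduli <- function() {
  GPa <- 1e9
  moduli_set(K = 17.84 * GPa, mu = 7.32 * GPa,
             alpha1 = -2.87 * GPa, alpha2 = -2.25 * GPa,
             mu1 = -1.71 * GPa, mu2 = -1.09 * GPa,
             beta1 = 2.97 * GPa, beta2 = 1.47 * GPa, beta3 = 2.14 * GPa,
             Ks1 = 1.5, Ks2 = 1.5, Kb1 = 1.5, Kb2 = 1.5)
}

#' Admissibility of a first-gradient parameter set
#'
#' Builds the quadratic form `M` such that the first-gradient energy at zero
#' orientation is `w1 = x' M x` with `x = (E11, E22, E12)`, and checks it for
#' positive definiteness.  The three diagonal coefficients are
#' `M11 = K/2 + mu/2 + alpha1 + 2 mu1 + beta1/2`,
#' `M22 = K/2 + mu/2 + alpha2 + 2 mu2 + beta2/2` and
#' `M33 = 2 (mu + mu1 + mu2)`; for the default calibration these evaluate to
#' 7.775, 8.885 and 9.04 GPa.
#'
#' @param p a [moduli_set()].
#' @return List with `matrix` (3x3), `diagonal` (the three coefficients,
#'   Pa), `eigenvalues`, and logical `positive_definite`.
#' @export
admissibility <- function(p) {
  M11 <- p$K / 2 + p$mu / 2 + p$alpha1 + 2 * p$mu1 + p$beta1 / 2
  M22 <- p$K / 2 + p$mu / 2 + p$alpha2 + 2 * p$mu2 + p$beta2 / 2
  M33 <- 2 * (p$mu + p$mu1 + p$mu2)
  # cross term E11*E22 of w1: K - mu + alpha1 + alpha2 + beta3 (split in M)
  M12 <- (p$K - p$mu + p$alpha1 + p$alpha2 + p$beta3) / 2
  M <- matrix(c(M11, M12, 0,
                M12, M22, 0,
                0,   0,   M33), 3, 3, byrow = TRUE)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  list(matrix = M,
       diagonal = c(M11, M22, M33),
       eigenvalues = ev,
       positive_definite = all(ev > 0))
}

#' @export
print.moduli_set <- function(x, ...) {
  cat("<moduli_set>\n")
  cat(sprintf("  first gradient [GPa]: K=%.4g mu=%.4g a1=%.4g a2=%.4g ",
              x$K / 1e9, x$mu / 1e9, x$alpha1 / 1e9, x$alpha2 / 1e9))
  cat(sprintf("m1=%.4g m2=%.4g b1=%.4g b2=%.4g b3=%.4g\n",
              x$mu1 / 1e9, x$mu2 / 1e9, x$beta1 / 1e9, x$beta2 / 1e9,
              x$beta3 / 1e9))
  cat(sprintf("  second gradient [N]:  Ks=(%.3g, %.3g) Kb=(%.3g, %.3g)\n",
              x$Ks1, x$Ks2, x$Kb1, x$Kb2))
  d <- admissibility(x)$diagonal
  cat(sprintf("  quadratic-form diagonal [GPa]: %.4g %.4g %.4g\n",
              d[1] / 1e9, d[2] / 1e9, d[3] / 1e9))
  invisible(x)
}
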