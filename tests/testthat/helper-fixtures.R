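# Shared fixtures: built in code, nothing on disk.

tab_moduli <- default_moduli()

# small meshes reused across files (construction is cheap but not free)
mesh_small <- build_mesh(0.075, 0.025, 6, 4)
mesh_unit <- build_mesh(1, 1, 1, 1)

# 2x2 rotation matrix
rot2 <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)

# Voigt vector -> symmetric strain matrix
voigt_to_E <- function(e) matrix(c(e[1], e[3] / 2, e[3] / 2, e[2]), 2, 2)

# h vector (6) -> Hessian array c(2,2,2)
h_to_hess <- function(h) {
  H <- array(0, c(2, 2, 2))
  H[1, 1, 1] <- h[1]; H[1, 2, 2] <- h[2]; H[1, 1, 2] <- H[1, 2, 1] <- h[3]
  H[2, 1, 1] <- h[4]; H[2, 2, 2] <- h[5]; H[2, 1, 2] <- H[2, 2, 1] <- h[6]
  H
}

# rotate a Hessian array by R (all three slots)
rotate_hess <- function(H, R) {
  Hn <- array(0, c(2, 2, 2))
  for (k in 1:2) for (p in 1:2) for (q in 1:2) {
    s <- 0
    for (a in 1:2) for (b in 1:2) for (c in 1:2)
      s <- s + R[k, a] * R[p, b] * R[q, c] * H[a, b, c]
    Hn[k, p, q] <- s
  }
  Hn
}

total_energy <- function(E, H, psi, p) {
  energy_w1(strain_invariants(E, psi), p) +
    energy_w2(second_gradient_measures(H, psi), p)
}

# brute-force minimizer of w1 over psi on a grid
grid_min_psi <- function(E, p, npts = 100001) {
  grid <- seq(0, pi, length.out = npts)
  e <- matrix(c(E[1, 1], E[2, 2], 2 * E[1, 2]), 3, npts)
  w <- osteoadapt:::.w1_qp(e, grid, p, p$mu, p$beta1, p$beta2)
  grid[which.min(w)]
}
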