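test_that("structural vectors rotate correctly; energy is pi-periodic", {
  a <- structural_vectors(0)
  expect_equal(a$A1, c(1, 0)); expect_equal(a$A2, c(0, 1))
  b <- structural_vectors(pi / 2)
  expect_equal(b$A1, c(0, 1)); expect_equal(b$A2, c(-1, 0))
  expect_equal(structural_vectors(pi)$A1, c(-1, 0))
  E <- voigt_to_E(c(1e-3, -4e-4, 6e-4))
  w0 <- energy_w1(strain_invariants(E, 0.3), tab_moduli)
  wp <- energy_w1(strain_invariants(E, 0.3 + pi), tab_moduli)
  expect_equal(w0, wp, tolerance = 1e-12)
  # generically NOT pi/2 periodic (beta1 != beta2, mu1 != mu2)
  wq <- energy_w1(strain_invariants(E, 0.3 + pi / 2), tab_moduli)
  expect_gt(abs(w0 - wq) / w0, 1e-4)
})

test_that("invariants satisfy the orthonormal-basis trace identities", {
  inv0 <- strain_invariants(matrix(0, 2, 2), 0.7)
  expect_true(all(unlist(inv0) == 0))
  inv <- strain_invariants(diag(c(1e-3, 0)), 0)
  expect_equal(inv$J1, 1e-3); expect_equal(inv$J2, 1e-6)
  expect_equal(inv$J4, 1e-3); expect_equal(inv$J5, 1e-6)
  expect_equal(inv$J6, 0); expect_equal(inv$J7, 0)
  set.seed(5)
  for (k in 1:200) {
    E <- voigt_to_E(random_strain_states(1, scale = 1e-2))
    psi <- runif(1, -4, 4)
    iv <- strain_invariants(E, psi)
    expect_equal(iv$J4 + iv$J6, iv$J1, tolerance = 1e-13)
    expect_equal(iv$J5 + iv$J7, iv$J2, tolerance = 1e-13)
    expect_gte(iv$J2, iv$J1^2 / 2 - 1e-18)
  }
  expect_error(strain_invariants(matrix(c(1, 2, 3, 4), 2, 2), 0),
               "symmetric")
})

test_that("energy values match hand-derived substitutions", {
  # uniaxial 1000 microstrain along A1, default calibration
  w <- energy_w1(strain_invariants(diag(c(1e-3, 0)), 0), tab_moduli)
  expect_equal(w, 7775, tolerance = 1e-10)
  # isotropic limit: pure dilatation is purely hydrostatic
  piso <- moduli_set(K = 2e9, mu = 1e9, 0, 0, 0, 0, 0, 0, 0)
  eps <- 1e-3
  wiso <- energy_w1(strain_invariants(diag(c(eps, eps)), 0.3), piso)
  expect_equal(wiso, 0.5 * 2e9 * (2 * eps)^2, tolerance = 1e-12)
  # second gradient: unit stretch gradient with the stock 1.5 N stiffness
  sg <- list(s1 = 1, s2 = 0, b1 = 0, b2 = 0)
  expect_equal(energy_w2(sg, tab_moduli), 0.75)
  # switch-off limit
  p0 <- moduli_set(tab_moduli$K, tab_moduli$mu, tab_moduli$alpha1,
                   tab_moduli$alpha2, tab_moduli$mu1, tab_moduli$mu2,
                   tab_moduli$beta1, tab_moduli$beta2, tab_moduli$beta3)
  H <- h_to_hess(c(1, 2, 3, 4, 5, 6))
  expect_equal(energy_w2(second_gradient_measures(H, 0.4), p0), 0)
})

test_that("second-gradient measures match direct differentiation", {
  # u1 = x^2/2 -> s1 = 1, rest 0 at psi = 0
  H <- h_to_hess(c(1, 0, 0, 0, 0, 0))
  m <- second_gradient_measures(H, 0)
  expect_equal(unlist(m), c(s1 = 1, s2 = 0, b1 = 0, b2 = 0))
  # u2 = x^2/2 -> pure bending of the A1 fiber
  Hb <- h_to_hess(c(0, 0, 0, 1, 0, 0))
  mb <- second_gradient_measures(Hb, 0)
  expect_equal(unlist(mb), c(s1 = 0, s2 = 0, b1 = 1, b2 = 0))
  expect_error(second_gradient_measures(array(c(0, 0, 0, 0, 1, 0, 0, 0),
                                              c(2, 2, 2)), 0),
               "symmetric")
})

test_that("stress, hyperstress and torque agree with finite differences", {
  set.seed(9)
  rel_err <- function(a, b) abs(a - b) / pmax(abs(b), 1e-9 * max(abs(b), 1))
  for (k in 1:25) {
    E <- voigt_to_E(random_strain_states(1))
    H <- h_to_hess(random_hessian_states(1))
    psi <- runif(1, 0, pi)
    st <- stress_and_torque(E, H, psi, tab_moduli)
    dpsi <- 1e-6
    fd_t <- (total_energy(E, H, psi + dpsi, tab_moduli) -
               total_energy(E, H, psi - dpsi, tab_moduli)) / (2 * dpsi)
    if (abs(fd_t) > 1e-3)
      expect_lt(rel_err(st$torque, fd_t), 1e-6)
    dE <- 1e-9
    for (i in 1:2) for (j in i:2) {
      P <- matrix(0, 2, 2); P[i, j] <- P[j, i] <- dE
      fd_s <- (total_energy(E + P, H, psi, tab_moduli) -
                 total_energy(E - P, H, psi, tab_moduli)) / (2 * dE) /
        ifelse(i == j, 1, 2)
      expect_lt(rel_err(st$stress[i, j], fd_s), 1e-5)
    }
    # w1 does not depend on the Hessian, so differentiate w2 alone
    # (exact for the quadratic energy up to roundoff)
    w2_of <- function(Harr) energy_w2(second_gradient_measures(Harr, psi),
                                      tab_moduli)
    dH <- 1e-5
    for (kk in 1:2) for (i in 1:2) for (j in i:2) {
      P <- array(0, c(2, 2, 2)); P[kk, i, j] <- P[kk, j, i] <- dH
      fd_p <- (w2_of(H + P) - w2_of(H - P)) / (2 * dH) /
        ifelse(i == j, 1, 2)
      expect_lt(abs(st$hyperstress[kk, i, j] - fd_p),
                1e-7 * (1 + abs(fd_p)))
    }
  }
})

test_that("torque vanishes where symmetry demands it", {
  piso <- moduli_set(K = 3e9, mu = 1e9, 0, 0, 0, 0, 0, 0, 0)
  set.seed(13)
  for (k in 1:20) {
    E <- voigt_to_E(random_strain_states(1))
    psi <- runif(1, 0, pi)
    expect_equal(stress_and_torque(E, NULL, psi, piso)$torque, 0,
                 tolerance = 1e-8)
  }
  # pure dilatation: psi-independent for ANY moduli
  for (psi in c(0.2, 1.1, 2.9)) {
    tq <- stress_and_torque(diag(c(1e-3, 1e-3)), NULL, psi,
                            tab_moduli)$torque
    expect_equal(tq / 7775, 0, tolerance = 1e-12)
  }
  # eigen-aligned states are stationary points of w1(psi)
  for (psi in c(0, pi / 2)) {
    tq <- stress_and_torque(diag(c(1e-3, 0)), NULL, psi,
                            tab_moduli)$torque
    expect_equal(tq / 7775, 0, tolerance = 1e-12)
  }
})

test_that("the invariant representation is frame-objective", {
  set.seed(17)
  for (k in 1:20) {
    E <- voigt_to_E(random_strain_states(1))
    H <- h_to_hess(random_hessian_states(1))
    psi <- runif(1, 0, pi)
    phi <- runif(1, 0, 2 * pi)
    R <- rot2(phi)
    w <- total_energy(E, H, psi, tab_moduli)
    wr <- total_energy(R %*% E %*% t(R), rotate_hess(H, R), psi + phi,
                       tab_moduli)
    expect_equal(wr, w, tolerance = 1e-9 * max(abs(w), 1))
  }
})

test_that("energy shares reproduce their closed forms and sum into w1", {
  sh0 <- energy_shares(matrix(0, 2, 2), 0.5, tab_moduli)
  expect_true(all(unlist(sh0) == 0))
  shd <- energy_shares(diag(c(2e-3, 2e-3)), 0.8, tab_moduli)
  expect_equal(shd$mu, 0, tolerance = 1e-18)
  sh <- energy_shares(diag(c(1e-3, 0)), 0, tab_moduli)
  expect_equal(sh$beta1, 0.5 * 2.97e9 * 1e-6, tolerance = 1e-12)
  expect_equal(sh$beta2, 0)
  expect_equal(sh$mu, 3660, tolerance = 1e-10)
  # all Eq-style terms (shares + non-evolving pieces) recompose w1
  set.seed(23)
  for (k in 1:20) {
    E <- voigt_to_E(random_strain_states(1))
    psi <- runif(1, 0, pi)
    iv <- strain_invariants(E, psi)
    sh <- energy_shares(E, psi, tab_moduli)
    rest <- with(iv, 0.5 * tab_moduli$K * J1^2 +
                   (tab_moduli$alpha1 * J4 + tab_moduli$alpha2 * J6) * J1 +
                   2 * tab_moduli$mu1 * J5 + 2 * tab_moduli$mu2 * J7 +
                   tab_moduli$beta3 * J4 * J6)
    expect_equal(sh$mu + sh$beta1 + sh$beta2 + rest,
                 energy_w1(iv, tab_moduli), tolerance = 1e-10)
    expect_true(all(unlist(sh[c("mu", "beta1", "beta2")]) >= 0))
  }
})
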