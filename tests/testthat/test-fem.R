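test_that("assembled stiffness is symmetric and zero load gives zero
          solution", {
  m <- mesh_small
  K <- assemble_stiffness(m, 0.4, tab_moduli)
  expect_lt(max(abs(K - Matrix::t(K))), 1e-6 * max(abs(K)))
  fixed <- osteoadapt:::.dirichlet_dofs(m, list(left = "both"))
  d <- solve_static(K, numeric(m$ndof), fixed)
  expect_equal(max(abs(d)), 0)
  expect_error(solve_static(K, numeric(m$ndof), integer(0)),
               "insufficient")
})

test_that("patch test: affine fields solve exactly, with and without the
          second gradient", {
  m <- mesh_small
  B <- matrix(c(1e-3, 4e-4, 4e-4, -6e-4), 2, 2)
  d_exact <- affine_coeffs(m, c(0, 0), B)
  bdofs <- osteoadapt:::.dirichlet_dofs(
    m, list(left = "both", right = "both", top = "both", bottom = "both"))
  for (psi in c(0, 0.37)) {
    for (sg in c(FALSE, TRUE)) {
      p <- if (sg) tab_moduli else
        moduli_set(tab_moduli$K, tab_moduli$mu, tab_moduli$alpha1,
                   tab_moduli$alpha2, tab_moduli$mu1, tab_moduli$mu2,
                   tab_moduli$beta1, tab_moduli$beta2, tab_moduli$beta3)
      K <- assemble_stiffness(m, psi, p)
      d <- solve_static(K, numeric(m$ndof), bdofs, d_exact[bdofs])
      expect_lt(max(abs(d - d_exact)), 1e-12 * max(abs(d_exact)))
    }
  }
})

test_that("uniform uniaxial traction on a free-sliding block gives uniform
          strain", {
  m <- mesh_small
  p0 <- moduli_set(3e9, 2e9, 0, 0, 0, 0, 0, 0, 0)   # isotropic, no K2
  sigma <- 1e6
  K <- assemble_stiffness(m, 0, p0)
  F <- assemble_load(m, list(right = c(sigma, 0)))
  fixed <- osteoadapt:::.dirichlet_dofs(m, list(left = "x", bottom = "y"))
  d <- solve_static(K, F, fixed)
  f <- osteoadapt:::.qp_fields(m, d)
  # closed-form uniform solution from the plane Voigt matrix
  C <- osteoadapt:::.voigt_C(0, p0, p0$mu, p0$beta1, p0$beta2)[1, , ]
  e_exact <- solve(C, c(sigma, 0, 0))
  expect_equal(max(abs(f$e[1, ] - e_exact[1])) / abs(e_exact[1]), 0,
               tolerance = 1e-9)
  expect_lt(max(abs(f$e[2, ] - e_exact[2])), 1e-9 * abs(e_exact[1]))
  expect_lt(max(abs(f$e[3, ])), 1e-9 * abs(e_exact[1]))
  # Clapeyron: stored energy equals half the external work
  en <- stored_energy(m, d, 0, p0)
  expect_equal(en, 0.5 * sum(F * d), tolerance = 1e-10)
})

test_that("double-force loading excites the second-gradient response", {
  m <- mesh_small
  K <- assemble_stiffness(m, 0, tab_moduli)
  F <- assemble_load(m, double_forces = list(right = c(1e2, 0)))
  expect_gt(max(abs(F)), 0)
  fixed <- osteoadapt:::.dirichlet_dofs(m, list(left = "both"))
  d <- solve_static(K, F, fixed)
  expect_gt(max(abs(d)), 0)
})

test_that("pin contact: inactive when clear, monotone and penalty-scaled
          when engaged", {
  # edge quadrature must resolve the contact patch width ~ 2 sqrt(2 r g)
  m <- build_mesh(0.075, 0.025, 30, 4)
  pin <- list(center = c(0.0375, -5e-3), radius = 5e-3,
              k_pen = 1e12, edge = "bottom")
  # no penetration: rigid upward motion moves the face away from the pin
  d_up <- affine_coeffs(m, c(0, 1e-3), matrix(0, 2, 2))
  ct <- contact_penalty(m, list(pin), d_up)
  expect_equal(ct$active, 0L)
  expect_equal(max(abs(ct$force)), 0)
  # monotone restoring force under increasing rigid penetration
  fprev <- 0
  for (delta in c(1e-4, 4e-4, 1.6e-3)) {
    dd <- affine_coeffs(m, c(0, -delta), matrix(0, 2, 2))
    ct <- contact_penalty(m, list(pin), dd)
    ftot <- sum(ct$force[m$ncp + seq_len(m$ncp)])
    expect_gt(ftot, fprev)
    fprev <- ftot
  }
  # doubling k_pen roughly halves the converged penetration
  p0 <- moduli_set(3e9, 2e9, 0, 0, 0, 0, 0, 0, 0)
  K <- assemble_stiffness(m, 0, p0)
  F <- assemble_load(m, list(top = c(0, -1e7)))
  fixed <- osteoadapt:::.dirichlet_dofs(m, list(left = "both"))
  pen <- c()
  for (kp in c(1e12, 2e12)) {
    pin$k_pen <- kp
    sol <- solve_equilibrium(m, K, F, fixed, pins = list(pin))
    expect_true(sol$converged)
    pen <- c(pen, sol$contact$max_penetration)
  }
  expect_equal(pen[1] / pen[2], 2, tolerance = 0.2)
})

test_that("cantilever tip deflection approaches the Timoshenko estimate", {
  m <- build_mesh(0.075, 0.025, 30, 10)
  Kb <- 10e9; mu <- 5e9
  piso <- moduli_set(Kb, mu, 0, 0, 0, 0, 0, 0, 0)
  tau0 <- 1.25e5
  K <- assemble_stiffness(m, 0, piso)
  F <- assemble_load(m, list(right = c(0, -tau0)))
  fixed <- osteoadapt:::.dirichlet_dofs(m, list(left = "both"))
  d <- solve_static(K, F, fixed)
  Ev <- osteoadapt:::.eval_matrix(m, 0.075, 0.0125)
  tip <- as.numeric(Ev %*% d[m$ncp + seq_len(m$ncp)])
  P <- tau0 * 0.025; L <- 0.075; h <- 0.025; I <- h^3 / 12
  Emod <- 4 * Kb * mu / (Kb + mu); G <- mu
  delta <- P * L^3 / (3 * Emod * I) + P * L / (5 / 6 * G * h)
  expect_equal(-tip, delta, tolerance = 0.05)
})
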