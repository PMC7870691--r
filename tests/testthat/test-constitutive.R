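test_that("elastin energy matches the closed neo-Hookean form", {
  p <- default_params()
  # undeformed identity
  expect_equal(psi_elastin(c(1, 1, 1), c(1, 1, 1), p), 0)
  # hand evaluation at a typical deposition tensor
  G <- c(1 / (1.2 * 1.67), 1.2, 1.67)
  I1 <- sum(G^2)
  expect_equal(psi_elastin(c(1, 1, 1), G, p), 0.04 * (I1 - 3), tolerance = 1e-12)
  # equibiaxial stretch on top of the deposition state
  F3 <- stretch3(1.1, 1.1)
  I1b <- sum((F3 * G)^2)
  expect_equal(psi_elastin(F3, G, p), 0.04 * (I1b - 3), tolerance = 1e-12)
  expect_error(psi_elastin(c(-1, 1, 1), c(1, 1, 1), p), "invalid kinematics")
})

test_that("collagen fiber energy matches an independent tensor evaluation", {
  p <- default_params()
  M <- c(0, cos(p$passive$alpha), sin(p$passive$alpha))

  # no deposition stretch, no dispersion: E = 0 at steady state
  p0 <- p
  p0$prestretch$g_coll <- 1
  p0$passive$kappa <- 0
  expect_equal(psi_collagen_fiber(c(1, 1, 1), c(1, 1, 1), M, p0), 0)

  # steady state with the default deposition tensor: independent script route
  g <- p$prestretch$g_coll
  G <- g * outer(M, M) + (1 / sqrt(g)) * (diag(3) - outer(M, M))
  expect_equal(det(G), 1, tolerance = 1e-12)
  C <- G %*% G
  E <- p$passive$kappa * sum(diag(C)) +
    (1 - 3 * p$passive$kappa) * drop(t(M) %*% C %*% M) - 1
  psi_ref <- p$passive$k1 / (2 * p$passive$k2) *
    (exp(p$passive$k2 * E^2) - 1)
  expect_equal(psi_collagen_fiber(c(1, 1, 1), c(1, 1, 1), M, p), psi_ref,
               tolerance = 1e-12)

  # off-steady cohort: full F F_dep^-1 G route through matrix algebra
  F3 <- stretch3(1.15, 0.95)
  Fd <- stretch3(1.05, 1)
  A <- diag(F3 / Fd)
  Cc <- t(G) %*% t(A) %*% A %*% G
  E2 <- p$passive$kappa * sum(diag(Cc)) +
    (1 - 3 * p$passive$kappa) * drop(t(M) %*% Cc %*% M) - 1
  psi_ref2 <- p$passive$k1 / (2 * p$passive$k2) * (exp(p$passive$k2 * E2^2) - 1)
  expect_equal(psi_collagen_fiber(F3, Fd, M, p), psi_ref2, tolerance = 1e-12)

  # compression contributes through the same even formula (no tension switch)
  Fc <- stretch3(0.9, 1)
  expect_gt(psi_collagen_fiber(Fc, c(1, 1, 1), M, p0), 0)
})

test_that("active energy matches the crossbridge closed form", {
  expect_equal(psi_active(1.5, 0, 0.3, 0.42), 0)
  expect_equal(psi_active(1, 0.5, 0, 0.42), 0)
  expect_equal(psi_active(1.21, 0.5, -0.1, 0.42), 0.42 / 2 * 0.5 * 0.11^2,
               tolerance = 1e-12)
})

test_that("mixture energy is the density-weighted sum of its parts", {
  p <- default_params()
  dep <- deposition_stretches(p, 0.92)
  st <- mixture_state(p)
  fil <- list(n = c(0.3, 0.1, 0.2, 0.4), u_rs = 0.05)

  # zero densities give zero energy
  st0 <- st
  st0$rho_elas <- 0
  st0$rho_csmc <- 0
  st0$rho_ssmc <- 0
  st0$cohorts$mass <- 0
  expect_equal(mixture_energy(st0, fil, dep, p), 0)

  # homeostatic state equals the sum of component oracles
  st$lam <- c(1.05, 1)
  F3 <- stretch3(1.05, 1)
  M <- dep$families[[1]]$M
  e_ref <- st$rho_elas * psi_elastin(F3, dep$G_elas, p) +
    st$cohorts$mass * psi_collagen_fiber(F3, c(1, 1, 1), M, p) +
    st$rho_csmc * psi_active(F3[2]^2, fil$n[3] + fil$n[4], fil$u_rs,
                             p$smc$mu_csmc)
  expect_equal(mixture_energy(st, fil, dep, p), e_ref, tolerance = 1e-12)

  # doubling every density doubles the energy
  st2 <- st
  st2$rho_elas <- 2 * st$rho_elas
  st2$rho_csmc <- 2 * st$rho_csmc
  st2$cohorts$mass <- 2 * st$cohorts$mass
  expect_equal(mixture_energy(st2, fil, dep, p),
               2 * mixture_energy(st, fil, dep, p), tolerance = 1e-12)

  st$rho_elas <- -1
  expect_error(mixture_energy(st, fil, dep, p), "state corruption")
})

test_that("analytic stress matches finite differences of the energy", {
  # energy consistency on random incompressible diagonal deformations
  set.seed(42)
  p <- default_params()
  dep <- deposition_stretches(p, 0.92)
  fil <- list(n = c(0.3, 0.1, 0.2, 0.4), u_rs = 0.05)
  h <- 1e-6
  for (i in 1:100) {
    lt <- runif(1, 0.85, 1.25)
    lz <- runif(1, 0.85, 1.25)
    st <- mixture_state(p, lam = c(lt, lz))
    st$cohorts <- data.frame(tau = c(0, 1), lam_t_dep = c(1, 1.04),
                             lam_z_dep = c(1, 1), mass = c(0.2, 0.1),
                             q = c(0.9, 1))
    sig <- cauchy_stress(st, fil, dep, p)
    en <- function(lt2, lz2) {
      s <- st
      s$lam <- c(lt2, lz2)
      mixture_energy(s, fil, dep, p)
    }
    # sigma_tt - sigma_rr = lam_t dPsi/dlam_t at J = 1 (radial entry adjusts)
    fd_t <- lt * (en(lt + h, lz) - en(lt - h, lz)) / (2 * h)
    fd_z <- lz * (en(lt, lz + h) - en(lt, lz - h)) / (2 * h)
    expect_equal(sig[2], fd_t, tolerance = 1e-5)
    expect_equal(sig[3], fd_z, tolerance = 1e-5)
    expect_equal(sig[1], 0)
  }
})

test_that("steady-state cohorts collapse to a single effective cohort", {
  # when every cohort is deposited at the current deformation, the collagen
  # stress depends only on the deposition tensor and total density
  p <- default_params()
  dep <- deposition_stretches(p, 0.92)
  fil <- list(n = c(1, 0, 0, 0), u_rs = 0)
  lam <- c(1.08, 0.97)
  many <- mixture_state(p, lam)
  many$cohorts <- data.frame(tau = 0:3, lam_t_dep = rep(lam[1], 4),
                             lam_z_dep = rep(lam[2], 4),
                             mass = c(0.1, 0.05, 0.1, 0.05), q = rep(1, 4))
  one <- mixture_state(p, lam)
  one$cohorts <- data.frame(tau = 0, lam_t_dep = lam[1], lam_z_dep = lam[2],
                            mass = 0.3, q = 1)
  many$rho_elas <- one$rho_elas <- 0
  many$rho_csmc <- one$rho_csmc <- 0
  expect_equal(cauchy_stress(many, fil, dep, p),
               cauchy_stress(one, fil, dep, p), tolerance = 1e-12)
})

test_that("deposition tensors are isochoric", {
  p <- default_params()
  dep <- deposition_stretches(p, 1.3)
  expect_equal(prod(dep$G_elas), 1, tolerance = 1e-12)
  for (fam in dep$families) {
    expect_equal(det(fam$G), 1, tolerance = 1e-12)
    expect_equal(sqrt(sum(fam$M^2)), 1, tolerance = 1e-12)
  }
  expect_equal(det(collagen_deposition_tensor(c(0, 1, 0), 1.1)), 1,
               tolerance = 1e-12)
})
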