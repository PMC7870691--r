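## Constrained-mixture constitutive model.
##
## Kinematic convention: the reduced vessel is a thin-walled cylinder whose
## deformation gradient is diagonal in the local (radial, circumferential,
## axial) frame. Diagonal tensors are stored as length-3 numeric vectors in
## that order. Full incompressibility is assumed (J = 1), so lambda_rr =
## 1 / (lambda_tt * lambda_zz); the deviatoric J^(-2/3) projections of the
## energy are retained in the formulas but are no-ops.

#' Diagonal stretch vector from in-plane stretches
#'
#' @param lam_t circumferential stretch (-)
#' @param lam_z axial stretch (-)
#' @return length-3 vector (radial, circumferential, axial) with the radial
#'   entry fixed by incompressibility.
#' @export
stretch3 <- function(lam_t, lam_z = 1) {
  if (any(lam_t <= 0) || any(lam_z <= 0)) {
    stop("invalid kinematics: non-positive stretch", call. = FALSE)
  }
  unname(c(1 / (lam_t * lam_z), lam_t, lam_z))
}

#' Collagen deposition stretch tensor for a fiber direction
#'
#' Fibers are laid down at a constant stretch `g` along the fiber direction
#' `M`, with transverse scaling `1/sqrt(g)` so the tensor is isochoric.
#'
#' @param M unit fiber direction (length-3).
#' @param g fiber deposition stretch (>= 1 in practice).
#' @return 3x3 matrix with unit determinant.
#' @export
collagen_deposition_tensor <- function(M, g) {
  M <- M / sqrt(sum(M^2))
  g * outer(M, M) + (1 / sqrt(g)) * (diag(3) - outer(M, M))
}

#' Deposition stretches and fiber-family precomputations
#'
#' Bundles the elastin deposition tensor (diagonal; radial entry from
#' incompressibility), the two symmetric collagen fiber families with their
#' deposition tensors, and the smooth-muscle direction.
#'
#' @param params `vh_params` list.
#' @param g_elas_circ elastin circumferential deposition stretch, normally
#'   produced by [solve_homeostasis()].
#' @return list with `G_elas` (length-3 diagonal), `g_ax`, `g_coll`,
#'   `g_elas_circ` and `families` (per-family precomputations).
#' @export
deposition_stretches <- function(params, g_elas_circ) {
  g_ax <- params$prestretch$g_ax
  g_c  <- params$prestretch$g_coll
  al   <- params$passive$alpha
  G_elas <- c(1 / (g_elas_circ * g_ax), g_elas_circ, g_ax)
  fams <- lapply(c(1, -1), function(s) {
    M <- c(0, cos(al), s * sin(al))
    G <- collagen_deposition_tensor(M, g_c)
    GM <- drop(G %*% M)
    list(M = M, G = G,
         G2diag = rowSums(G^2),   # diagonal of G %*% G (G symmetric)
         GM2 = GM^2)
  })
  list(g_elas_circ = g_elas_circ, g_ax = g_ax, g_coll = g_c,
       G_elas = G_elas, families = fams)
}

## invariants, energy, unit-density Cauchy stress components and fiber stress
## for collagen cohorts of one family. a2: matrix (n_cohorts x 3) of squared
## diagonal entries of A = F %*% F_dep^-1.
.coll_eval <- function(a2, fam, passive) {
  kap <- passive$kappa
  I1 <- drop(a2 %*% fam$G2diag)
  I4 <- drop(a2 %*% fam$GM2)
  E <- kap * I1 + (1 - 3 * kap) * I4 - 1
  ek <- exp(passive$k2 * E^2)
  psi <- passive$k1 / (2 * passive$k2) * (ek - 1)
  dpsi <- passive$k1 * E * ek
  w <- kap * matrix(fam$G2diag, nrow(a2), 3, byrow = TRUE) +
    (1 - 3 * kap) * matrix(fam$GM2, nrow(a2), 3, byrow = TRUE)
  sig <- 2 * dpsi * a2 * w          # sigma_hat_ii = lambda_i dpsi/dlambda_i
  zeta <- 2 * dpsi * (E + 1)        # tr(sigma_hat): scalar fiber-stress measure
  list(I1 = I1, I4 = I4, E = E, psi = psi, sig = sig, zeta = zeta)
}

#' Elastin strain-energy density
#'
#' Neo-Hookean energy of the elastin constituent,
#' `C10 * (I1bar - 3)` with `I1bar` the first invariant of the deviatoric
#' right Cauchy-Green tensor of `F_elas = F . G_elas`.
#'
#' @param F mixture stretch, length-3 diagonal vector (see [stretch3()]).
#' @param G_elas elastin deposition stretch, length-3 diagonal vector with
#'   unit product.
#' @param params `vh_params` list.
#' @return energy per unit (referential, normalized) elastin density (MPa).
#' @export
psi_elastin <- function(F, G_elas, params) {
  Fe <- F * G_elas
  if (any(!is.finite(Fe)) || any(Fe <= 0)) {
    stop("invalid kinematics: elastin stretch not positive definite",
         call. = FALSE)
  }
  J <- prod(Fe)
  I1 <- J^(-2 / 3) * sum(Fe^2)
  params$passive$C10 * (I1 - 3)
}

#' Collagen fiber strain-energy density for one cohort
#'
#' GOH fiber energy `k1/(2 k2) * (exp(k2 * E^2) - 1)` with the
#' dispersion-weighted invariant `E = kappa*I1bar + (1-3*kappa)*I4bar - 1` of
#' the cohort deformation `F_coll = F . F_dep^-1 . G_coll`. The energy is
#' symmetric in E: compressed fibers contribute through the same formula (no
#' tension-only switch is used).
#'
#' @param F current mixture stretch (length-3 diagonal vector).
#' @param F_dep mixture stretch at cohort deposition (length-3 diagonal
#'   vector); at steady state `F_dep = F`.
#' @param M unit fiber direction.
#' @param params `vh_params` list.
#' @return energy per unit cohort mass (MPa).
#' @export
psi_collagen_fiber <- function(F, F_dep, M, params) {
  if (any(F <= 0) || any(F_dep <= 0)) {
    stop("invalid kinematics: non-positive stretch", call. = FALSE)
  }
  G <- collagen_deposition_tensor(M, params$prestretch$g_coll)
  GM <- drop(G %*% M / sqrt(sum(M^2)))
  fam <- list(M = M, G = G, G2diag = rowSums(G^2), GM2 = GM^2)
  a2 <- matrix((F / F_dep)^2, 1, 3)
  .coll_eval(a2, fam, params$passive)$psi
}

#' Active smooth-muscle strain-energy density
#'
#' `mu/2 * (n3+n4) * (I4_smc + u_rs - 1)^2`: energy of attached crossbridges
#' at filament overlap `I4_smc + u_rs - 1`.
#'
#' @param I4_smc fourth invariant of the SMC stretch along the circumferential
#'   cell direction (-).
#' @param n_attached `n3 + n4`, fraction of attached crossbridges in `[0,1]`.
#' @param u_rs normalized filament sliding (-).
#' @param mu_csmc active stiffness parameter (MPa).
#' @return energy per unit contractile SMC density (MPa).
#' @export
psi_active <- function(I4_smc, n_attached, u_rs, mu_csmc) {
  stopifnot(n_attached >= 0, n_attached <= 1)
  mu_csmc / 2 * n_attached * (I4_smc + u_rs - 1)^2
}

#' Single-point mixture state
#'
#' Container for the referential constituent densities and the collagen cohort
#' ledger at one material point. Cohort masses are totals over both symmetric
#' fiber families (the families see identical invariants under diagonal
#' kinematics).
#'
#' @param params `vh_params` list.
#' @param lam current in-plane stretches `c(lam_t, lam_z)` vs the homeostatic
#'   reference.
#' @return list of class `mixture_state` with densities, a cohort data frame
#'   (`tau`, `lam_t_dep`, `lam_z_dep`, `mass`, `q`), current stretch and a
#'   running overstretch history `beta_hist`.
#' @export
mixture_state <- function(params, lam = c(1, 1)) {
  d <- params$densities
  st <- list(
    rho_elas = d$rho0_elas,
    rho_csmc = d$rho0_csmc,
    rho_ssmc = d$rho0_ssmc,
    cohorts = data.frame(tau = 0L, lam_t_dep = 1, lam_z_dep = 1,
                         mass = d$rho0_coll, q = 1),
    lam = lam,
    beta_hist = 0
  )
  class(st) <- c("mixture_state", "list")
  st
}

#' Total collagen density of a mixture state
#'
#' @param state `mixture_state`.
#' @return sum over cohorts of `mass * q`.
#' @export
collagen_density <- function(state) {
  sum(state$cohorts$mass * state$cohorts$q)
}

## squared A = F / F_dep entries for every cohort: (n x 3)
.cohort_a2 <- function(cohorts, lam) {
  F3 <- stretch3(lam[1], lam[2])
  Fd_t <- cohorts$lam_t_dep
  Fd_z <- cohorts$lam_z_dep
  cbind((F3[1] * Fd_t * Fd_z)^2, (F3[2] / Fd_t)^2, (F3[3] / Fd_z)^2)
}

#' Mixture strain-energy density
#'
#' Mass-averaged energy of elastin, all collagen cohorts of both fiber
#' families and the contractile SMC term:
#' `Psi = rho_elas psi_elas + sum_cohorts m q psi_coll + rho_csmc psi_act`.
#'
#' @param state `mixture_state` (see [mixture_state()]).
#' @param fil filament state: list with `n` (fractions n1..n4) and `u_rs`.
#' @param dep output of [deposition_stretches()].
#' @param params `vh_params` list.
#' @return energy density (MPa).
#' @export
mixture_energy <- function(state, fil, dep, params) {
  if (state$rho_elas < 0 || state$rho_csmc < 0 || state$rho_ssmc < 0 ||
      any(state$cohorts$mass < 0)) {
    stop("state corruption: negative density", call. = FALSE)
  }
  F3 <- stretch3(state$lam[1], state$lam[2])
  e_el <- state$rho_elas * psi_elastin(F3, dep$G_elas, params)
  a2 <- .cohort_a2(state$cohorts, state$lam)
  ev <- .coll_eval(a2, dep$families[[1]], params$passive)
  e_co <- sum(state$cohorts$mass * state$cohorts$q * ev$psi)
  I4s <- F3[2]^2
  e_ac <- state$rho_csmc *
    psi_active(I4s, fil$n[3] + fil$n[4], fil$u_rs, params$smc$mu_csmc)
  e_el + e_co + e_ac
}

#' Mixture Cauchy stress (diagonal, radial condition enforced)
#'
#' Push-forward of the energy derivative under full incompressibility, with
#' the Lagrange pressure set by the thin-wall condition `sigma_rr = 0`.
#'
#' @inheritParams mixture_energy
#' @return length-3 Cauchy stress vector (radial, circumferential, axial) in
#'   MPa; the radial entry is 0 by construction.
#' @export
cauchy_stress <- function(state, fil, dep, params) {
  sh <- .stress_hat(state, fil, dep, params)
  sh - sh[1]
}

## sigma_hat_ii = sum_constituents rho * lambda_i dpsi/dlambda_i (no pressure)
.stress_hat <- function(state, fil, dep, params) {
  F3 <- stretch3(state$lam[1], state$lam[2])
  Fe <- F3 * dep$G_elas
  s_el <- state$rho_elas * 2 * params$passive$C10 * Fe^2
  a2 <- .cohort_a2(state$cohorts, state$lam)
  ev <- .coll_eval(a2, dep$families[[1]], params$passive)
  mq <- state$cohorts$mass * state$cohorts$q
  s_co <- drop(mq %*% ev$sig)
  I4s <- F3[2]^2
  natt <- fil$n[3] + fil$n[4]
  s_ac <- c(0, state$rho_csmc * 2 * params$smc$mu_csmc * natt *
              (I4s + fil$u_rs - 1) * I4s, 0)
  s_el + s_co + s_ac
}

#' Fiber-stress measure of a collagen cohort
#'
#' Trace of the unit-density Cauchy stress of the cohort, used as the scalar
#' fiber stress entering the stress-deviation stimulus of the remodeling and
#' damage laws. At steady state (`F_dep = F`) it depends only on the
#' deposition tensor, so all steady cohorts share one homeostatic value.
#'
#' @inheritParams psi_collagen_fiber
#' @return scalar fiber stress (MPa).
#' @export
collagen_fiber_stress <- function(F, F_dep, M, params) {
  G <- collagen_deposition_tensor(M, params$prestretch$g_coll)
  GM <- drop(G %*% (M / sqrt(sum(M^2))))
  fam <- list(G2diag = rowSums(G^2), GM2 = GM^2)
  a2 <- matrix((F / F_dep)^2, 1, 3)
  .coll_eval(a2, fam, params$passive)$zeta
}
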