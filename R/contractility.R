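## Vasoactive-agent chemistry, Hai-Murphy four-state crossbridge kinetics and
## filament-sliding mechanics. Kinetics run on a seconds time scale; the
## vessel-level code uses the steady states (quasi-static separation from the
## day-scale remodeling).

#' Normalized Hill response to an agent concentration
#'
#' `R = c / (c + K)`, in `[0, 1)`.
#'
#' @param conc agent concentration (M, >= 0).
#' @param K Hill inflection constant (M, > 0).
#' @return normalized response (vectorized).
#' @export
hill_response <- function(conc, K) {
  stopifnot(all(conc >= 0), K > 0)
  conc / (conc + K)
}

#' Endothelium-produced NO concentration in response to ACh
#'
#' Log-dose saturation fit of endothelial NO release,
#' `[NO]_ec = amp * (log10(ACh) + offset) / (shape + log10(ACh) + offset)`,
#' scaled linearly by the intact endothelium fraction (a denuded endothelium
#' produces no NO). The fit covers ACh above `10^-offset` M; below that the
#' output is clipped to zero with a warning (the curve is not a measurement
#' there).
#'
#' @param conc_ACh acetylcholine bath concentration (M).
#' @param phi_ec intact endothelium fraction in `[0, 1]`.
#' @param params `vh_params` list.
#' @return NO concentration produced by the endothelium (M).
#' @export
endothelial_no <- function(conc_ACh, phi_ec, params) {
  ct <- params$contractility
  stopifnot(phi_ec >= 0, phi_ec <= 1)
  if (conc_ACh <= 0) return(0)
  x <- log10(conc_ACh) + ct$ACh_offset
  if (x < 0) {
    warning("ACh concentration below the fitted domain; NO_ec clipped to 0")
    return(0)
  }
  max(ct$ACh_amp * x / (ct$ACh_shape + x), 0) * phi_ec
}

#' Intracellular calcium concentration
#'
#' `Ca = Ca_hom + alpha_PE * R_PE - alpha_NO * R_NO`, clipped at zero.
#'
#' @param R_PE,R_NO normalized PE and NO responses in `[0, 1]`.
#' @param params `vh_params` list.
#' @return calcium concentration (M).
#' @export
calcium_level <- function(R_PE, R_NO, params) {
  ct <- params$contractility
  pmax(ct$Ca_hom + ct$alpha_PE * R_PE - ct$alpha_NO * R_NO, 0)
}

#' Crossbridge transition rates from the chemical environment
#'
#' Phosphorylation rates `k1 = k6` follow Michaelis-Menten kinetics of the
#' calcium-calmodulin complex `CaCaM = alpha_Ca * Ca`:
#' `k1 = CaCaM^2 / (CaCaM^2 + K_CaCaM^2)`. Dephosphorylation rates
#' `k2 = k5 = k2_hom + alpha2 * R_NO` increase with NO. `k3`, `k4`, `k7` are
#' fixed constants.
#'
#' @param Ca intracellular calcium (M, >= 0).
#' @param R_NO normalized NO response in `[0, 1]`.
#' @param params `vh_params` list.
#' @return named list of rates `k1..k7` (1/s).
#' @export
phosphorylation_rates <- function(Ca, R_NO, params) {
  ct <- params$contractility
  stopifnot(Ca >= 0)
  cacam <- ct$alpha_Ca * Ca
  k1 <- cacam^2 / (cacam^2 + ct$K_CaCaM^2)
  k2 <- ct$k2_hom + ct$alpha2 * R_NO
  list(k1 = k1, k2 = k2, k3 = ct$k3, k4 = ct$k4, k5 = k2, k6 = k1, k7 = ct$k7)
}

#' Resolved chemical environment for a dosing condition
#'
#' Composes the agent responses: PE acts directly, applied NO (e.g. a
#' nitroprusside dose) and endothelium-produced NO (ACh pathway, scaled by the
#' intact endothelium fraction) add, and the resulting calcium sets the
#' crossbridge rates.
#'
#' @param conc_PE,conc_ACh,conc_NO bath concentrations (M).
#' @param phi_ec intact endothelium fraction in `[0, 1]`.
#' @param params `vh_params` list.
#' @return list with responses (`R_PE`, `R_NO`), concentrations (`Ca`,
#'   `NO_total`, `NO_ec`) and `rates`.
#' @export
chem_env <- function(conc_PE = 0, conc_ACh = 0, conc_NO = 0, phi_ec = 1,
                     params = default_params()) {
  ct <- params$contractility
  no_ec <- endothelial_no(conc_ACh, phi_ec, params)
  no_tot <- conc_NO + no_ec
  R_NO <- hill_response(no_tot, ct$K_NO)
  R_PE <- hill_response(conc_PE, ct$K_PE)
  Ca <- calcium_level(R_PE, R_NO, params)
  list(R_PE = R_PE, R_NO = R_NO, NO_ec = no_ec, NO_total = no_tot, Ca = Ca,
       rates = phosphorylation_rates(Ca, R_NO, params))
}

#' Hai-Murphy rate matrix
#'
#' 4x4 generator of the four-state crossbridge kinetics (states: n1 detached
#' dephosphorylated, n2 detached phosphorylated, n3 attached phosphorylated,
#' n4 attached dephosphorylated, the latch state). Columns sum to zero, so the
#' dynamics conserve `sum(n)`.
#'
#' @param rates named list with `k1..k7` (1/s).
#' @return 4x4 matrix.
#' @export
hm_rate_matrix <- function(rates) {
  with(rates, matrix(c(
    -k1, k2, 0, k7,
    k1, -(k2 + k3), k4, 0,
    0, k3, -(k4 + k5), k6,
    0, 0, k5, -(k6 + k7)
  ), 4, 4, byrow = TRUE))
}

#' Advance the crossbridge state fractions over a time interval
#'
#' Exact (matrix-exponential) integration of the linear Hai-Murphy system;
#' unconditionally stable for stiff rate combinations and conserving
#' `sum(n) = 1` to machine precision.
#'
#' @param n state fractions `c(n1, n2, n3, n4)` summing to 1.
#' @param rates named list with `k1..k7`.
#' @param dt_s time interval (s).
#' @return updated state fractions.
#' @export
hai_murphy_step <- function(n, rates, dt_s) {
  stopifnot(length(n) == 4, dt_s >= 0)
  A <- hm_rate_matrix(rates)
  drop(as.matrix(Matrix::expm(A * dt_s)) %*% n)
}

#' Steady state of the crossbridge kinetics
#'
#' The unique normalized non-negative null vector of the rate matrix. If the
#' attached states are unreachable and the detached split is indeterminate
#' (degenerate matrix), returns `n1 = 1` with a warning.
#'
#' @param rates named list with `k1..k7`.
#' @return steady state fractions `c(n1, n2, n3, n4)`.
#' @export
hai_murphy_steady <- function(rates) {
  A <- hm_rate_matrix(rates)
  B <- rbind(A[1:3, ], rep(1, 4))
  n <- tryCatch(solve(B, c(0, 0, 0, 1)), error = function(e) NULL)
  if (is.null(n) || any(!is.finite(n)) || any(n < -1e-9)) {
    warning("degenerate crossbridge kinetics; returning all-detached state")
    return(c(1, 0, 0, 0))
  }
  pmax(n, 0) / sum(pmax(n, 0))
}

#' Filament matrix driving stress
#'
#' `P_mat = mu * (n3+n4) * (I4_smc + u_rs - 1)` (with the deviatoric factor
#' `J^(-2/3) = 1` under incompressibility): the stress the surrounding matrix
#' exerts on the contractile unit.
#'
#' @param u_rs normalized filament sliding.
#' @param I4_smc fourth invariant of the SMC stretch.
#' @param n state fractions.
#' @param params `vh_params` list.
#' @return driving stress (MPa).
#' @export
p_mat <- function(u_rs, I4_smc, n, params) {
  params$smc$mu_csmc * (n[3] + n[4]) * (I4_smc + u_rs - 1)
}

#' Crossbridge driving stress (three-branch law)
#'
#' Clamped between the cycling-bridge floor `kappa_c * n3` and the
#' all-attached ceiling `kappa_c * (n3 + n4)`.
#'
#' @inheritParams p_mat
#' @return driving stress (MPa).
#' @export
p_smc <- function(u_rs, I4_smc, n, params) {
  pm <- p_mat(u_rs, I4_smc, n, params)
  lo <- params$smc$kappa_c * n[3]
  hi <- params$smc$kappa_c * (n[3] + n[4])
  min(max(pm, lo), hi)
}

#' Transient filament-sliding evolution
#'
#' Explicit integration of `du/dt = (P_smc - P_mat) / eta` at fixed state
#' fractions and stretch; converges to the sliding at which
#' `P_mat = P_smc`.
#'
#' @param u_rs initial sliding.
#' @param I4_smc fourth invariant of the SMC stretch.
#' @param n state fractions.
#' @param params `vh_params` list.
#' @param t_end integration time (s).
#' @param dt_s step (s), defaults to the configured kinetic step.
#' @return final sliding value.
#' @export
sliding_evolution <- function(u_rs, I4_smc, n, params, t_end,
                              dt_s = params$contractility$dt_s) {
  eta <- params$contractility$eta
  steps <- max(1L, ceiling(t_end / dt_s))
  for (i in seq_len(steps)) {
    u_rs <- u_rs + dt_s / eta *
      (p_smc(u_rs, I4_smc, n, params) - p_mat(u_rs, I4_smc, n, params))
  }
  u_rs
}

#' Quasi-static filament sliding
#'
#' Closed-form steady sliding reached from the current value: if `P_mat` is
#' already inside the band `[kappa_c n3, kappa_c (n3+n4)]` the sliding does
#' not evolve; below the band it converges to
#' `u = kappa_c n3 / (mu (n3+n4)) + 1 - I4`; above it to
#' `u = kappa_c / mu + 1 - I4`.
#'
#' @inheritParams p_mat
#' @return steady sliding value.
#' @export
sliding_steady <- function(u_rs, I4_smc, n, params) {
  natt <- n[3] + n[4]
  if (natt <= 0) return(u_rs)
  mu <- params$smc$mu_csmc
  kc <- params$smc$kappa_c
  pm <- p_mat(u_rs, I4_smc, n, params)
  if (pm < kc * n[3]) {
    kc * n[3] / (mu * natt) + 1 - I4_smc
  } else if (pm > kc * natt) {
    kc / mu + 1 - I4_smc
  } else {
    u_rs
  }
}

#' Steady active circumferential stress under a dosing condition
#'
#' Composes chemistry, crossbridge steady state and quasi-static sliding into
#' one stress evaluation: agents set the rates, the rates set the state
#' fractions, the sliding relaxes to its steady value, and the resulting
#' crossbridge stress is pushed forward and weighted by the surviving
#' contractile SMC density.
#'
#' @param conc_PE,conc_ACh,conc_NO bath concentrations (M).
#' @param phi_ec intact endothelium fraction.
#' @param I4_smc fourth invariant of the SMC stretch.
#' @param rho_csmc_rel relative contractile SMC density
#'   `rho_csmc / rho0_csmc`.
#' @param params `vh_params` list.
#' @param u_rs previous sliding value (path dependence of the three-branch
#'   law); defaults to the relaxed state.
#' @return list with `stress` (active Cauchy circumferential stress, MPa),
#'   `P_mat`, state fractions `n`, sliding `u_rs` and the chemical
#'   environment `env`.
#' @export
active_tone <- function(conc_PE = 0, conc_ACh = 0, conc_NO = 0, phi_ec = 1,
                        I4_smc = 1, rho_csmc_rel = 1,
                        params = default_params(), u_rs = 0) {
  env <- chem_env(conc_PE, conc_ACh, conc_NO, phi_ec, params)
  n <- hai_murphy_steady(env$rates)
  u <- sliding_steady(u_rs, I4_smc, n, params)
  pm <- p_mat(u, I4_smc, n, params)
  sig <- 2 * I4_smc * pm * rho_csmc_rel * default_rho0_csmc(params)
  list(stress = sig, P_mat = pm, n = n, u_rs = u, env = env)
}

default_rho0_csmc <- function(params) params$densities$rho0_csmc
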