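## Day-scale remodeling laws: collagen cohort turnover, SMC phenotype
## switching, endothelial healing and inflammation. The vessel-level daily
## driver lives in vessel.R; the functions here are the elementary update
## rules, each one explicit forward-Euler over one step of length dt_day.

#' One survival-decay step of a collagen cohort
#'
#' `q <- q * exp(-K_qh * dt * (1 + dzeta^2))`: stress-accelerated first-order
#' decay. At homeostasis (`dzeta = 0`) the half-life is `log(2)/K_qh` days.
#'
#' @param q current survival fraction(s) in `(0, 1]`.
#' @param delta_zeta normalized fiber-stress deviation(s).
#' @param params `vh_params` list.
#' @return updated survival fraction(s).
#' @export
cohort_survival_step <- function(q, delta_zeta, params) {
  r <- params$remodeling
  q * exp(-r$K_qh * r$dt_day * (1 + delta_zeta^2))
}

#' Normalized fiber-stress deviation
#'
#' `(sigma_f - sigma_f_hom) / sigma_f_hom`: dimensionless deviation of the
#' current cohort fiber stress from its homeostatic value; 0 at homeostasis,
#' -1 for a fully unloaded fiber.
#'
#' @param sigma_fiber current fiber stress (MPa, vectorized).
#' @param sigma_fiber_hom homeostatic fiber stress (MPa, > 0).
#' @return dimensionless deviation(s).
#' @export
delta_zeta <- function(sigma_fiber, sigma_fiber_hom) {
  if (any(sigma_fiber_hom <= 0)) {
    stop("homeostatic fiber stress must be > 0", call. = FALSE)
  }
  (sigma_fiber - sigma_fiber_hom) / sigma_fiber_hom
}

#' Baseline collagen production rate
#'
#' Chosen by the homeostatic stationarity condition: the mass deposited per
#' step must exactly replace the homeostatic first-order decay, i.e.
#' `m0 * dt = rho0_coll * (1 - exp(-K_qh * dt))`. With this choice the total
#' collagen density is an exact fixed point at homeostasis for any step size.
#'
#' @param params `vh_params` list.
#' @return baseline production rate `m0` (mass per day, both families).
#' @export
m0_collagen <- function(params) {
  r <- params$remodeling
  params$densities$rho0_coll * (1 - exp(-r$K_qh * r$dt_day)) / r$dt_day
}

#' Collagen production rate of new cohorts
#'
#' `m = m0 * Gamma` with the production stimulus
#' `Gamma = (1 + (rho_csmc/rho0_csmc) * K_m * dlambda) * rho_ssmc/rho0_ssmc`
#' (original variant). Under the `mech_independent_production` variant the
#' mechanical gain is dropped: `Gamma = rho_ssmc/rho0_ssmc`. Gamma is clamped
#' at zero.
#'
#' @param rho_csmc,rho_ssmc current contractile / synthetic SMC densities
#'   (vectorized over material points).
#' @param dlambda mechanical stimulus `lambda_tt - 1`.
#' @param params `vh_params` list.
#' @return deposition mass rate (per day, both families).
#' @export
collagen_production <- function(rho_csmc, rho_ssmc, dlambda, params) {
  d <- params$densities
  gam <- if (params$remodeling$variant == "mech_independent_production") {
    rho_ssmc / d$rho0_ssmc
  } else {
    (1 + rho_csmc / d$rho0_csmc * params$remodeling$K_m * dlambda) *
      rho_ssmc / d$rho0_ssmc
  }
  m0_collagen(params) * pmax(gam, 0)
}

#' One phenotype-switching step of the SMC densities
#'
#' Contractile cells dedifferentiate at rate `dlambda * K_dd` (and
#' redifferentiate for negative `dlambda`); the contractile pool is capped by
#' the relative elastin grip and its increase by the available synthetic
#' cells. Synthetic cells proliferate mechanically (`dlambda * K_pl`) and
#' under inflammation (`K_ic * phi_ic`), and receive whatever mass leaves the
#' contractile pool, so phenotype exchange conserves SMC mass apart from the
#' explicit proliferation terms. Under the `no_redifferentiation` variant the
#' mechanical terms are switched off whenever `dlambda < 0`.
#'
#' @param rho_csmc,rho_ssmc current densities (vectorized over points).
#' @param dlambda mechanical stimulus `lambda_tt - 1`.
#' @param phi_ic inflammation level in `[0, 1]`.
#' @param rho_elas_rel relative elastin density `rho_elas / rho0_elas`.
#' @param params `vh_params` list.
#' @return list with updated `rho_csmc` and `rho_ssmc`.
#' @export
smc_phenotype_step <- function(rho_csmc, rho_ssmc, dlambda, phi_ic,
                               rho_elas_rel, params) {
  r <- params$remodeling
  d <- params$densities
  dt <- r$dt_day
  off_mech <- r$variant == "no_redifferentiation" & dlambda < 0
  dl <- ifelse(off_mech, 0, dlambda)

  rc_new <- rho_csmc * (1 - dl * r$K_dd * dt)
  # elastin-grip cap, then availability cap on any increase: a contractile
  # gain can only draw on the synthetic pool left after its own
  # proliferation update
  rs_prolif <- rho_ssmc * (dl * r$K_pl * dt + 1 + r$K_ic * dt * phi_ic)
  rc_new <- pmin(rc_new, d$rho0_csmc * rho_elas_rel)
  rc_new <- pmin(rc_new, rho_csmc + pmax(rs_prolif, 0))
  rc_new <- pmax(rc_new, 0)

  rs_new <- rs_prolif + (rho_csmc - rc_new)
  if (any(rs_new < -1e-12)) warning("synthetic SMC density clipped at 0")
  rs_new <- pmax(rs_new, 0)
  list(rho_csmc = rc_new, rho_ssmc = rs_new)
}

#' One logistic endothelial healing step
#'
#' Forward-Euler step of the logistic regrowth law:
#' `phi <- (K_ec * dt * (1 - phi) + 1) * phi`. Fixed points at 0 (no cells
#' left, no recovery) and 1 (fully healed); phi stays in `[0, 1]` for
#' `K_ec * dt <= 1`.
#'
#' @param phi_ec intact endothelium fraction in `[0, 1]`.
#' @param params `vh_params` list.
#' @return updated fraction.
#' @export
endothelium_heal_step <- function(phi_ec, params) {
  stopifnot(all(phi_ec >= 0), all(phi_ec <= 1))
  r <- params$remodeling
  (r$K_ec * r$dt_day * (1 - phi_ec) + 1) * phi_ec
}

#' Inflammation level
#'
#' Inflammatory agents enter where the endothelium is missing:
#' `phi_ic = 1 - phi_ec`.
#'
#' @param phi_ec intact endothelium fraction in `[0, 1]`.
#' @return inflammation level in `[0, 1]`.
#' @export
inflammation <- function(phi_ec) {
  stopifnot(all(phi_ec >= 0), all(phi_ec <= 1))
  1 - phi_ec
}
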