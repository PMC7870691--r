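## Acute clamp damage: overstretch history, contractile SMC and collagen
## damage fractions, endothelial survival.

#' Update the overstretch history
#'
#' Running maximum of the absolute circumferential stretch deviation
#' `|lambda_tt - 1|` over the loading history. Non-decreasing, so damage is
#' irreversible: releasing the load does not reduce beta.
#'
#' @param beta_hist previous history value (>= 0).
#' @param lambda_tt current local circumferential stretch vs the homeostatic
#'   reference (> 0).
#' @return updated beta (vectorized).
#' @export
update_beta <- function(beta_hist, lambda_tt) {
  if (any(lambda_tt <= 0)) stop("lambda_tt must be > 0", call. = FALSE)
  pmax(beta_hist, abs(lambda_tt - 1))
}

#' Contractile SMC damage fraction
#'
#' `d = 1 - exp(-beta / m_csmc)`: saturating fraction of contractile cells
#' killed by the overstretch history.
#'
#' @param beta overstretch history (>= 0).
#' @param m_csmc damage constant (> 0).
#' @return damage fraction in `[0, 1)` (vectorized).
#' @export
smc_damage <- function(beta, m_csmc) {
  stopifnot(all(beta >= 0), m_csmc > 0)
  1 - exp(-beta / m_csmc)
}

#' Collagen damage fraction
#'
#' `d = 1 - exp(-dzeta / m_coll)` for positive fiber overstress `dzeta`;
#' compressive deviations do not destroy collagen.
#'
#' @param delta_zeta normalized fiber-stress deviation (see [delta_zeta()]).
#' @param m_coll_dmg damage constant (> 0).
#' @return damage fraction in `[0, 1)` (vectorized).
#' @export
collagen_damage <- function(delta_zeta, m_coll_dmg) {
  stopifnot(m_coll_dmg > 0)
  ifelse(delta_zeta > 0, 1 - exp(-delta_zeta / m_coll_dmg), 0)
}

#' Global endothelial survival fraction
#'
#' The local endothelium dies where the luminal overstretch history exceeds
#' the threshold `m_ec`. The model tracks a single global survival fraction:
#' the fraction of luminal surface points below the threshold.
#'
#' @param beta_field per-point beta values on the luminal surface.
#' @param m_ec death threshold on beta.
#' @return scalar fraction of intact endothelium in `[0, 1]`.
#' @export
endothelium_damage <- function(beta_field, m_ec) {
  if (length(beta_field) == 0) {
    stop("empty luminal surface: no endothelium points", call. = FALSE)
  }
  mean(beta_field < m_ec)
}
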