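## Parametric clamp-injury profiles. The true overstretch field under a clamp
## comes from 3D contact mechanics; here it is abstracted by a signed
## circumferential stretch-deviation field on the half cylinder that mimics a
## flattened tube: a compression plateau in the clamped contact region
## (centered at theta = pi/2) and narrow tensile zones at the clamp-edge
## angular positions (theta = 0 and pi) where the inner wall bends around the
## plate edge, both decaying radially outward. The overstretch measure beta is
## the magnitude of the deviation, so compression kills cells and endothelium,
## while only the tensile edge zones overstress (and damage) collagen.
## Three parameters are calibrated once per clamp load against the acute
## global endothelial survival, mean contractile-SMC damage and mean collagen
## damage; the tensile-zone width is fixed at the bending length scale
## 2 h / r of the wall.

## radial decay of the injury toward the outer wall
.beta_radial <- function(rhat) 1 - 0.6 * rhat

#' Signed clamp stretch-deviation field
#'
#' @param theta circumferential positions on the half cylinder, in `[0, pi]`
#'   (rad); clamp edges sit at 0 and pi, the contact flat at pi/2.
#' @param rhat normalized radial position, 0 = luminal surface, 1 = outer wall
#'   (recycled against `theta`).
#' @param peak_t,width_t peak and circumferential width of the tensile
#'   clamp-edge zones (-, rad).
#' @param peak_c,width_c peak and width of the compressive contact plateau.
#' @return signed circumferential stretch deviation `lambda_tt - 1` (-).
#' @export
fixture_delta <- function(theta, rhat, peak_t, width_t, peak_c, width_c) {
  stopifnot(peak_t >= 0, width_t > 0, peak_c >= 0, width_c > 0)
  d_edge <- pmin(theta, pi - theta)
  d_mid <- abs(theta - pi / 2)
  (peak_t * exp(-(d_edge / width_t)^4) -
      peak_c * exp(-(d_mid / width_c)^4)) * .beta_radial(rhat)
}

#' Clamp-injury overstretch field
#'
#' Magnitude of the signed stretch deviation of [fixture_delta()]; with the
#' default zero compression component this is the classic edge-concentrated
#' tensile profile, deterministic and maximal at the luminal-surface edge
#' points.
#'
#' @inheritParams fixture_delta
#' @param peak,width tensile peak and width (aliases of `peak_t`, `width_t`).
#' @return beta values (-).
#' @export
fixture_beta <- function(theta, rhat = 0, peak, width,
                         peak_c = 0, width_c = 1) {
  if (peak_c == 0) {
    d_edge <- pmin(theta, pi - theta)
    peak * exp(-(d_edge / width)^4) * .beta_radial(rhat)
  } else {
    abs(fixture_delta(theta, rhat, peak, width, peak_c, width_c))
  }
}

## acute injury levels (global endothelial survival, mean contractile SMC
## damage, mean collagen damage) measured immediately after the two clamp
## loads; calibration targets for the profile parameters.
.clamp_injury_targets <- function(load_case) {
  tab <- list(
    "0.6"  = c(phi_ec = 0.3113, d_csmc = 1 - 0.7170, d_coll = 1 - 0.9076),
    "1.27" = c(phi_ec = 0.2719, d_csmc = 1 - 0.7190, d_coll = 1 - 0.9071)
  )
  key <- format(load_case)
  if (is.null(tab[[key]])) {
    stop("no calibration targets for clamp load ", load_case,
         " N; supply an explicit injury profile", call. = FALSE)
  }
  tab[[key]]
}

## mean collagen damage over the grid implied by a signed stretch field;
## only tensile points overstress the fibers (the membrane kinematics does not
## represent the flattened contact region, and compression does not damage
## collagen)
.mean_d_coll <- function(delta, params, zeta_hom) {
  mean(.d_coll_field(delta, params, zeta_hom))
}

.d_coll_field <- function(delta, params, zeta_hom) {
  M <- c(0, cos(params$passive$alpha), sin(params$passive$alpha))
  d <- numeric(length(delta))
  ten <- delta > 0
  if (any(ten)) {
    zc <- vapply(delta[ten], function(x) {
      collagen_fiber_stress(stretch3(1 + x, 1), c(1, 1, 1), M, params)
    }, numeric(1))
    d[ten] <- collagen_damage(delta_zeta(zc, zeta_hom),
                              params$damage$m_coll_dmg)
  }
  d
}

#' Calibrate the injury-profile parameters for a clamp load
#'
#' Finds the parameters of [fixture_delta()] such that the acute global
#' endothelial survival, the grid-mean contractile SMC damage and the
#' grid-mean collagen damage match the measured levels for the given clamp
#' load. The tensile-zone width is fixed at the wall bending scale
#' `2 * thickness / r0`; the tensile peak is set by the collagen target
#' (collagen is only damaged in tension), then the compression peak and width
#' by the SMC and endothelial targets through nested root solves.
#'
#' @param params `vh_params` list.
#' @param load_case clamp load in N per 2 mm clamp length (0.6 or 1.27).
#' @param targets optional named vector
#'   `c(phi_ec =, d_csmc =, d_coll =)` overriding the stored acute levels.
#' @return list with `peak_t`, `width_t`, `peak_c`, `width_c` and the achieved
#'   `phi_ec`, `d_csmc`, `d_coll`.
#' @export
calibrate_clamp_profile <- function(params, load_case, targets = NULL) {
  if (is.null(targets)) targets <- .clamp_injury_targets(load_case)
  g <- params$geometry
  grid <- .vessel_grid(g)
  th_lum <- .lumen_theta(g)
  m_ec <- params$damage$m_ec
  width_t <- 2 * g$thickness / (g$inner_diameter / 2)
  zeta_hom <- collagen_fiber_stress(
    c(1, 1, 1), c(1, 1, 1),
    c(0, cos(params$passive$alpha), sin(params$passive$alpha)), params)

  # 1. tensile peak from the collagen target (compression does not damage it)
  f_coll <- function(pt, pc = 0, wc = 1) {
    d <- fixture_delta(grid$theta, grid$rhat, pt, width_t, pc, wc)
    .mean_d_coll(d, params, zeta_hom) - targets[["d_coll"]]
  }
  peak_t <- stats::uniroot(f_coll, c(0.01, 3), tol = 1e-9,
                           extendInt = "upX")$root

  # 2. compression width from the endothelial target, peak from the SMC target
  width_for <- function(pc) {
    f <- function(wc) {
      b <- abs(fixture_delta(th_lum, 0, peak_t, width_t, pc, wc))
      endothelium_damage(b, m_ec) - targets[["phi_ec"]]
    }
    if (f(0.02) < 0 || f(pi) > 0) return(NA_real_)
    stats::uniroot(f, c(0.02, pi), tol = 1e-10)$root
  }
  dc_for <- function(pc) {
    wc <- width_for(pc)
    if (is.na(wc)) return(NA_real_)
    b <- abs(fixture_delta(grid$theta, grid$rhat, peak_t, width_t, pc, wc))
    mean(smc_damage(b, params$damage$m_csmc)) - targets[["d_csmc"]]
  }
  lo <- m_ec + 0.02
  hi <- 0.95
  flo <- dc_for(lo)
  fhi <- dc_for(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
    stop("injury-profile calibration failed for load ", load_case,
         call. = FALSE)
  }
  peak_c <- stats::uniroot(dc_for, c(lo, hi), tol = 1e-9)$root
  width_c <- width_for(peak_c)
  # refine the tensile peak against the overlap with the compression field,
  # then the compression pair, until the coupling has converged
  for (it in 1:4) {
    peak_t <- stats::uniroot(f_coll, c(0.01, 3), tol = 1e-9, extendInt = "upX",
                             pc = peak_c, wc = width_c)$root
    peak_c <- stats::uniroot(dc_for, c(lo, hi), tol = 1e-9)$root
    width_c <- width_for(peak_c)
  }

  delta <- fixture_delta(grid$theta, grid$rhat, peak_t, width_t, peak_c, width_c)
  b_lum <- abs(fixture_delta(th_lum, 0, peak_t, width_t, peak_c, width_c))
  list(peak_t = peak_t, width_t = width_t, peak_c = peak_c, width_c = width_c,
       phi_ec = endothelium_damage(b_lum, m_ec),
       d_csmc = mean(smc_damage(abs(delta), params$damage$m_csmc)),
       d_coll = .mean_d_coll(delta, params, zeta_hom))
}

#' Write an injury profile to CSV
#'
#' Evaluates the signed injury field on the configured material-point grid and
#' writes a `point, theta, rhat, delta, beta` table, the exchange format
#' accepted by [apply_clamp()].
#'
#' @param path output CSV path.
#' @param params `vh_params` list.
#' @param profile list with `peak_t`, `width_t`, `peak_c`, `width_c` as from
#'   [calibrate_clamp_profile()].
#' @return the data frame, invisibly.
#' @export
write_beta_profile <- function(path, params, profile) {
  grid <- .vessel_grid(params$geometry)
  delta <- fixture_delta(grid$theta, grid$rhat, profile$peak_t,
                         profile$width_t, profile$peak_c, profile$width_c)
  df <- data.frame(point = seq_len(nrow(grid)), theta = grid$theta,
                   rhat = grid$rhat, delta = delta, beta = abs(delta))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
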