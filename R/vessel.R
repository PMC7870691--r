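## Reduced thin-walled vessel: homeostatic prestress, clamp damage
## application, daily healing driver, excision and virtual wire myograph.
##
## The vessel is a half cylinder of material points sharing one diagonal
## deformation (uniform membrane kinematics); points differ in their injury
## and hence in densities and cohort masses. Because stress is linear in the
## densities at shared kinematics, global equilibrium uses the point-mean
## state. Pressurized steps are axially plane-strain (lam_z = 1), matching a
## short fixed-end segment; excision releases both pressure and the axial
## constraint.

.vessel_grid <- function(g) {
  th <- (seq_len(g$n_theta) - 0.5) / g$n_theta * pi
  rh <- if (g$n_r == 1) 0 else (seq_len(g$n_r) - 1) / (g$n_r - 1)
  expand.grid(theta = th, rhat = rh)
}

.lumen_theta <- function(g) (seq_len(g$n_theta_lumen) - 0.5) / g$n_theta_lumen * pi

## point-mean state: densities and cohort mass*q vector
.mean_state <- function(v) {
  list(rho_elas = mean(v$state$rho_elas),
       rho_csmc = mean(v$state$rho_csmc),
       rho_ssmc = mean(v$state$rho_ssmc),
       mq = colMeans(v$state$Mmass) * v$state$cohorts$q)
}

## mixture stress components (tt - rr, zz - rr) at shared kinematics for an
## aggregate state; n, u are the crossbridge state and sliding actually used.
.sigma_mix <- function(v, lam_t, lam_z, ms, n, u) {
  p <- v$params
  F3 <- stretch3(lam_t, lam_z)
  Fe <- F3 * v$dep$G_elas
  s <- ms$rho_elas * 2 * p$passive$C10 * Fe^2
  a2 <- .cohort_a2(v$state$cohorts, c(lam_t, lam_z))
  ev <- .coll_eval(a2, v$dep$families[[1]], p$passive)
  s <- s + drop(ms$mq %*% ev$sig)
  I4 <- F3[2]^2
  s[2] <- s[2] + ms$rho_csmc * 2 * p$smc$mu_csmc * (n[3] + n[4]) *
    (I4 + u - 1) * I4
  c(tt = s[2] - s[1], zz = s[3] - s[1])
}

## circumferential stress for the in vivo (pressurized) steps: the filament
## sliding stays at its stored value unless the latch is allowed to engage
## in vivo
.sigma_tt <- function(v, lam_t, lam_z = 1, ms = .mean_state(v)) {
  u <- if (v$params$numerics$latch_tone_in_vivo) {
    sliding_steady(v$u_rs, lam_t^2, v$n_hom, v$params)
  } else {
    v$u_rs
  }
  .sigma_mix(v, lam_t, lam_z, ms, v$n_hom, u)[["tt"]]
}

#' Homeostatic prestress solve
#'
#' Builds the reduced vessel at its diastolic reference configuration and
#' finds the elastin circumferential deposition stretch such that the mixture
#' circumferential Cauchy stress balances the thin-wall Laplace stress
#' `p * r / h`. By default the smooth muscle filaments sit at their deposition
#' state in vivo and contribute no net tone to this balance; with
#' `numerics$latch_tone_in_vivo = TRUE` the latch engages in vivo and its
#' steady basal tone enters the prestress solve. The collagen deposition stretch and the axial elastin
#' deposition stretch are fixed prior knowledge. The returned state is
#' mechanobiologically homeostatic by construction: the stretch deviation and
#' all fiber-stress deviations are zero, so remodeling leaves it stationary.
#'
#' @param params `vh_params` list, see [default_params()].
#' @return object of class `vessel_model`.
#' @export
solve_homeostasis <- function(params) {
  params <- validate_params(params)
  g <- params$geometry
  r0 <- g$inner_diameter / 2
  h0 <- g$thickness
  lap <- g$pressure * r0 / h0

  # basal crossbridge state (no agents, intact endothelium); by default the
  # filaments sit at their deposition state in vivo (u = 0, no net tone), so
  # the prestress balance is passive
  env <- chem_env(0, 0, 0, 1, params)
  n_hom <- hai_murphy_steady(env$rates)
  u_hom <- if (params$numerics$latch_tone_in_vivo) {
    sliding_steady(0, 1, n_hom, params)
  } else 0
  act <- 2 * params$smc$mu_csmc * (n_hom[3] + n_hom[4]) * u_hom *
    params$densities$rho0_csmc

  resid <- function(gc) {
    dep <- deposition_stretches(params, gc)
    Fe <- dep$G_elas
    s_el <- params$densities$rho0_elas * 2 * params$passive$C10 *
      (Fe[2]^2 - Fe[1]^2)
    a2 <- matrix(1, 1, 3)
    ev <- .coll_eval(a2, dep$families[[1]], params$passive)
    s_co <- params$densities$rho0_coll * (ev$sig[1, 2] - ev$sig[1, 1])
    s_el + s_co + act - lap
  }
  br <- params$numerics$g_elas_bracket
  if (resid(br[1]) * resid(br[2]) > 0) {
    stop("homeostatic prestress: no elastin deposition stretch in [",
         br[1], ", ", br[2], "] balances the Laplace stress", call. = FALSE)
  }
  gc <- stats::uniroot(resid, br, tol = params$numerics$tol_equil)$root
  dep <- deposition_stretches(params, gc)

  zeta_hom <- collagen_fiber_stress(c(1, 1, 1), c(1, 1, 1),
                                    dep$families[[1]]$M, params)
  grid <- .vessel_grid(g)
  npt <- nrow(grid)
  v <- list(
    params = params, dep = dep,
    geom = list(r0 = r0, h0 = h0, pressure = g$pressure),
    grid = grid,
    state = list(
      rho_elas = rep(params$densities$rho0_elas, npt),
      rho_csmc = rep(params$densities$rho0_csmc, npt),
      rho_ssmc = rep(params$densities$rho0_ssmc, npt),
      cohorts = data.frame(tau = 0, lam_t_dep = 1, lam_z_dep = 1, q = 1),
      Mmass = matrix(params$densities$rho0_coll, npt, 1),
      beta = rep(0, npt)
    ),
    lam = c(t = 1, z = 1),
    u_rs = u_hom, n_hom = n_hom, zeta_hom = zeta_hom,
    phi_ec = 1, phi_ic = 0,
    day = 0, excised = FALSE,
    history = NULL
  )
  class(v) <- c("vessel_model", "list")
  v$history <- .history_row(v, dlambda = 0)
  # consistency check: the reference configuration must be in equilibrium
  res <- .equil_residual(v, 1)
  if (abs(res) > 1e-8) {
    stop("homeostatic equilibrium residual ", format(res), " MPa", call. = FALSE)
  }
  v
}

.equil_residual <- function(v, lam_t, ms = .mean_state(v)) {
  .sigma_tt(v, lam_t, 1, ms) -
    v$geom$pressure * v$geom$r0 * lam_t^2 / v$geom$h0
}

## pressurized equilibrium: circumferential stretch balancing Laplace
.solve_equilibrium <- function(v) {
  ms <- .mean_state(v)
  f <- function(l) .equil_residual(v, l, ms)
  sol <- tryCatch(
    stats::uniroot(f, c(0.55, 1.8), extendInt = "upX",
                   tol = v$params$numerics$tol_equil),
    error = function(e) {
      stop("equilibrium solve failed at day ", v$day, ": ",
           conditionMessage(e), call. = FALSE)
    })
  sol$root
}

#' Equilibrium circumferential stretch under a given pressure
#'
#' Solves the pressurized membrane balance (mean wall stress against the
#' Laplace stress at the deformed radius and thickness) for the vessel's
#' current constituent state.
#'
#' @param v `vessel_model`.
#' @param pressure intraluminal pressure (MPa); defaults to the vessel's
#'   current pressure.
#' @return circumferential stretch vs the homeostatic reference.
#' @export
equilibrium_stretch <- function(v, pressure = v$geom$pressure) {
  v$geom$pressure <- pressure
  .solve_equilibrium(v)
}

.history_row <- function(v, dlambda) {
  d <- v$params$densities
  data.frame(
    day = v$day,
    elastin = mean(v$state$rho_elas) / d$rho0_elas,
    collagen = sum(colMeans(v$state$Mmass) * v$state$cohorts$q) / d$rho0_coll,
    csmc = mean(v$state$rho_csmc) / d$rho0_csmc,
    ssmc = mean(v$state$rho_ssmc) / d$rho0_ssmc,
    endothelium = v$phi_ec,
    inflammation = v$phi_ic,
    dlambda = dlambda,
    lam_t = unname(v$lam["t"])
  )
}

#' Relative constituent content of a vessel state
#'
#' @param v `vessel_model`.
#' @return named vector: elastin, collagen, contractile SMC, synthetic SMC
#'   (grid means relative to their homeostatic densities), endothelium
#'   survival and inflammation level.
#' @export
constituent_fractions <- function(v) {
  d <- v$params$densities
  c(elastin = mean(v$state$rho_elas) / d$rho0_elas,
    collagen = sum(colMeans(v$state$Mmass) * v$state$cohorts$q) / d$rho0_coll,
    csmc = mean(v$state$rho_csmc) / d$rho0_csmc,
    ssmc = mean(v$state$rho_ssmc) / d$rho0_ssmc,
    endothelium = v$phi_ec,
    inflammation = v$phi_ic)
}

#' Apply acute clamp damage
#'
#' Imposes a signed circumferential stretch-deviation field on the material
#' points — either the calibrated parametric profile for the requested clamp
#' load or a user-supplied profile — and converts it once into constituent
#' loss: contractile SMCs die by `1 - exp(-beta/m_csmc)` with
#' `beta = |lambda_tt - 1|` (removed, not converted), collagen cohorts lose
#' the damage fraction implied by the acute fiber-overstress at the per-point
#' clamp stretch (tensile zones only; compression does not destroy collagen),
#' and the global endothelial survival is the fraction of luminal points with
#' beta below the death threshold. A 0.0 N load leaves the state untouched.
#' Damage is frozen afterwards (plate removal does not add injury).
#'
#' @param v `vessel_model` in the homeostatic state.
#' @param load_case clamp load in N per 2 mm clamp length: 0.0, 0.6 or 1.27.
#' @param profile optional injury profile: either a list with `peak_t`,
#'   `width_t`, `peak_c`, `width_c` (see [fixture_delta()]), or a data frame /
#'   CSV path with columns `theta`, `rhat` and `delta` (signed) or `beta`
#'   (treated as tensile) matching the model grid.
#' @return updated `vessel_model`.
#' @export
apply_clamp <- function(v, load_case, profile = NULL) {
  stopifnot(inherits(v, "vessel_model"))
  if (load_case == 0) return(v)
  p <- v$params
  if (is.null(profile)) {
    profile <- calibrate_clamp_profile(p, load_case)
  }
  if (is.character(profile)) profile <- utils::read.csv(profile)
  if (is.data.frame(profile)) {
    if (nrow(profile) != nrow(v$grid)) {
      stop("injury profile has ", nrow(profile), " points; grid has ",
           nrow(v$grid), call. = FALSE)
    }
    delta <- if (!is.null(profile$delta)) profile$delta else profile$beta
    # luminal field approximated by the profile's innermost ring
    delta_lum <- delta[profile$rhat == min(profile$rhat)]
  } else {
    delta <- fixture_delta(v$grid$theta, v$grid$rhat, profile$peak_t,
                           profile$width_t, profile$peak_c, profile$width_c)
    delta_lum <- fixture_delta(.lumen_theta(p$geometry), 0, profile$peak_t,
                               profile$width_t, profile$peak_c,
                               profile$width_c)
  }

  v$state$beta <- update_beta(v$state$beta, 1 + delta)
  d_csmc <- smc_damage(v$state$beta, p$damage$m_csmc)
  v$state$rho_csmc <- p$densities$rho0_csmc * (1 - d_csmc)

  # acute fiber overstress at the per-point clamp stretch (tensile zones only)
  d_coll <- .d_coll_field(delta, p, v$zeta_hom)
  v$state$Mmass <- v$state$Mmass * (1 - d_coll)

  beta_lum <- abs(delta_lum)

  v$phi_ec <- endothelium_damage(beta_lum, p$damage$m_ec)
  v$phi_ic <- inflammation(v$phi_ec)
  v$history <- rbind(v$history, .history_row(v, dlambda = 0))
  v
}

#' One daily remodeling step
#'
#' Per step of length `dt_day`: solve the pressurized membrane equilibrium
#' (radial-only kinematics) for the circumferential stretch; evaluate the
#' stretch deviation and the per-cohort fiber-stress deviations; decay all
#' cohort survival fractions; deposit one new cohort per fiber family at the
#' current deformation; switch SMC phenotypes; heal the endothelium and update
#' inflammation. Elastin is never produced or degraded.
#'
#' @param v `vessel_model` (post-clamp or homeostatic).
#' @return updated `vessel_model` with one more history row.
#' @export
remodeling_step <- function(v) {
  p <- v$params
  dt <- p$remodeling$dt_day

  lam_t <- .solve_equilibrium(v)
  if (p$numerics$latch_tone_in_vivo) {
    v$u_rs <- sliding_steady(v$u_rs, lam_t^2, v$n_hom, p)
  }
  v$lam <- c(t = lam_t, z = 1)
  dl <- lam_t - 1

  a2 <- .cohort_a2(v$state$cohorts, v$lam)
  zeta <- .coll_eval(a2, v$dep$families[[1]], p$passive)$zeta
  dz <- delta_zeta(zeta, v$zeta_hom)
  v$state$cohorts$q <- cohort_survival_step(v$state$cohorts$q, dz, p)

  m_new <- collagen_production(v$state$rho_csmc, v$state$rho_ssmc, dl, p) * dt
  v$state$cohorts <- rbind(v$state$cohorts,
                           data.frame(tau = v$day + dt, lam_t_dep = lam_t,
                                      lam_z_dep = 1, q = 1))
  v$state$Mmass <- cbind(v$state$Mmass, m_new)

  ph <- smc_phenotype_step(v$state$rho_csmc, v$state$rho_ssmc, dl, v$phi_ic,
                           v$state$rho_elas / p$densities$rho0_elas, p)
  v$state$rho_csmc <- ph$rho_csmc
  v$state$rho_ssmc <- ph$rho_ssmc

  v$phi_ec <- endothelium_heal_step(v$phi_ec, p)
  v$phi_ic <- inflammation(v$phi_ec)

  keep <- colMeans(v$state$Mmass) * v$state$cohorts$q >
    p$numerics$prune_tol | seq_along(v$state$cohorts$q) == nrow(v$state$cohorts)
  v$state$cohorts <- v$state$cohorts[keep, , drop = FALSE]
  v$state$Mmass <- v$state$Mmass[, keep, drop = FALSE]

  v$day <- v$day + dt
  v$history <- rbind(v$history, .history_row(v, dlambda = dl))
  v
}

#' Run a healing period
#'
#' Repeats [remodeling_step()] for `days / dt_day` steps at constant pressure.
#'
#' @param v `vessel_model`.
#' @param days healing duration (days), e.g. 31 or 91.
#' @return updated `vessel_model`; the daily time series accumulates in
#'   `v$history` (class `healing_history`).
#' @export
heal <- function(v, days) {
  n <- round(days / v$params$remodeling$dt_day)
  for (i in seq_len(n)) v <- remodeling_step(v)
  class(v$history) <- c("healing_history", "data.frame")
  v
}

#' Excise the vessel
#'
#' Releases the intraluminal pressure and the axial constraint and finds the
#' unloaded configuration: in-plane and axial stretches such that both the
#' circumferential and the axial mean Cauchy stresses vanish (thin ring,
#' traction-free). The axial recoil follows from the zero-axial-force
#' condition against the axial deposition prestretch.
#'
#' @param v `vessel_model`.
#' @return updated `vessel_model` with `excised = TRUE` and `lam` at the
#'   unloaded state.
#' @export
excise <- function(v) {
  if (v$excised) return(v)
  ms <- .mean_state(v)
  p <- v$params
  nb <- v$n_hom
  # ex vivo the ring equilibrates over minutes, so the latch engages: the
  # sliding relaxes to its steady state at every trial stretch
  lam_z_free <- function(lt, u) {
    f <- function(lz) .sigma_mix(v, lt, lz, ms, nb, u)[["zz"]]
    stats::uniroot(f, c(0.25, 1.6), extendInt = "upX",
                   tol = p$numerics$tol_equil)$root
  }
  f_t <- function(lt) {
    u <- sliding_steady(v$u_rs, lt^2, v$n_hom, p)
    lz <- lam_z_free(lt, u)
    .sigma_mix(v, lt, lz, ms, nb, u)[["tt"]]
  }
  lt <- stats::uniroot(f_t, c(0.35, 1.4), extendInt = "upX",
                       tol = p$numerics$tol_equil)$root
  u <- sliding_steady(v$u_rs, lt^2, v$n_hom, p)
  lz <- lam_z_free(lt, u)
  v$u_rs <- u
  v$lam <- c(t = lt, z = lz)
  v$geom$pressure <- 0
  v$excised <- TRUE
  v
}

## wall force per unit axial length on the two rods at a given circumferential
## stretch: two load-bearing wall segments at deformed thickness.
.wall_force <- function(v, lam_t, ms, n, u) {
  lz <- stats::uniroot(
    function(lz) .sigma_mix(v, lam_t, lz, ms, n, u)[["zz"]],
    c(0.25, 1.6), extendInt = "upX", tol = v$params$numerics$tol_equil)$root
  stt <- .sigma_mix(v, lam_t, lz, ms, n, u)[["tt"]]
  h_def <- v$geom$h0 / (lam_t * lz)
  list(force = 2 * stt * h_def, lam_z = lz)
}

#' Virtual wire-myograph experiment
#'
#' Mounts the excised ring on two rigid rods, sweeps the rod gap to record the
#' force-displacement curve (three zones: no contact, low-stiffness
#' straightening modeled with a thin-ring bending-scale stiffness, and wall
#' stretching), pre-loads to the target force per unit length, then holds the
#' gap isometrically while vasoactive doses are applied cumulatively
#' (phenylephrine, then acetylcholine, then applied NO).
#'
#' @param v `vessel_model` (excised; [excise()] is called if needed).
#' @param doses named numeric vector of cumulative bath additions (M), in
#'   order; names among `PE`, `ACh`, `NO`. Defaults to the configured
#'   protocol.
#' @return object of class `myograph_result`: `force_displacement` (gap vs
#'   force per length), `doses` (stage table with isometric forces),
#'   `preload_gap`, `lam_pre` and geometry.
#' @export
myograph <- function(v, doses = NULL) {
  v <- excise(v)
  p <- v$params
  my <- p$myograph
  if (is.null(doses)) {
    doses <- c(PE = my$dose_PE, ACh = my$dose_ACh, NO = my$dose_NO)
  }
  ms <- .mean_state(v)
  nb <- v$n_hom

  r_u <- unname(v$lam["t"]) * v$geom$r0
  if (r_u <= my$rod_radius) stop("rods do not fit the unloaded lumen", call. = FALSE)
  g1 <- 2 * (r_u - my$rod_radius)          # rods touch the slack ring
  g2 <- pi * (r_u - my$rod_radius)         # perimeter taut
  lam_of <- function(g) {
    unname(v$lam["t"] * (2 * g + 2 * pi * my$rod_radius) / (2 * pi * r_u))
  }
  u0 <- v$u_rs
  wall <- function(g, u) {
    lt <- lam_of(g)
    u2 <- sliding_steady(u, lt^2, v$n_hom, p)
    w <- .wall_force(v, lt, ms, nb, u2)
    c(force = w$force, u = u2, lam_z = w$lam_z, lam_t = lt)
  }
  # bending-scale stiffness for the straightening zone
  dg <- 1e-4
  slope0 <- (wall(g2 + 2 * dg, u0)[["force"]] - wall(g2 + dg, u0)[["force"]]) / dg
  k_bend <- (v$geom$h0 / (2 * r_u))^2 * max(slope0, 0)
  f_bend2 <- k_bend * (g2 - g1)
  force_at <- function(g, u) {
    if (g <= g1) return(c(force = 0, u = u))
    if (g <= g2) return(c(force = k_bend * (g - g1), u = u))
    w <- wall(g, u)
    c(force = f_bend2 + w[["force"]], u = w[["u"]])
  }

  # preload solve on the stretching branch
  fpre <- function(g) force_at(g, u0)[["force"]] - my$preload_per_length
  g_pre <- tryCatch(
    stats::uniroot(fpre, c(g2 + 1e-6, g2 * 1.6), extendInt = "upX",
                   tol = 1e-12)$root,
    error = function(e) stop("preload unreachable: ", conditionMessage(e),
                             call. = FALSE))
  gs <- seq(0, max(g2 * 1.35, g_pre * 1.1), length.out = 150)
  fd <- data.frame(gap = gs,
                   force = vapply(gs, function(g) force_at(g, u0)[["force"]],
                                  numeric(1)))
  st <- wall(g_pre, u0)
  lam_pre <- st[["lam_t"]]
  lam_z_pre <- st[["lam_z"]]
  u_pre <- st[["u"]]

  # isometric dosing at fixed gap: cumulative agent additions
  iso_force <- function(n, u) {
    stt <- .sigma_mix(v, lam_pre, lam_z_pre, ms, n, u)[["tt"]]
    f_bend2 + 2 * stt * v$geom$h0 / (lam_pre * lam_z_pre)
  }
  bath <- c(PE = 0, ACh = 0, NO = 0)
  stage <- data.frame(stage = "preload", PE = 0, ACh = 0, NO = 0,
                      force = my$preload_per_length)
  n_cur <- nb
  u_cur <- u_pre
  for (i in seq_along(doses)) {
    agent <- names(doses)[i]
    bath[agent] <- bath[agent] + doses[i]
    env <- chem_env(bath["PE"], bath["ACh"], bath["NO"], v$phi_ec, p)
    n_cur <- hai_murphy_steady(env$rates)
    u_cur <- sliding_steady(u_cur, lam_pre^2, n_cur, p)
    stage <- rbind(stage, data.frame(
      stage = paste0("+", agent), PE = unname(bath["PE"]),
      ACh = unname(bath["ACh"]), NO = unname(bath["NO"]),
      force = iso_force(n_cur, u_cur)))
  }
  out <- list(force_displacement = fd, doses = stage, preload_gap = g_pre,
              lam_pre = lam_pre, lam_z_pre = lam_z_pre,
              zones = c(contact = unname(g1), taut = unname(g2)),
              phi_ec = v$phi_ec)
  class(out) <- c("myograph_result", "list")
  out
}

#' Run one full experimental case
#'
#' Executes the five-step protocol for one of the six case codes: homeostatic
#' prestress, clamping at the case's load, an optional one-month healing
#' period (healed cases), excision and the virtual myograph. Deterministic:
#' the model contains no randomness.
#'
#' @param case_id one of `"A0"`, `"R0"`, `"A1"`, `"R1"`, `"A2"`, `"R2"`
#'   (A = acute, R = after one month of remodeling; 0/1/2 = clamp load 0.0,
#'   0.6, 1.27 N).
#' @param params `vh_params` list.
#' @param healing_days healing duration for the R cases (days).
#' @return object of class `vessel_case`: the final `vessel_model`, the
#'   constituent-fraction summary, the healing time series (if any) and the
#'   myograph result.
#' @export
run_case <- function(case_id, params = default_params(), healing_days = 31) {
  case_id <- match.arg(case_id, c("A0", "R0", "A1", "R1", "A2", "R2"))
  load <- c("0" = 0, "1" = 0.6, "2" = 1.27)[[substr(case_id, 2, 2)]]
  healed <- substr(case_id, 1, 1) == "R"

  v <- solve_homeostasis(params)
  v <- apply_clamp(v, load)
  if (healed) v <- heal(v, healing_days)
  fr <- constituent_fractions(v)
  my <- myograph(excise(v))

  out <- list(case_id = case_id, load_case = load, healed = healed,
              healing_days = if (healed) healing_days else 0,
              fractions = fr,
              history = v$history,
              myograph = my,
              vessel = v,
              config_hash = params_hash(params))
  class(out) <- c("vessel_case", "list")
  out
}

#' @method print vessel_model
#' @export
print.vessel_model <- function(x, ...) {
  cat("<vessel_model> reduced thin-walled vessel\n")
  cat(sprintf("  day %.1f | lam_t %.4f lam_z %.4f | %s | pressure %g MPa\n",
              x$day, x$lam["t"], x$lam["z"],
              if (x$excised) "excised" else "in vivo", x$geom$pressure))
  fr <- constituent_fractions(x)
  cat("  relative content:\n")
  print(round(fr, 4))
  invisible(x)
}

#' @method print vessel_case
#' @export
print.vessel_case <- function(x, ...) {
  cat(sprintf("<vessel_case> %s (clamp %.2f N%s)\n", x$case_id, x$load_case,
              if (x$healed) sprintf(", %d days healed", x$healing_days) else ""))
  print(round(x$fractions, 4))
  d <- x$myograph$doses
  cat("  myograph isometric force (N/mm):\n")
  for (i in seq_len(nrow(d))) {
    cat(sprintf("    %-8s %.5f\n", d$stage[i], d$force[i]))
  }
  invisible(x)
}

#' @method summary vessel_case
#' @export
summary.vessel_case <- function(object, ...) {
  list(case = object$case_id, fractions = object$fractions,
       doses = object$myograph$doses, config_hash = object$config_hash)
}

#' @method plot healing_history
#' @export
plot.healing_history <- function(x, ...) {
  graphics::matplot(x$day, cbind(x$elastin, x$collagen, x$csmc, x$ssmc),
                    type = "l", lty = 1, lwd = 2,
                    col = c("grey40", "firebrick", "steelblue", "darkorange"),
                    xlab = "healing time (days)", ylab = "relative content", ...)
  graphics::lines(x$day, x$endothelium, lty = 2)
  graphics::legend("topleft",
                   c("elastin", "collagen", "cSMC", "sSMC", "endothelium"),
                   lty = c(1, 1, 1, 1, 2), lwd = c(2, 2, 2, 2, 1),
                   col = c("grey40", "firebrick", "steelblue", "darkorange", 1),
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' @method plot myograph_result
#' @export
plot.myograph_result <- function(x, ...) {
  graphics::plot(x$force_displacement$gap, x$force_displacement$force,
                 type = "l", lwd = 2, xlab = "rod gap (mm)",
                 ylab = "force per length (N/mm)", ...)
  graphics::abline(v = x$zones, lty = 3, col = "grey50")
  invisible(x)
}
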