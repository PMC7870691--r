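test_that("homeostatic prestress balances the Laplace stress", {
  p <- fast_params()
  v <- solve_homeostasis(p)
  # target from the printed geometry: 0.01 * 0.325 / 0.04 MPa
  lap <- 0.01 * 0.325 / 0.04
  expect_equal(lap, 0.08125)
  # cross-module check through the exported single-point stress
  st <- mixture_state(p)
  fil <- list(n = v$n_hom, u_rs = v$u_rs)
  sig <- cauchy_stress(st, fil, v$dep, p)
  expect_equal(sig[2], lap, tolerance = 1e-8)
  expect_lt(abs(vesselheal:::.equil_residual(v, 1)), 1e-10)
  # all deviations vanish at the reference
  expect_equal(unname(v$lam), c(1, 1))
  expect_equal(v$phi_ec, 1)
})

test_that("homeostasis is a fixed point of the healing loop", {
  p <- fast_params()
  v <- heal(solve_homeostasis(p), 31)
  h <- v$history
  for (col in c("elastin", "collagen", "csmc", "ssmc", "endothelium")) {
    expect_lt(max(abs(h[[col]] - 1)), 1e-9)
  }
  expect_lt(max(abs(h$dlambda)), 1e-9)
})

test_that("equilibrium radius grows monotonically with pressure", {
  p <- fast_params()
  v <- solve_homeostasis(p)
  lams <- vapply(seq(0, 0.02, by = 0.0025),
                 function(pr) equilibrium_stretch(v, pr), numeric(1))
  expect_true(all(diff(lams) > 0))
  expect_equal(lams[5], 1, tolerance = 1e-9)  # 10 kPa is the reference
})

test_that("a zero clamp load leaves the vessel bitwise untouched", {
  p <- fast_params()
  v <- solve_homeostasis(p)
  expect_identical(apply_clamp(v, 0), v)
})

test_that("clamping converts the calibrated injury into density loss", {
  p <- fast_params()
  v <- apply_clamp(solve_homeostasis(p), 0.6)
  fr <- constituent_fractions(v)
  expect_equal(unname(fr["elastin"]), 1)
  expect_equal(unname(fr["ssmc"]), 1)     # acute damage removes, not converts
  expect_equal(unname(fr["csmc"]), 0.7170, tolerance = 2e-3)
  expect_equal(unname(fr["collagen"]), 0.9076, tolerance = 5e-3)
  expect_equal(unname(fr["endothelium"]), 0.3113, tolerance = 5e-3)
  expect_equal(unname(fr["inflammation"]), 1 - fr[["endothelium"]])
  # both clamp loads injure similarly
  v2 <- apply_clamp(solve_homeostasis(p), 1.27)
  fr2 <- constituent_fractions(v2)
  expect_lt(abs(fr2[["csmc"]] - fr[["csmc"]]), 0.02)
})

test_that("healing trajectories dip, overshoot and recover", {
  p <- fast_params()
  v <- heal(apply_clamp(solve_homeostasis(p), 1.27), 31)
  h <- v$history
  hh <- h[h$day >= 1, ]
  # elastin is never produced or degraded
  expect_true(all(h$elastin == 1))
  # contractile SMCs dip below the acute level, then partially recover
  acute <- h$csmc[2]
  expect_lt(min(hh$csmc), acute - 0.02)
  expect_gt(h$csmc[nrow(h)], min(hh$csmc))
  # synthetic SMCs overshoot and come back down
  expect_gt(max(hh$ssmc), 1.5)
  expect_lt(hh$ssmc[nrow(hh)], max(hh$ssmc))
  # collagen recovers beyond its damaged level
  expect_gt(h$collagen[nrow(h)], h$collagen[2])
  # endothelium heals to the published one-month fraction
  expect_equal(h$endothelium[nrow(h)], 0.8184, tolerance = 2e-3)
  # inflammation stays complementary throughout
  expect_equal(h$inflammation + h$endothelium, rep(1, nrow(h)))
})

test_that("user-supplied injury profiles are accepted and validated", {
  p <- fast_params()
  v <- solve_homeostasis(p)
  prof <- calibrate_clamp_profile(p, 0.6)
  csv <- tempfile(fileext = ".csv")
  df <- write_beta_profile(csv, p, prof)
  expect_equal(nrow(df), p$geometry$n_theta * p$geometry$n_r)
  v1 <- apply_clamp(v, 0.6, profile = prof)
  v2 <- apply_clamp(v, 0.6, profile = csv)
  expect_equal(v2$state$rho_csmc, v1$state$rho_csmc, tolerance = 1e-12)
  expect_equal(v2$state$Mmass, v1$state$Mmass, tolerance = 1e-12)
  # grid mismatch is an error
  bad <- df[-1, ]
  expect_error(apply_clamp(v, 0.6, profile = bad), "grid")
})

test_that("excision unloads the ring", {
  p <- fast_params()
  v <- excise(solve_homeostasis(p))
  expect_true(v$excised)
  expect_equal(v$geom$pressure, 0)
  # both in-plane and axial mean stresses vanish at the unloaded stretch
  ms <- vesselheal:::.mean_state(v)
  u <- sliding_steady(v$u_rs, unname(v$lam["t"])^2, v$n_hom, p)
  s <- vesselheal:::.sigma_mix(v, unname(v$lam["t"]), unname(v$lam["z"]), ms,
                               v$n_hom, u)
  expect_lt(abs(s[["tt"]]), 1e-9)
  expect_lt(abs(s[["zz"]]), 1e-9)
})

test_that("the myograph force-displacement curve has three zones", {
  p <- fast_params()
  my <- myograph(solve_homeostasis(p))
  fd <- my$force_displacement
  z1 <- fd$force[fd$gap <= my$zones["contact"]]
  expect_true(all(z1 == 0))
  mid <- fd$gap > my$zones["contact"] & fd$gap <= my$zones["taut"]
  out <- fd$gap > my$zones["taut"] & fd$force > 0
  slope_mid <- diff(range(fd$force[mid])) / diff(range(fd$gap[mid]))
  hi <- fd[fd$gap >= my$preload_gap, ]
  slope_out <- (hi$force[nrow(hi)] - hi$force[1]) /
    (hi$gap[nrow(hi)] - hi$gap[1])
  expect_gt(slope_mid, 0)
  expect_gt(slope_out, 10 * slope_mid)  # stretching much stiffer than straightening
  # preload reached on the stretching branch
  expect_gt(my$preload_gap, my$zones["taut"])
})

test_that("isometric dosing shows the constrict-then-dilate signature", {
  p <- fast_params()
  v <- solve_homeostasis(p)
  d <- myograph(v)$doses
  expect_equal(d$force[d$stage == "preload"], p$myograph$preload_per_length)
  f <- d$force
  expect_gt(f[2], f[1])  # PE constricts
  expect_lt(f[3], f[2])  # ACh relaxes
  expect_lt(f[4], f[3])  # NO relaxes further
})

test_that("acute cases respond less to ACh than healed cases", {
  p <- fast_params()
  v <- solve_homeostasis(p)
  va <- apply_clamp(v, 0.6)             # endothelium 0.31
  vr <- heal(va, 31)                    # endothelium 0.85
  da <- myograph(va)$doses
  dr <- myograph(vr)$doses
  drop_a <- da$force[da$stage == "+PE"] - da$force[da$stage == "+ACh"]
  drop_r <- dr$force[dr$stage == "+PE"] - dr$force[dr$stage == "+ACh"]
  expect_gt(drop_a, 0)
  expect_gt(drop_r, drop_a)
  # PE response is positive in every case
  expect_gt(da$force[2] - da$force[1], 0)
  expect_gt(dr$force[2] - dr$force[1], 0)
})

test_that("case runs are deterministic and the control cases coincide", {
  p <- fast_params()
  a0 <- run_case("A0", p)
  r0 <- run_case("R0", p)
  # no randomness anywhere: a rerun bit-reproduces the case
  a0b <- run_case("A0", p)
  expect_identical(a0$fractions, a0b$fractions)
  expect_identical(a0$myograph$doses$force, a0b$myograph$doses$force)
  # an unclamped month of remodeling changes nothing measurable
  expect_equal(r0$fractions, a0$fractions, tolerance = 1e-9)
  expect_equal(r0$myograph$doses$force, a0$myograph$doses$force,
               tolerance = 1e-6)
  expect_equal(unname(a0$fractions), rep(c(1, 0), c(5, 1)))
})

test_that("the two clamp loads give nearly identical myograph curves", {
  p <- fast_params()
  a1 <- run_case("A1", p)
  a2 <- run_case("A2", p)
  f1 <- a1$myograph$force_displacement$force
  f2 <- a2$myograph$force_displacement$force
  scale <- max(f1)
  expect_lt(max(abs(f1 - f2)) / scale, 0.01)
})
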