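# Shared fixtures for the analytic steady-state tests
fx_chemo <- fixture_chemotaxis()
chi0 <- sensitivity_chi(fx_chemo$receptor, fx_chemo$motor)

test_that("general solver equals the chemotaxis closed form pointwise", {
  p_gen <- steady_state_density(fx_chemo$env, fx_chemo$receptor, fx_chemo$motor)
  p_cf <- chemotaxis_closed_form(fx_chemo$env, chi0, fx_chemo$receptor)
  expect_lt(max(abs(p_gen$density - p_cf$density) / p_cf$density), 1e-8)
})

test_that("sensitivity factors scale as the signalling architecture dictates", {
  rp <- fx_chemo$receptor; mp <- fx_chemo$motor
  # proportional to receptor cooperativity
  rp2 <- receptor_params(N = 12)
  expect_equal(sensitivity_chi(rp2, mp)$chi, 2 * chi0$chi, tolerance = 1e-12)
  # dampened to zero by strong rotational diffusion
  expect_lt(sensitivity_chi(rp, motor_params(D_r = 1e6))$chi, 1e-4 * chi0$chi)
  # receptors lose gain at saturated activity
  rp3 <- receptor_params(a0_ref = 0.999)
  expect_lt(sensitivity_chi(rp3, mp)$receptor_gain, 0.01 * chi0$receptor_gain)
})

test_that("uniform environments give uniform distributions", {
  env <- make_linear_gradient("ligand", 0.5, 0.5, 0, 400)
  prof <- steady_state_density(env, fx_chemo$receptor, fx_chemo$motor)
  expect_lt(diff(range(prof$density)) / mean(prof$density), 1e-12)
  # and zero drift everywhere
  expect_equal(max(abs(activity_difference(env$grid, env, fx_chemo$receptor,
                                           fx_chemo$motor))), 0)
})

test_that("without receptor gain the density is exactly inverse speed", {
  rp0 <- receptor_params(dalpha_dT = 0, da0_dT = 0)
  sp <- speed_profile("linear_in_T", v0 = 20, dv_dT = 0.5, T_ref = 25)
  env <- make_linear_gradient("temperature", 20, 30, 0, 500, speed = sp)
  prof <- steady_state_density(env, rp0, fx_chemo$motor)
  v <- speed(sp, T = prof$temperature)
  ref <- (1 / v) / trapz_(prof$x, 1 / v)
  expect_lt(max(abs(prof$density - ref) / ref), 1e-12)
})

test_that("activity difference makes up-gradient runs longer", {
  x <- seq(50, 350, by = 50)
  da <- activity_difference(x, fx_chemo$env, fx_chemo$receptor, fx_chemo$motor)
  dz <- tumbling_rate_difference(x, fx_chemo$env, fx_chemo$receptor,
                                 fx_chemo$motor)
  # attractant increases to the right: right-movers are less active
  expect_true(all(da < 0))
  expect_true(all(sign(dz) == sign(da)))
})

test_that("weak-ligand chemotaxis linearizes to an exponential profile", {
  rp <- fx_chemo$receptor
  env <- make_linear_gradient("ligand", 0, 0.05, 0, 400)  # L << KI
  prof <- chemotaxis_closed_form(env, 3, rp)
  L <- prof$ligand
  lin <- exp(3 * L * (1 / rp$KI - 1 / rp$KA))
  lin <- lin / trapz_(prof$x, lin)
  expect_lt(max(abs(prof$density - lin) / lin), 1e-4)
})

test_that("fit_chi inverts the closed form and flags degenerate kernels", {
  prof <- chemotaxis_closed_form(fx_chemo$env, 2, fx_chemo$receptor)
  fit <- fit_chi(prof, fx_chemo$env, fx_chemo$receptor)
  expect_equal(fit$chi, 2, tolerance = 1e-6)
  env_flat <- make_linear_gradient("ligand", 1, 1, 0, 400)
  prof_flat <- steady_state_density(env_flat, fx_chemo$receptor,
                                    fx_chemo$motor)
  expect_error(fit_chi(prof_flat, env_flat, fx_chemo$receptor), "degenerate")
})

test_that("the ideal closed form is scale-free: fit_chi is exact at any
          steepness", {
  # with perfect adaptation the analytic log-density is exactly linear in
  # the saturating kernel, so the fitted sensitivity cannot depend on the
  # gradient (the steepness-dependent decline seen in chambers is a
  # finite-cell / boundary effect, exercised in the simulator tests)
  chis <- vapply(c(0.00125, 0.005, 0.02), function(slope) {
    env <- make_linear_gradient("ligand", 0, slope * 400, 0, 400)
    prof <- steady_state_density(env, fx_chemo$receptor, fx_chemo$motor)
    fit_chi(prof, env, fx_chemo$receptor)$chi
  }, numeric(1))
  expect_equal(chis, rep(chi0$chi, 3), tolerance = 1e-6)
})

test_that("effective potential marks accumulation structure", {
  env_flat <- make_linear_gradient("ligand", 1, 1, 0, 400)
  prof_flat <- steady_state_density(env_flat, fx_chemo$receptor,
                                    fx_chemo$motor)
  expect_equal(max(abs(effective_potential(prof_flat))), 0, tolerance = 1e-10)
  # chemotaxis: monotone decreasing along increasing attractant
  prof <- steady_state_density(fx_chemo$env, fx_chemo$receptor,
                               fx_chemo$motor)
  expect_true(all(diff(effective_potential(prof)) < 0))
  expect_equal(prof$potential, effective_potential(prof))
  # wild-type pH: interior potential well
  fx <- fixture_ph()
  prof_ph <- steady_state_density(fx$env, fx$receptor, fx$motor)
  U <- effective_potential(prof_ph)
  imin <- which.min(U)
  expect_gt(imin, 1)
  expect_lt(imin, length(U))
  # Tar-only and Tsr-only mutants: monotone potentials of opposite slope
  fx_tar <- fixture_ph(f_a = 1); fx_tsr <- fixture_ph(f_a = 0)
  U_tar <- effective_potential(steady_state_density(fx_tar$env,
                                                    fx_tar$receptor, fx_tar$motor))
  U_tsr <- effective_potential(steady_state_density(fx_tsr$env,
                                                    fx_tsr$receptor, fx_tsr$motor))
  expect_true(all(diff(U_tar) > 0))   # increases with pH: accumulate low
  expect_true(all(diff(U_tsr) < 0))   # decreases with pH: accumulate high
})

test_that("preferred point finds the push-pull balance", {
  # mirror-symmetric Tar/Tsr parameters with equal fractions: balance at the
  # mirror point
  ph <- list(pKI_tar = 9, pKA_tar = 8, pKI_tsr = 5, pKA_tsr = 6,
             f_a = 0.5, f_s = 0.5)
  rp <- receptor_params(ph = ph)
  env <- make_linear_gradient("ph", 5.8, 8.2, 0, 800)
  pp <- preferred_point(env, rp, fx_chemo$motor)
  expect_true(pp$interior)
  expect_equal(pp$signal, 7, tolerance = 1e-6)
  # thermotaxis, constant speed and motor threshold: T* = T_c
  fx <- fixture_thermo()
  pp_t <- preferred_point(fx$env, fx$receptor, fx$motor)
  expect_equal(pp_t$signal, critical_temperature(fx$receptor),
               tolerance = 1e-6)
  # speed increasing with temperature drags the preferred point below T_c
  fx_v <- fixture_thermo(speed = speed_profile("linear_in_T", v0 = 20,
                                               dv_dT = 0.4, T_ref = 25))
  pp_v <- preferred_point(fx_v$env, fx_v$receptor, fx_v$motor)
  expect_lt(pp_v$signal, critical_temperature(fx_v$receptor) - 0.1)
  # boundary accumulation reported when the drift never reverses
  fx_tar <- fixture_ph(f_a = 1)
  pp_b <- preferred_point(fx_tar$env, fx_tar$receptor, fx_tar$motor)
  expect_false(pp_b$interior)
  expect_equal(pp_b$x_star, fx_tar$env$x_min)
})

test_that("preferred pH is log-linear in the Tar/Tsr ratio", {
  ratios <- 10^seq(-0.5, 0.5, length.out = 5)
  fx <- fixture_ph()
  tu <- ph_tunability(ratios, fx$env, fx$receptor, fx$motor)
  expect_gt(tu$r_squared, 0.99)
  # odd symmetry for mirror-symmetric dissociation constants: doubling and
  # halving the ratio shift the preferred pH by opposite equal amounts
  ph <- list(pKI_tar = 9, pKA_tar = 8, pKI_tsr = 5, pKA_tsr = 6,
             f_a = 0.5, f_s = 0.5)
  rp <- receptor_params(ph = ph)
  env <- make_linear_gradient("ph", 5.8, 8.2, 0, 800)
  star <- function(r) {
    rp$ph$f_a <- r / (1 + r); rp$ph$f_s <- 1 - rp$ph$f_a
    preferred_point(env, rp, fx$motor)$signal
  }
  expect_equal(star(2) - star(1), -(star(0.5) - star(1)), tolerance = 1e-6)
})

test_that("the three pH regimes span the tunability trichotomy", {
  ratios <- 10^seq(-0.5, 0.5, length.out = 5)
  mp <- motor_params()
  eta <- vapply(c("subdued", "balanced", "tunable"), function(nm) {
    fx <- fixture_ph(regime = nm)
    ph_tunability(ratios, fx$env, fx$receptor, mp)$eta
  }, numeric(1))
  expect_lt(eta[["subdued"]], 0.75)
  expect_equal(eta[["balanced"]], 1, tolerance = 0.15)
  expect_gt(eta[["tunable"]], 1.4)
})

test_that("dispersion measures the width on the signal axis", {
  # uniform density on pH in [6, 8]: sd = 2/sqrt(12)
  x <- seq(0, 800, length.out = 401)
  prof <- new_density_profile_(data.frame(
    x = x, ph = 6 + 2 * x / 800, density = rep(1 / 800, 401)))
  expect_equal(dispersion(prof, "ph"), 2 / sqrt(12), tolerance = 1e-4)
  # near-delta density: dispersion near zero
  d <- exp(-((x - 400) / 2)^2); d <- d / trapz_(x, d)
  prof2 <- new_density_profile_(data.frame(x = x, ph = 6 + 2 * x / 800,
                                           density = d))
  expect_lt(dispersion(prof2, "ph"), 0.01)
  # the balanced (accuracy-optimal) regime is the tightest of the three
  disp <- vapply(c("subdued", "balanced", "tunable"), function(nm) {
    fx <- fixture_ph(regime = nm)
    dispersion(steady_state_density(fx$env, fx$receptor, fx$motor), "ph")
  }, numeric(1))
  expect_lt(disp[["balanced"]], disp[["subdued"]])
  expect_lt(disp[["balanced"]], disp[["tunable"]])
})

test_that("thermotaxis accumulates at T_c and is robust to motor-K drift", {
  fx <- fixture_thermo()
  prof <- thermo_density(fx$env, fx$receptor, fx$motor)
  T_c <- attr(prof, "T_c")
  expect_equal(prof$temperature[which.max(prof$density)], T_c,
               tolerance = diff(prof$temperature[1:2]) + 1e-9)
  # leading-order Gaussian approximation agrees near T_c
  lo <- attr(prof, "leading_order")
  near <- abs(prof$temperature - T_c) < 1
  expect_lt(max(abs(lo$density[near] - prof$density[near]) /
                  prof$density[near]), 0.02)
  # temperature-dependent motor threshold barely moves the distribution
  fx_k <- fixture_thermo(kappa = 0.02)
  prof_k <- thermo_density(fx_k$env, fx_k$receptor, fx_k$motor)
  expect_lt(max(abs(prof_k$density - prof$density)) / max(prof$density), 0.05)
  # speed rising with temperature shifts the peak below T_c
  fx_v <- fixture_thermo(speed = speed_profile("linear_in_T", v0 = 20,
                                               dv_dT = 0.4, T_ref = 25))
  prof_v <- thermo_density(fx_v$env, fx_v$receptor, fx_v$motor)
  expect_lt(prof_v$temperature[which.max(prof_v$density)], T_c)
})

test_that("combined gradients reduce to thermotaxis and shift the peak", {
  # exact reduction at zero ligand
  fx0 <- fixture_combined(grad_L = 0, L_mid = 0)
  fx_t <- fixture_thermo()
  p0 <- combined_density(fx0$env, fx0$receptor, fx0$motor)
  pt <- steady_state_density(fx_t$env, fx_t$receptor, fx_t$motor)
  expect_lt(max(abs(p0$density - pt$density)), 1e-10)
  # uniform attractant background lowers the accumulation temperature
  fx_u <- fixture_combined(grad_L = 0, L_mid = 0.2)
  pu <- combined_density(fx_u$env, fx_u$receptor, fx_u$motor)
  T_c <- critical_temperature(fx_u$receptor)
  expect_lt(pu$temperature[which.max(pu$density)], T_c - 0.5)
  # opposing gradients push the accumulation strictly colder as they steepen
  T_star <- vapply(c(0, 3, 5, 6), function(g) {
    fx <- fixture_combined(grad_L = g, L_mid = 0.2)
    preferred_point(fx$env, fx$receptor, fx$motor)$signal
  }, numeric(1))
  expect_true(all(diff(T_star) < 0))
  expect_true(all(T_star < T_c))
})

test_that("densities are normalized and grid-converged", {
  for (fx in list(fx_chemo, fixture_ph(), fixture_thermo(),
                  fixture_combined())) {
    prof <- steady_state_density(fx$env, fx$receptor, fx$motor)
    expect_true(all(prof$density >= 0))
    expect_equal(trapz_(prof$x, prof$density), 1, tolerance = 1e-8)
  }
  # halving the grid spacing leaves the density unchanged at 1e-6 sup-norm
  g1 <- seq(0, 400, length.out = 513)
  g2 <- seq(0, 400, length.out = 1025)
  p1 <- steady_state_density(fx_chemo$env, fx_chemo$receptor, fx_chemo$motor,
                             grid = g1)
  p2 <- steady_state_density(fx_chemo$env, fx_chemo$receptor, fx_chemo$motor,
                             grid = g2)
  expect_lt(max(abs(p2$density[seq(1, 1025, 2)] - p1$density)) /
              max(p1$density), 1e-6)
})
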