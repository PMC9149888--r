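test_that("single-crystal intensities match the uniaxial closed forms", {
  tns <- raman_tensor(2.5)
  o0 <- euler_orientation(0, 0)
  # c-axis along the canal axis: cross extinguishes, parallel is flat a^2
  expect_equal(single_crystal_intensity(o0, polarization_config("cross"), tns,
                                        c(0, 17, 45, 90)), rep(0, 4))
  expect_equal(single_crystal_intensity(o0, polarization_config("parallel"),
                                        tns, c(0, 33)), rep(1, 2))
  # in-plane c-axis: b^2 when e_i aligns with c, a^2 when normal to it
  o90 <- euler_orientation(90, 0)
  par <- polarization_config("parallel")
  expect_equal(single_crystal_intensity(o90, par, tns, 0), 2.5^2)
  expect_equal(single_crystal_intensity(o90, par, tns, 90), 1)
  # 180-degree periodicity
  rot <- seq(0, 170, 10)
  o <- euler_orientation(35, 28)
  expect_equal(single_crystal_intensity(o, par, tns, rot),
               single_crystal_intensity(o, par, tns, rot + 180))
})

test_that("population curves are non-negative, periodic and lose structure when isotropic", {
  tns <- raman_tensor(2.5)
  o <- euler_orientation(40, 20)
  rot <- seq(0, 350, 10)
  for (geom in c("parallel", "cross")) {
    cfg <- polarization_config(geom)
    cur <- population_intensity(o, list(lambda2 = -5, lambda4 = -3), cfg, tns,
                                rot, normalize = FALSE)
    expect_true(all(cur >= 0))
    expect_equal(cur[1:18], cur[19:36], tolerance = 1e-10)
  }
  iso <- population_intensity(o, list(lambda2 = 0, lambda4 = 0),
                              polarization_config("parallel"), tns, rot,
                              normalize = FALSE)
  expect_lt(diff(range(iso)) / mean(iso), 1e-10)
})

test_that("a near-delta ODF reproduces the single-crystal curve", {
  tns <- raman_tensor(2.5)
  o <- euler_orientation(35, 25)
  rot <- seq(0, 180, 10)
  pop <- population_intensity(o, list(lambda2 = -50, lambda4 = 0),
                              polarization_config("parallel"), tns, rot,
                              normalize = FALSE, n_beta = 128)
  sc <- single_crystal_intensity(o, polarization_config("parallel"), tns, rot)
  expect_lt(max(abs(pop - sc)) / max(sc), 0.01)
})

test_that("quadrature averaging agrees with brute-force Monte-Carlo orientation draws", {
  tns <- raman_tensor(2.5)
  o <- euler_orientation(30, 40)
  odf <- list(lambda2 = -4, lambda4 = -2)
  rot <- seq(0, 180, 20)
  for (geom in c("parallel", "cross")) {
    cfg <- polarization_config(geom)
    qd <- population_intensity(o, odf, cfg, tns, rot, normalize = FALSE)
    mc <- mc_population_intensity(o, odf, cfg, tns, rot, n = 2e5, seed = 5)
    expect_equal(qd, mc, tolerance = 0.01)
  }
})

test_that("noiseless angular series round-trip to the generating parameters", {
  truth_o <- euler_orientation(20.87, 70)
  truth_odf <- odf_params(-7, -8.5)
  tns <- raman_tensor(2.5)
  pair <- make_angular_series(truth_o, truth_odf, tns,
                              angles = seq(0, 180, length.out = 19),
                              noise_sd = 0)
  fit <- fit_angular_series(pair$parallel, pair$cross, b_over_a = 2.5)
  expect_equal(fit$orientation$theta, 20.87, tolerance = 1e-3)
  expect_equal(fit$orientation$psi, 70, tolerance = 1e-3)
  expect_equal(fit$odf$P2, truth_odf$P2, tolerance = 1e-4)
  expect_equal(fit$odf$P4, truth_odf$P4, tolerance = 1e-4)
  expect_false(fit$degenerate)
  expect_lt(fit$residual_rms, 1e-6)
})

test_that("noisy recovery stays inside spectroscopic tolerances for a couple of seeds", {
  truth_o <- euler_orientation(20.87, 70)
  truth_odf <- odf_params(-7, -8.5)
  tns <- raman_tensor(2.5)
  for (seed in c(4, 12)) {
    pair <- make_angular_series(truth_o, truth_odf, tns,
                                angles = seq(0, 180, length.out = 19),
                                noise_sd = 0.02, seed = seed)
    fit <- fit_angular_series(pair$parallel, pair$cross, b_over_a = 2.5)
    expect_lt(abs(fit$orientation$theta - 20.87), 2)
    expect_lt(abs(wrap_delta(fit$orientation$psi - 70)), 3)
    expect_lt(abs(fit$odf$P2 - truth_odf$P2), 0.03)
  }
})

test_that("an isotropic population flags the Euler angles as unidentifiable", {
  tns <- raman_tensor(2.5)
  pair <- make_angular_series(euler_orientation(30, 10), odf_params(0, 0),
                              tns, angles = seq(0, 180, length.out = 19),
                              noise_sd = 0.01, seed = 6)
  fit <- fit_angular_series(pair$parallel, pair$cross, b_over_a = 2.5)
  expect_true(fit$degenerate)
})

test_that("a depth-dependent psi lag is recovered from two-depth series", {
  truth_o <- euler_orientation(20.87, 40)
  truth_odf <- odf_params(-7, -8.5)
  tns <- raman_tensor(2.5)
  ang <- seq(0, 180, length.out = 19)
  surf <- make_angular_series(truth_o, truth_odf, tns, angles = ang,
                              noise_sd = 0.02, seed = 21, z = 0)
  deep <- make_angular_series(truth_o, truth_odf, tns, angles = ang,
                              noise_sd = 0.02, seed = 22, z = 10, psi_lag = 7)
  f0 <- fit_angular_series(surf$parallel, surf$cross, b_over_a = 2.5)
  f1 <- fit_angular_series(deep$parallel, deep$cross, b_over_a = 2.5)
  lag <- wrap_delta(f1$orientation$psi - f0$orientation$psi)
  expect_lt(abs(lag - 7), 3)
})

test_that("series preconditions are enforced", {
  tns <- raman_tensor(2.5)
  pair <- make_angular_series(euler_orientation(20, 0), odf_params(-5, 0),
                              tns, angles = seq(0, 180, 30), noise_sd = 0)
  expect_error(fit_angular_series(pair$parallel, NULL), "required")
  expect_error(fit_angular_series(pair$parallel, pair$parallel),
               "polarization tags")
  expect_error(fit_angular_series(pair$parallel, pair$cross), "8 angles")
  expect_error(angular_series(1:5, rep(0, 5), "parallel"), "positive maximum")
})
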