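test_that("pseudo-Voigt obeys its height and width definitions", {
  for (eta in c(0, 0.5, 1)) {
    b <- sub_band(958, 8, amplitude = 37, eta = eta)
    expect_equal(pseudo_voigt(958, b), 37)
    expect_equal(pseudo_voigt(c(954, 962), b), c(37, 37) / 2, tolerance = 1e-12)
  }
  expect_error(sub_band(958, -1, 1, 0.5), "fwhm")
  expect_error(sub_band(958, 8, 1, 1.2), "eta")
})

test_that("band area matches numerical integration of the profile", {
  b <- sub_band(958, 9, amplitude = 120, eta = 0.3)
  num <- integrate(function(x) pseudo_voigt(x, b), -Inf, Inf)$value
  expect_equal(band_area(b), num, tolerance = 1e-8)
})

test_that("noiseless fits recover bands to optimizer tolerance", {
  truth <- list(sub_band(955, 9, 80, 0.4))
  s <- make_nu1_spectrum(truth, noise_sd = 0)
  fit <- fit_nu1_region(s, init = list(sub_band(953, 12, 60, 0.5)),
                        n_starts = 1)
  expect_lt(fit$residual_rms, 1e-8 * 80)
  expect_equal(fit$bands[[1]]$center, 955, tolerance = 1e-6)
  expect_equal(fit$bands[[1]]$fwhm, 9, tolerance = 1e-5)

  # re-fitting data generated from the returned parameters can do no worse
  s2 <- make_nu1_spectrum(fit$bands, noise_sd = 0)
  fit2 <- fit_nu1_region(s2, init = fit$bands, n_starts = 1)
  expect_lte(fit2$residual_rms, fit$residual_rms + 1e-10)
})

test_that("three-band recovery from noisy spectra hits spectroscopic tolerances", {
  truth <- list(sub_band(948.9, 12, 40, 0.5),
                sub_band(958.0, 10, 100, 0.5),
                sub_band(971.9, 12, 15, 0.5))
  for (seed in c(2, 9)) {
    s <- make_nu1_spectrum(truth, noise_sd = 0.01, seed = seed)
    fit <- fit_nu1_region(s)
    centers <- vapply(fit$bands, `[[`, numeric(1), "center")
    fwhms <- vapply(fit$bands, `[[`, numeric(1), "fwhm")
    # the two stronger components pin down sharply; the weak 971.9
    # shoulder carries proportionally more statistical uncertainty
    expect_lt(max(abs(centers[1:2] - c(948.9, 958.0))), 0.3)
    expect_lt(abs(centers[3] - 971.9), 0.5)
    expect_lt(max(abs(fwhms / c(12, 10, 12) - 1)), 0.1)
  }
})

test_that("amplitude ratios are recovered within 5% on separated two-band spectra", {
  # brute-force oracle: grid search over the two amplitudes at fixed shapes
  b1 <- sub_band(950, 8, 60, 0.5)
  b2 <- sub_band(962, 8, 90, 0.5)
  s <- make_nu1_spectrum(list(b1, b2), noise_sd = 0)
  grid <- expand.grid(a1 = seq(40, 80, 0.5), a2 = seq(70, 110, 0.5))
  sse <- mapply(function(a1, a2) {
    model <- pseudo_voigt(s$wavenumber, sub_band(950, 8, a1, 0.5)) +
      pseudo_voigt(s$wavenumber, sub_band(962, 8, a2, 0.5))
    sum((model - s$intensity)^2)
  }, grid$a1, grid$a2)
  oracle <- grid[which.min(sse), ]
  fit <- fit_nu1_region(s, init = list(sub_band(951, 10, 50, 0.5),
                                       sub_band(961, 10, 80, 0.5)),
                        n_starts = 1)
  ratio <- fit$bands[[1]]$amplitude / fit$bands[[2]]$amplitude
  expect_equal(ratio, oracle$a1 / oracle$a2, tolerance = 0.05)
  expect_equal(ratio, 60 / 90, tolerance = 0.05)
})

test_that("reported FWHM matches the half-height width of the reconstructed curve", {
  s <- make_nu1_spectrum(list(sub_band(957, 11, 70, 0.35)), noise_sd = 0)
  fit <- fit_nu1_region(s, init = list(sub_band(955, 9, 50, 0.5)), n_starts = 1)
  b <- fit$bands[[1]]
  xf <- seq(b$center - 40, b$center + 40, 1e-3)
  prof <- pseudo_voigt(xf, b)
  above <- xf[prof >= b$amplitude / 2]
  expect_equal(max(above) - min(above), b$fwhm, tolerance = 1e-3)
})

test_that("fit preconditions are enforced", {
  s <- make_nu1_spectrum(noise_sd = 0)
  expect_error(fit_nu1_region(s, init = list(sub_band(900, 10, 1, 0.5))),
               "outside")
  expect_error(fit_nu1_region(s, window = c(958, 958.5)), "10 samples")
  expect_error(fit_nu1_region(s, init = rep(list(sub_band(958, 10, 1, 0.5)), 5)),
               "1 and 4")
})

test_that("scan layers are translation-invariant and mask cavity cells", {
  # identical spectra -> constant layers
  s <- make_nu1_spectrum(noise_sd = 0, grid = seq(930, 985, 0.5))
  scan <- scan_table(data.frame(x = 0:3, y = 0), rep(list(s), 4))
  layers <- extract_scan_layers(scan)
  expect_false(any(layers$empty))
  expect_lt(diff(range(layers$center)), 1e-6)
  expect_lt(diff(range(layers$intensity)) / mean(layers$intensity), 1e-6)

  # line scan crossing a cavity: near-zero amplitude cells marked empty
  zero <- raman_spectrum(s$wavenumber, rnorm(length(s$wavenumber), 0, 0.01))
  scan2 <- scan_table(data.frame(x = 0:4, y = 0),
                      c(rep(list(s), 2), list(zero), rep(list(s), 2)))
  layers2 <- extract_scan_layers(scan2)
  expect_identical(layers2$empty, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_true(all(is.na(layers2$center[layers2$empty])))

  expect_error(extract_scan_layers(scan_table(data.frame(x = numeric(),
                                                         y = numeric()),
                                              list())),
               "empty")
})

test_that("an annular centre downshift is reproduced in the centre layer", {
  scan <- make_map_scene(extent = 8, cavity_radius = 3, lamella_width = 3,
                        annulus_shift = -1.5, noise_sd = 0,
                        grid = seq(930, 985, 0.5))
  layers <- extract_scan_layers(scan, band_index = 2)
  r <- sqrt(layers$x^2 + layers$y^2)
  inside <- !layers$empty & r >= 3 & r < 6
  outside <- !layers$empty & r >= 6
  expect_true(all(layers$empty[r < 3]))
  expect_lt(max(abs(layers$center[inside] - 956.5)), 0.1)
  expect_lt(max(abs(layers$center[outside] - 958.0)), 0.1)
})
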