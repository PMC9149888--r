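test_that("two-column read/write round-trips at full precision and tolerates headers", {
  s <- raman_spectrum(seq(920, 990, 0.5), rnorm(141, 100, 5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(s, f)
  r <- read_spectrum(f)
  expect_equal(r$wavenumber, s$wavenumber)
  expect_equal(r$intensity, s$intensity)

  # header line is skipped; rows are sorted on read
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("wavenumber intensity", "930 5.5", "920 10.0", "925 7.25"), f2)
  r2 <- read_spectrum(f2)
  expect_equal(r2$wavenumber, c(920, 925, 930))
  expect_equal(r2$intensity, c(10.0, 7.25, 5.5))

  # long-csv round trip preserves metadata
  s$meta <- list(x = 3, y = -2, z = 0, polarization = "cross")
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(s, f3, dialect = "long-csv")
  r3 <- read_spectrum(f3, dialect = "long-csv")
  expect_equal(r3$intensity, s$intensity)
  expect_identical(r3$meta$polarization, "cross")
})

test_that("malformed and degenerate inputs are rejected with informative errors", {
  f <- withr::local_tempfile()
  writeLines(c("920,1.0", "921,oops", "922,2.0"), f)
  expect_error(read_spectrum(f), "line 2")
  f2 <- withr::local_tempfile()
  writeLines(c("920,1.0", "920,2.0", "922,3.0"), f2)
  expect_error(read_spectrum(f2), "duplicate")
  expect_error(raman_spectrum(c(1, 2, 2), c(0, 0, 0)), "duplicate")
  expect_error(raman_spectrum(1:3, c(0, Inf, 0)), "finite")
  expect_error(raman_spectrum(1:3, 1:3, list(polarization = "diagonal")))
})

test_that("scan tables round-trip through long CSV", {
  scan <- make_map_scene(extent = 2, cavity_radius = 0, noise_sd = 0.01,
                         grid = seq(930, 980, 1))
  f <- withr::local_tempfile(fileext = ".csv")
  write_scan(scan, f)
  r <- read_scan(f)
  expect_equal(nrow(r$positions), nrow(scan$positions))
  i <- which(scan$positions$x == 1 & scan$positions$y == -1)
  j <- which(r$positions$x == 1 & r$positions$y == -1)
  expect_equal(r$spectra[[j]]$intensity, scan$spectra[[i]]$intensity)
})

test_that("wavenumber calibration shifts, rescales and is idempotent", {
  s <- raman_spectrum(seq(900, 1000, 0.5), rep(1, 201))
  # single line observed 0.3 too high -> axis shifted down by 0.3
  cal <- calibrate_wavenumber(s, data.frame(nominal = 950, observed = 950.3))
  expect_equal(cal$wavenumber, s$wavenumber - 0.3)

  # two pairs: solve nominal = offset + slope * observed by hand
  ref <- data.frame(nominal = c(940, 980), observed = c(940.5, 981.0))
  slope <- diff(ref$nominal) / diff(ref$observed)   # 40 / 40.5
  offset <- ref$nominal[1] - slope * ref$observed[1]
  cal2 <- calibrate_wavenumber(s, ref)
  expect_equal(cal2$wavenumber, offset + slope * s$wavenumber)
  # residual at the reference lines is zero
  expect_equal(offset + slope * ref$observed, ref$nominal)

  # identical nominal/observed pairs leave the spectrum unchanged
  cal3 <- calibrate_wavenumber(s, data.frame(nominal = c(940, 980),
                                             observed = c(940, 980)))
  expect_equal(cal3$wavenumber, s$wavenumber)

  # re-applying the same line list is the identity
  cal4 <- calibrate_wavenumber(cal2, ref)
  expect_identical(cal4$wavenumber, cal2$wavenumber)

  expect_error(calibrate_wavenumber(s, data.frame(nominal = c(1, 2),
                                                  observed = c(5, 5))),
               "degenerate")
})

test_that("background subtraction removes a linear ramp without touching the peak", {
  wn <- seq(920, 990, 0.1)
  ramp <- 2 + 0.05 * wn
  peak <- 80 * exp(-(wn - 955)^2 / (2 * 3^2))
  s <- raman_spectrum(wn, ramp + peak)
  out <- subtract_background(s, "linear-endpoints")
  edge <- c(seq_len(20), length(wn) - seq_len(20) + 1)
  expect_lt(max(abs(out$intensity[edge])), 1e-9)
  expect_equal(max(out$intensity), 80, tolerance = 1e-6)

  flat <- subtract_background(raman_spectrum(wn, rep(5, length(wn))))
  expect_lt(max(abs(flat$intensity)), 1e-12)

  expect_error(subtract_background(s, window = c(800, 900)), "outside")
  expect_error(subtract_background(s, window = c(920, 920.1)), "3 samples")
})

test_that("FFT smoothing is an ideal low-pass that preserves the mean", {
  wn <- seq(0, 127, 1) + 920
  n <- length(wn)
  # on-bin sinusoid at 0.25 cycles/sample, above a 0.2-Nyquist cutoff
  hi <- sin(2 * pi * 32 * (0:(n - 1)) / n)
  s <- raman_spectrum(wn, 10 + hi)
  out <- smooth_fft(s, cutoff = 0.4)
  expect_lt(max(abs(out$intensity - 10)), 1e-6)
  expect_equal(mean(out$intensity), mean(s$intensity), tolerance = 1e-12)

  # all-pass returns the input
  set.seed(7)
  s2 <- raman_spectrum(wn, rnorm(n, 50, 4))
  expect_equal(smooth_fft(s2, 1)$intensity, s2$intensity, tolerance = 1e-10)

  # white noise loses variance under any real cutoff (Parseval)
  sm <- smooth_fft(s2, 0.1)
  expect_lt(var(sm$intensity), var(s2$intensity))

  nonuni <- raman_spectrum(c(1, 2, 3.5, 4, 5.5, 6, 7, 8.2), rnorm(8))
  expect_error(smooth_fft(nonuni, 0.5), "resample")
  expect_silent(smooth_fft(nonuni, 0.5, resample = TRUE))
  expect_error(smooth_fft(s2, 0), "cutoff")
})
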