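#' Synthetic nu1 spectrum with known sub-band truth
#'
#' Forward-models the phosphate nu1 region as the sum of pseudo-Voigt
#' sub-bands on a 920-990 1/cm grid at 0.1 1/cm spacing (the spectral
#' resolution of a triple-monochromator acquisition), plus an optional
#' linear baseline and additive Gaussian noise.
#'
#' @param bands list of [sub_band()]s; default the three-band model at
#'   948.9 / 958.0 / 971.9 1/cm with heights 40 / 100 / 15.
#' @param noise_sd additive noise standard deviation as a fraction of the
#'   clean signal maximum (default 0).
#' @param seed RNG seed (deterministic output for a fixed seed).
#' @param baseline length-2 `c(intercept, slope)` of a linear baseline in
#'   counts and counts per 1/cm, or `NULL`.
#' @param grid wavenumber grid; default `seq(920, 990, 0.1)`.
#' @return A [raman_spectrum] with the generating truth in `meta$truth`.
#' @export
make_nu1_spectrum <- function(bands = NULL, noise_sd = 0, seed = 1L,
                              baseline = NULL, grid = seq(920, 990, by = 0.1)) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.null(bands))
    bands <- list(sub_band(948.9, 12, 40, 0.5),
                  sub_band(958.0, 10, 100, 0.5),
                  sub_band(971.9, 12, 15, 0.5))
  y <- pv_sum(grid, bands)
  if (!is.null(baseline)) y <- y + baseline[1] + baseline[2] * grid
  if (noise_sd > 0) {
    rng <- get_rng(seed)
    y <- y + rng$rnorm(length(grid), 0, noise_sd * max(pv_sum(grid, bands)))
  }
  s <- raman_spectrum(grid, y)
  s$meta$truth <- list(bands = bands, baseline = baseline,
                       noise_sd = noise_sd, seed = seed)
  s
}

#' Synthetic hyperspectral map around a Haversian canal
#'
#' Emulates a 2-D Raman map at 1 um lateral resolution around a circular
#' cavity (the Haversian canal): inside the cavity the mineral amplitude
#' is zero; the first annulus outside the wall (one lamella wide) carries
#' a band-centre downshift and FWHM broadening of the main nu1 component
#' plus an enhanced low-wavenumber sub-band; farther out, the total
#' intensity is modulated periodically with the lamellar spacing.
#'
#' @param extent map half-size, micrometres; grid is
#'   `seq(-extent, extent, by = spacing)` in x and y around the cavity
#'   centre at the origin.
#' @param spacing lateral step, micrometres (default 1).
#' @param cavity_radius canal radius, micrometres (default 5); `<= 0`
#'   disables the cavity and all radial structure (uniform scene).
#' @param lamella_width first-lamella width and intensity modulation
#'   period, micrometres (default 5, the middle of the 3-7 um range of
#'   osteonal lamellae).
#' @param annulus_shift band-centre shift of the main component inside the
#'   first lamella, 1/cm (default -1.5).
#' @param annulus_broadening FWHM increase inside the first lamella, 1/cm
#'   (default 3).
#' @param annulus_948_gain multiplicative gain of the 948.9 1/cm sub-band
#'   inside the first lamella (default 2.7, the near-canal enhancement).
#' @param modulation_depth relative amplitude of the lamellar intensity
#'   modulation (default 0.15).
#' @param noise_sd,seed as in [make_nu1_spectrum()].
#' @param grid wavenumber grid (default `seq(920, 990, 0.1)`).
#' @return A [scan_table()] with truth stored in the table's
#'   `attr(, "truth")`.
#' @export
make_map_scene <- function(extent = 10, spacing = 1, cavity_radius = 5,
                           lamella_width = 5, annulus_shift = -1.5,
                           annulus_broadening = 3, annulus_948_gain = 2.7,
                           modulation_depth = 0.15, noise_sd = 0, seed = 1L,
                           grid = seq(920, 990, by = 0.1)) {
  xs <- seq(-extent, extent, by = spacing)
  ys <- seq(-extent, extent, by = spacing)
  if (cavity_radius > extent)
    stop("cavity must lie inside the mapped area", call. = FALSE)
  rng <- get_rng(seed)
  pos <- expand.grid(x = xs, y = ys)
  spectra <- vector("list", nrow(pos))
  for (i in seq_len(nrow(pos))) {
    r <- sqrt(pos$x[i]^2 + pos$y[i]^2)
    if (cavity_radius > 0 && r < cavity_radius) {
      y <- if (noise_sd > 0) rng$rnorm(length(grid), 0, noise_sd * 100)
           else numeric(length(grid))
      spectra[[i]] <- raman_spectrum(grid, y,
                                     list(x = pos$x[i], y = pos$y[i]))
      next
    }
    in_annulus <- cavity_radius > 0 && r < cavity_radius + lamella_width
    shift <- if (in_annulus) annulus_shift else 0
    broad <- if (in_annulus) annulus_broadening else 0
    gain <- if (in_annulus) annulus_948_gain else 1
    amp <- if (cavity_radius > 0)
      1 + modulation_depth * cos(2 * pi * (r - cavity_radius) / lamella_width)
    else 1
    bands <- list(
      sub_band(948.9, 12, 15 * gain * amp, 0.5),
      sub_band(958.0 + shift, 10 + broad, 100 * amp, 0.5),
      sub_band(971.9, 12, 10 * amp, 0.5))
    y <- pv_sum(grid, bands)
    if (noise_sd > 0) y <- y + rng$rnorm(length(grid), 0, noise_sd * max(y))
    spectra[[i]] <- raman_spectrum(grid, y, list(x = pos$x[i], y = pos$y[i]))
  }
  scan <- scan_table(pos, spectra)
  attr(scan, "truth") <- list(cavity_radius = cavity_radius,
                              lamella_width = lamella_width,
                              annulus_shift = annulus_shift,
                              annulus_broadening = annulus_broadening,
                              annulus_948_gain = annulus_948_gain,
                              modulation_depth = modulation_depth,
                              noise_sd = noise_sd, seed = seed)
  scan
}

#' Synthetic polarized angular series pair
#'
#' Generates parallel and cross rotation series from the population
#' forward model with known orientation/ODF/tensor truth, applies
#' multiplicative Gaussian noise, and returns [angular_series()] objects
#' ready for [fit_angular_series()]. A second depth with an azimuthal lag
#' can be produced by shifting `psi` (the in-depth angular lag between
#' axial orientations seen when refocusing the confocal probe).
#'
#' @param orient an [euler_orientation()] truth.
#' @param odf an [odf_params()] truth.
#' @param tensor a [raman_tensor()] truth.
#' @param angles rotation angles, degrees; default `seq(0, 180, by = 10)`.
#' @param noise_sd multiplicative noise sigma (default 0.02).
#' @param seed RNG seed.
#' @param z focal depth tag, micrometres.
#' @param psi_lag added to `psi` before generation (default 0), emulating
#'   the depth-dependent azimuth lag.
#' @return List with elements `parallel` and `cross`
#'   ([angular_series()]s) and `truth`.
#' @export
make_angular_series <- function(orient, odf, tensor,
                                angles = seq(0, 180, by = 10),
                                noise_sd = 0.02, seed = 1L, z = 0,
                                psi_lag = 0) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  gen <- euler_orientation(orient$theta, orient$psi + psi_lag, orient$phi)
  rng <- get_rng(seed)
  out <- list()
  for (geom in c("parallel", "cross")) {
    cfg <- polarization_config(geom)
    mu <- population_intensity(gen, odf, cfg, tensor, angles)
    if (noise_sd > 0) mu <- mu * (1 + rng$rnorm(length(mu), 0, noise_sd))
    mu <- pmax(mu, 1e-9)
    out[[geom]] <- angular_series(angles, mu, geom, z = z)
  }
  out$truth <- list(orientation = gen, odf = odf, tensor = tensor,
                    noise_sd = noise_sd, seed = seed)
  out
}

#' Plywood parameter presets reproducing realistic tilt excursions
#'
#' Three presets emulating radial out-of-plane tilt profiles across
#' osteonal lamellae, with lamellar-scale periods (~5-7 um): the
#' `"x-axis"` scene oscillates inside a 10-30 degree envelope with a
#' moderate decaying twisted fraction; the `"y-axis"` scene stays inside
#' 16-26 degrees and is oscillating-dominated (the twisted motif is not
#' the predominant one); the `"mixed"` scene carries a strong twisted
#' fraction at the wall (Vt(0) = 0.6) so that both motifs contribute
#' identifiable amplitude — the benchmark truth for parameter-recovery
#' studies.
#'
#' @param scene `"x-axis"`, `"y-axis"` or `"mixed"`.
#' @return A [plywood_params()].
#' @export
preset_plywood <- function(scene = c("x-axis", "y-axis", "mixed")) {
  scene <- match.arg(scene)
  switch(scene,
    "x-axis" = plywood_params(ht = 0.25, gt = 0.05, At = 5, Bt = 0.9,
                              Dt = 0.6, A0 = 5, B0 = 1.26, C0 = 1.2, D0 = 21),
    "y-axis" = plywood_params(ht = 0.05, gt = 0.05, At = 2, Bt = 0.8,
                              Dt = 0.3, A0 = 2, B0 = 1.1, C0 = 0.8, D0 = 21),
    "mixed"  = plywood_params(ht = 0.6, gt = 0.03, At = 8, Bt = 0.9,
                              Dt = 0.6, A0 = 6, B0 = 1.26, C0 = 1.2, D0 = 20))
}

#' Synthetic probe-convolved tilt profile
#'
#' @param p a [plywood_params()] truth (see [preset_plywood()]).
#' @param probe a [probe_model()].
#' @param positions observation positions, micrometres; default
#'   `seq(0, 30, 0.5)`.
#' @param noise_sd additive angular noise, degrees (default 1).
#' @param seed RNG seed.
#' @return An [angle_profile()] with truth in `attr(, "truth")`.
#' @export
make_theta_profile <- function(p, probe, positions = seq(0, 30, by = 0.5),
                               noise_sd = 1, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  th <- convolved_plywood(positions, p, probe)
  if (noise_sd > 0) {
    rng <- get_rng(seed)
    th <- th + rng$rnorm(length(th), 0, noise_sd)
  }
  prof <- angle_profile(positions, th)
  attr(prof, "truth") <- list(params = p, probe = probe,
                              noise_sd = noise_sd, seed = seed)
  prof
}

#' Synthetic cavity-edge intensity line scan
#'
#' A step field (zero inside the cavity, bulk level outside) convolved
#' with the Gaussian probe, plus relative Gaussian noise — the situation
#' from which the probe response function is estimated experimentally.
#'
#' @param probe a [probe_model()] truth.
#' @param positions scan positions, micrometres; the wall sits at `wall`.
#' @param wall cavity-wall position, micrometres (default 0).
#' @param bulk_level plateau intensity outside the cavity (default 100).
#' @param noise_sd relative noise sigma (default 0.02).
#' @param seed RNG seed.
#' @return data.frame with columns `position`, `intensity`; truth in
#'   `attr(, "truth")`.
#' @export
make_edge_profile <- function(probe, positions = seq(-8, 8, by = 0.25),
                              wall = 0, bulk_level = 100, noise_sd = 0.02,
                              seed = 1L) {
  step <- function(x) ifelse(x >= wall, bulk_level, 0)
  y <- convolve_profile(step, probe, positions, x_min = -Inf)
  if (noise_sd > 0) {
    rng <- get_rng(seed)
    y <- y + rng$rnorm(length(y), 0, noise_sd * bulk_level)
  }
  out <- data.frame(position = positions, intensity = y)
  attr(out, "truth") <- list(probe = probe, wall = wall,
                             bulk_level = bulk_level, noise_sd = noise_sd,
                             seed = seed)
  out
}
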