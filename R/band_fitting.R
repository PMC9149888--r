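#' Define a pseudo-Voigt sub-band
#'
#' @param center band position, 1/cm.
#' @param fwhm full width at half maximum, 1/cm, > 0.
#' @param amplitude peak height, counts, >= 0.
#' @param eta Lorentzian fraction in [0, 1]; 0 is pure Gaussian, 1 pure
#'   Lorentzian.
#' @return A `sub_band` object (named list).
#' @export
sub_band <- function(center, fwhm, amplitude = 1, eta = 0.5) {
  if (!is.finite(fwhm) || fwhm <= 0) stop("fwhm must be > 0", call. = FALSE)
  if (eta < 0 || eta > 1) stop("eta must lie in [0, 1]", call. = FALSE)
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  structure(list(center = center, fwhm = fwhm, amplitude = amplitude,
                 eta = eta), class = "sub_band")
}

#' Evaluate a pseudo-Voigt profile
#'
#' Linear-combination pseudo-Voigt: `amplitude * (eta * L + (1 - eta) * G)`
#' where the Lorentzian L and Gaussian G share the same centre and FWHM and
#' both have unit peak height, so the profile's value at the centre is
#' exactly `amplitude`.
#'
#' @param x wavenumber vector, 1/cm.
#' @param band a [sub_band()], or a list with fields `center`, `fwhm`,
#'   `amplitude`, `eta`.
#' @return Intensity vector, same length as `x`.
#' @examples
#' b <- sub_band(958, 10, amplitude = 100, eta = 0.3)
#' pseudo_voigt(958 + c(-5, 0, 5), b)  # half height at +/- fwhm/2
#' @export
pseudo_voigt <- function(x, band) {
  if (band$fwhm <= 0) stop("fwhm must be > 0", call. = FALSE)
  u <- (x - band$center) / band$fwhm
  L <- 1 / (1 + 4 * u^2)
  G <- exp(-4 * log(2) * u^2)
  band$amplitude * (band$eta * L + (1 - band$eta) * G)
}

pv_sum <- function(x, bands) {
  y <- numeric(length(x))
  for (b in bands) y <- y + pseudo_voigt(x, b)
  y
}

#' Integrated area of a pseudo-Voigt band
#'
#' Closed form: `amplitude * fwhm * (eta * pi/2 + (1 - eta) * sqrt(pi / (4 log 2)))`.
#'
#' @param band a [sub_band()].
#' @return Band area (counts * 1/cm).
#' @export
band_area <- function(band) {
  band$amplitude * band$fwhm *
    (band$eta * pi / 2 + (1 - band$eta) * sqrt(pi / (4 * log(2))))
}

#' Default nu1 sub-band initialisation
#'
#' Three pseudo-Voigt start bands at 948.9, 958.0 and 971.9 1/cm — the
#' sub-band structure of the apatite nu1 P-O stretching region in osteonal
#' bone, with the dominant component at 958.0 1/cm.
#'
#' @param amplitude start height given to each band.
#' @return List of three [sub_band()] objects.
#' @export
nu1_default_bands <- function(amplitude = 1) {
  list(sub_band(948.9, 12, amplitude * 0.4, 0.5),
       sub_band(958.0, 10, amplitude, 0.5),
       sub_band(971.9, 12, amplitude * 0.15, 0.5))
}

#' Fit the nu1 phosphate region with pseudo-Voigt sub-bands
#'
#' Nonlinear least squares (Levenberg-Marquardt via \pkg{minpack.lm}) of a
#' sum of 1-4 pseudo-Voigt sub-bands to the windowed spectrum. Band
#' centres are bounded to the window, FWHMs to [1, 40] 1/cm, amplitudes to
#' >= 0 and Lorentzian fractions to [0, 1]. A multi-start strategy jitters
#' the initial centres/widths (fixed RNG seed) to escape local minima; the
#' start with the lowest residual wins, ties broken in favour of fewer
#' parameters pinned at a bound.
#'
#' @param s a [raman_spectrum].
#' @param init list of initial [sub_band()]s; default three bands at
#'   948.9 / 958.0 / 971.9 1/cm scaled to the window maximum.
#' @param window length-2 numeric, fit window in 1/cm (default
#'   `c(920, 990)`).
#' @param n_starts number of jittered initialisations (default 5).
#' @param seed RNG seed for the jitter.
#' @return A `band_fit` object: list with `bands` (sorted by centre),
#'   `residual_rms`, `fit_window`, `covariance`, `converged` and `area`
#'   (per-band integrated areas).
#' @export
fit_nu1_region <- function(s, init = NULL, window = c(920, 990),
                           n_starts = 5, seed = 1L) {
  stopifnot(inherits(s, "raman_spectrum"))
  sel <- s$wavenumber >= window[1] & s$wavenumber <= window[2]
  if (sum(sel) < 10) stop("fit window contains fewer than 10 samples", call. = FALSE)
  x <- s$wavenumber[sel]
  y <- s$intensity[sel]
  if (is.null(init)) init <- nu1_default_bands(max(y))
  if (length(init) < 1 || length(init) > 4)
    stop("between 1 and 4 initial bands required", call. = FALSE)
  for (b in init)
    if (b$center < window[1] || b$center > window[2])
      stop("initial band centre outside the fit window", call. = FALSE)

  nb <- length(init)
  pack <- function(bands) unlist(lapply(bands, function(b)
    c(b$center, b$fwhm, b$amplitude, b$eta)))
  unpack <- function(p) lapply(seq_len(nb), function(i) {
    q <- p[(4 * i - 4) + 1:4]
    list(center = q[1], fwhm = q[2], amplitude = q[3], eta = q[4])
  })
  lower <- rep(c(window[1], 1, 0, 0), nb)
  upper <- rep(c(window[2], 40, Inf, 1), nb)
  resid_fn <- function(p) pv_sum(x, unpack(p)) - y

  p0 <- pack(init)
  rng <- get_rng(seed)
  best <- NULL
  for (k in seq_len(n_starts)) {
    pk <- p0
    if (k > 1) {  # jitter centres by up to 1.5 1/cm, widths by 20%
      jc <- rng$runif(nb, -1.5, 1.5)
      jw <- rng$runif(nb, 0.8, 1.2)
      for (i in seq_len(nb)) {
        pk[4 * i - 3] <- min(max(pk[4 * i - 3] + jc[i], lower[4 * i - 3]),
                             upper[4 * i - 3])
        pk[4 * i - 2] <- min(max(pk[4 * i - 2] * jw[i], 1), 40)
      }
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(pk, lower, upper, resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rms <- sqrt(mean(fit$fvec^2))
    at_bound <- sum(abs(fit$par - lower) < 1e-10 | abs(fit$par - upper) < 1e-10)
    if (is.null(best) || rms < best$rms - 1e-12 ||
        (abs(rms - best$rms) <= 1e-12 && at_bound < best$at_bound)) {
      best <- list(fit = fit, rms = rms, at_bound = at_bound)
    }
  }
  if (is.null(best))
    stop("band fit failed to converge from any start", call. = FALSE)

  bands <- lapply(unpack(best$fit$par), function(b)
    sub_band(b$center, b$fwhm, b$amplitude, b$eta))
  o <- order(vapply(bands, `[[`, numeric(1), "center"))
  bands <- bands[o]
  covar <- tryCatch({
    cv <- stats::vcov(best$fit)
    perm <- as.vector(outer(1:4, (o - 1) * 4, `+`))
    cv[perm, perm, drop = FALSE]
  }, error = function(e) NULL)
  structure(list(bands = bands,
                 residual_rms = best$rms,
                 fit_window = window,
                 covariance = covar,
                 converged = best$fit$info %in% 1:4,
                 area = vapply(bands, band_area, numeric(1))),
            class = "band_fit")
}

#' @export
print.band_fit <- function(x, ...) {
  cat("<band_fit>", length(x$bands), "sub-bands, residual RMS",
      format(x$residual_rms, digits = 4), "\n")
  for (b in x$bands)
    cat(sprintf("  centre %8.2f  fwhm %6.2f  height %10.4g  eta %.2f\n",
                b$center, b$fwhm, b$amplitude, b$eta))
  invisible(x)
}

#' Extract intensity / position / FWHM layers from a scan
#'
#' Fits the nu1 region at every scan position and assembles map layers of
#' fitted peak height ("intensity"), band centre and FWHM for one chosen
#' sub-band. Positions whose total fitted nu1 amplitude falls below
#' `floor_frac` times the median amplitude over the scan are marked empty
#' (`NA`) — these are cavity cells, e.g. inside the Haversian canal, where
#' the mineral signal vanishes.
#'
#' @param scan a [scan_table()].
#' @param band_index which sub-band (by centre order) to report; default 2,
#'   the main component near 958 1/cm in the three-band model.
#' @param init,window,n_starts,seed passed to [fit_nu1_region()];
#'   `n_starts` defaults to 1 for speed since per-pixel spectra start from
#'   the previous solution's neighbourhood.
#' @param floor_frac amplitude floor as a fraction of the scan's median
#'   total nu1 amplitude (default 0.05).
#' @return A `map_layers` object: data.frame with columns `x`, `y`, `z`,
#'   `intensity`, `center`, `fwhm`, `empty`.
#' @export
extract_scan_layers <- function(scan, band_index = 2, init = NULL,
                                window = c(920, 990), n_starts = 1,
                                seed = 1L, floor_frac = 0.05) {
  stopifnot(inherits(scan, "scan_table"))
  n <- length(scan$spectra)
  if (n == 0) stop("empty scan", call. = FALSE)
  fits <- vector("list", n)
  total_amp <- numeric(n)
  for (i in seq_len(n)) {
    fits[[i]] <- tryCatch(
      fit_nu1_region(scan$spectra[[i]], init = init, window = window,
                     n_starts = n_starts, seed = seed),
      error = function(e) NULL)
    total_amp[i] <- if (is.null(fits[[i]])) 0 else
      sum(vapply(fits[[i]]$bands, `[[`, numeric(1), "amplitude"))
  }
  floor_amp <- floor_frac * stats::median(total_amp)
  out <- scan$positions
  out$intensity <- NA_real_
  out$center <- NA_real_
  out$fwhm <- NA_real_
  out$empty <- total_amp < floor_amp | vapply(fits, is.null, logical(1))
  for (i in seq_len(n)) {
    if (out$empty[i]) next
    f <- fits[[i]]
    bi <- min(band_index, length(f$bands))
    out$intensity[i] <- f$bands[[bi]]$amplitude
    out$center[i] <- f$bands[[bi]]$center
    out$fwhm[i] <- f$bands[[bi]]$fwhm
  }
  class(out) <- c("map_layers", "data.frame")
  out
}
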