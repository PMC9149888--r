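#' Construct a Raman spectrum object
#'
#' A `raman_spectrum` couples a strictly increasing wavenumber axis (1/cm)
#' with an intensity vector (arbitrary counts) and acquisition metadata:
#' stage position (`x`, `y` in micrometres), focal depth (`z`, micrometres)
#' and the polarization geometry of the acquisition. The polarization label
#' encodes the backscattering Porto configurations used for bone work:
#' `"parallel"` for z(yy)z-bar, `"cross"` for z(xy)z-bar, or
#' `"unpolarized"`.
#'
#' @param wavenumber numeric vector, strictly increasing, 1/cm.
#' @param intensity numeric vector of the same length, finite.
#' @param meta named list of acquisition tags. Recognised entries: `x`, `y`,
#'   `z` (micrometres) and `polarization` (one of `"parallel"`, `"cross"`,
#'   `"unpolarized"`). Additional entries are carried along untouched.
#' @return An object of class `raman_spectrum`: a list with elements
#'   `wavenumber`, `intensity` and `meta`.
#' @examples
#' s <- raman_spectrum(seq(920, 990, 0.5), rnorm(141, 100, 1))
#' print(s)
#' @export
raman_spectrum <- function(wavenumber, intensity, meta = list()) {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity))
    stop("wavenumber and intensity must have the same length", call. = FALSE)
  if (anyNA(wavenumber) || any(!is.finite(wavenumber)))
    stop("wavenumber axis must be finite", call. = FALSE)
  if (anyNA(intensity) || any(!is.finite(intensity)))
    stop("intensity must be finite", call. = FALSE)
  if (length(wavenumber) > 1 && any(diff(wavenumber) <= 0)) {
    if (any(duplicated(wavenumber)))
      stop("duplicate wavenumber values in axis", call. = FALSE)
    stop("wavenumber axis must be strictly increasing", call. = FALSE)
  }
  if (!is.null(meta$polarization)) {
    meta$polarization <- match.arg(meta$polarization,
                                   c("parallel", "cross", "unpolarized"))
  }
  structure(list(wavenumber = wavenumber, intensity = intensity, meta = meta),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  rng <- range(x$wavenumber)
  cat(sprintf("<raman_spectrum> %d points, %.1f-%.1f 1/cm", length(x$wavenumber),
              rng[1], rng[2]))
  if (!is.null(x$meta$polarization)) cat(", ", x$meta$polarization, sep = "")
  if (!is.null(x$meta$calibration)) cat(" [calibrated]")
  cat("\n")
  invisible(x)
}

#' Read a spectrum from a text file
#'
#' Two dialects are supported: `"two-column"` — whitespace- or
#' comma-separated wavenumber/intensity pairs, optionally preceded by a
#' single non-numeric header line; and `"long-csv"` — a CSV with columns
#' `x, y, z, polarization, wavenumber, intensity` from which a single
#' spectrum is taken (the file must contain exactly one position).
#' Rows are sorted by wavenumber on read; duplicated wavenumbers are an
#' error because they leave the axis ambiguous.
#'
#' @param path file path.
#' @param dialect `"two-column"` (default) or `"long-csv"`.
#' @return A [raman_spectrum].
#' @seealso [write_spectrum()], [read_scan()]
#' @export
read_spectrum <- function(path, dialect = c("two-column", "long-csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "long-csv") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("wavenumber", "intensity")
    if (!all(need %in% names(tab)))
      stop("long-csv dialect requires wavenumber and intensity columns",
           call. = FALSE)
    pos <- unique(tab[intersect(c("x", "y", "z"), names(tab))])
    if (nrow(pos) > 1)
      stop("long-csv file holds multiple positions; use read_scan()",
           call. = FALSE)
    meta <- as.list(pos)
    if ("polarization" %in% names(tab))
      meta$polarization <- unique(tab$polarization)[1]
    o <- order(tab$wavenumber)
    wn <- tab$wavenumber[o]
    if (any(duplicated(wn)))
      stop("duplicate wavenumber values in ", path, call. = FALSE)
    return(raman_spectrum(wn, tab$intensity[o], meta))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)
  parse_row <- function(l) {
    fields <- strsplit(trimws(l), "[,;[:space:]]+")[[1]]
    suppressWarnings(as.numeric(fields))
  }
  first <- parse_row(lines[1])
  start <- 1L
  if (anyNA(first)) start <- 2L  # tolerate one header line
  if (start > length(lines)) stop("no numeric rows in ", path, call. = FALSE)
  vals <- lapply(seq(start, length(lines)), function(i) {
    v <- parse_row(lines[i])
    if (length(v) < 2 || anyNA(v[1:2]))
      stop(sprintf("malformed row at line %d of %s", i, path), call. = FALSE)
    v[1:2]
  })
  m <- do.call(rbind, vals)
  o <- order(m[, 1])
  wn <- m[o, 1]
  if (any(duplicated(wn)))
    stop("duplicate wavenumber values in ", path, call. = FALSE)
  raman_spectrum(wn, m[o, 2])
}

#' Write a spectrum to a text file
#'
#' @param s a [raman_spectrum].
#' @param path output path.
#' @param dialect `"two-column"` (comma-separated, full precision) or
#'   `"long-csv"`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, dialect = c("two-column", "long-csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(s, "raman_spectrum"))
  if (dialect == "two-column") {
    writeLines(paste(format(s$wavenumber, digits = 17),
                     format(s$intensity, digits = 17), sep = ","), path)
  } else {
    m <- s$meta
    tab <- data.frame(
      x = if (is.null(m$x)) 0 else m$x,
      y = if (is.null(m$y)) 0 else m$y,
      z = if (is.null(m$z)) 0 else m$z,
      polarization = if (is.null(m$polarization)) "unpolarized" else m$polarization,
      wavenumber = s$wavenumber, intensity = s$intensity)
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a scan table (line scan or map) from long CSV
#'
#' Long format: one row per (position, wavenumber) sample with columns
#' `x, y, z, polarization, wavenumber, intensity` (`z` and `polarization`
#' optional). Positions in micrometres; the grid may be irregular for line
#' scans and regular for maps.
#'
#' @param path CSV path.
#' @return A `scan_table`: a list with `positions` (data.frame of x, y, z)
#'   and `spectra` (list of [raman_spectrum], one per position).
#' @export
read_scan <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "wavenumber", "intensity")
  if (!all(need %in% names(tab)))
    stop("scan CSV requires columns x, y, wavenumber, intensity", call. = FALSE)
  if (!"z" %in% names(tab)) tab$z <- 0
  key <- interaction(tab$x, tab$y, tab$z, drop = TRUE)
  idx <- split(seq_len(nrow(tab)), key)
  spectra <- vector("list", length(idx))
  pos <- data.frame(x = numeric(length(idx)), y = numeric(length(idx)),
                    z = numeric(length(idx)))
  for (i in seq_along(idx)) {
    rows <- tab[idx[[i]], ]
    o <- order(rows$wavenumber)
    meta <- list(x = rows$x[1], y = rows$y[1], z = rows$z[1])
    if ("polarization" %in% names(rows)) meta$polarization <- rows$polarization[1]
    spectra[[i]] <- raman_spectrum(rows$wavenumber[o], rows$intensity[o], meta)
    pos[i, ] <- c(rows$x[1], rows$y[1], rows$z[1])
  }
  o <- order(pos$y, pos$x)
  scan_table(pos[o, , drop = FALSE], spectra[o])
}

#' Construct a scan table
#'
#' @param positions data.frame with numeric columns `x`, `y` and optionally
#'   `z` (micrometres).
#' @param spectra list of [raman_spectrum] objects, one per row of
#'   `positions`.
#' @return An object of class `scan_table`.
#' @export
scan_table <- function(positions, spectra) {
  positions <- as.data.frame(positions)
  if (!"z" %in% names(positions)) positions$z <- rep(0, nrow(positions))
  rownames(positions) <- NULL
  if (nrow(positions) != length(spectra))
    stop("one spectrum per position required", call. = FALSE)
  if (any(!is.finite(as.matrix(positions[c("x", "y", "z")]))))
    stop("positions must be finite", call. = FALSE)
  structure(list(positions = positions, spectra = spectra),
            class = "scan_table")
}

#' @export
print.scan_table <- function(x, ...) {
  cat(sprintf("<scan_table> %d positions, x in [%g, %g] um, y in [%g, %g] um\n",
              nrow(x$positions), min(x$positions$x), max(x$positions$x),
              min(x$positions$y), max(x$positions$y)))
  invisible(x)
}

#' Write a scan table to long CSV
#'
#' @param scan a `scan_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "scan_table"))
  parts <- lapply(seq_along(scan$spectra), function(i) {
    s <- scan$spectra[[i]]
    data.frame(x = scan$positions$x[i], y = scan$positions$y[i],
               z = scan$positions$z[i],
               polarization = if (is.null(s$meta$polarization)) "unpolarized"
                              else s$meta$polarization,
               wavenumber = s$wavenumber, intensity = s$intensity)
  })
  utils::write.csv(do.call(rbind, parts), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Calibrate the wavenumber axis against reference lamp lines
#'
#' High-resolution acquisitions drift; a reference lamp (typically neon)
#' recorded alongside each measurement pins the axis. With a single
#' reference line the axis is shifted by the nominal-minus-observed offset;
#' with two or more lines an affine correction (offset plus linear
#' dispersion rescale) is fitted by least squares so the observed lines
#' land on their nominal positions.
#'
#' @param s a [raman_spectrum].
#' @param ref data.frame (or 2-column matrix) with columns `nominal` and
#'   `observed`, both 1/cm, one row per reference line.
#' @return The calibrated [raman_spectrum]; the fitted transform is stored
#'   in `meta$calibration` as `c(offset, slope)` applied as
#'   `offset + slope * wavenumber`.
#' @export
calibrate_wavenumber <- function(s, ref) {
  stopifnot(inherits(s, "raman_spectrum"))
  ref <- as.data.frame(ref)
  if (ncol(ref) == 2 && !all(c("nominal", "observed") %in% names(ref)))
    names(ref) <- c("nominal", "observed")
  if (nrow(ref) < 1) stop("at least one reference line required", call. = FALSE)
  if (any(duplicated(ref$nominal)))
    stop("nominal reference wavenumbers must be distinct", call. = FALSE)
  # already calibrated against this very line list: applying the same
  # correction twice would double-count the drift
  if (!is.null(s$meta$calibration_ref) &&
      isTRUE(all.equal(s$meta$calibration_ref, ref[c("nominal", "observed")])))
    return(s)
  if (nrow(ref) == 1) {
    offset <- ref$nominal[1] - ref$observed[1]
    slope <- 1
  } else {
    if (any(duplicated(ref$observed)) || diff(range(ref$observed)) == 0)
      stop("degenerate reference pairs: observed values coincide", call. = FALSE)
    fit <- stats::lm(nominal ~ observed, data = ref)
    offset <- unname(stats::coef(fit)[1])
    slope <- unname(stats::coef(fit)[2])
  }
  out <- s
  out$wavenumber <- offset + slope * s$wavenumber
  out$meta$calibration <- c(offset = offset, slope = slope)
  out$meta$calibration_ref <- ref[c("nominal", "observed")]
  out
}

#' Subtract a baseline from a spectrum
#'
#' Estimates the background inside `window` from the spectrum's edge
#' regions and subtracts it. `"linear-endpoints"` draws a straight line
#' through the mean intensity of the first and last `edge_frac` of the
#' window; `"polynomial"` fits a degree-`degree` polynomial to those same
#' edge regions. Signal between the edges is untouched apart from the
#' subtraction, so negative residuals are possible and permitted.
#'
#' @param s a [raman_spectrum].
#' @param method `"linear-endpoints"` (default) or `"polynomial"`.
#' @param window length-2 numeric, 1/cm interval to operate on; defaults to
#'   the full axis.
#' @param degree polynomial degree for `method = "polynomial"`.
#' @param edge_frac fraction of the window, at each end, treated as
#'   peak-free baseline support (default 0.1).
#' @return A [raman_spectrum] restricted to `window` with the baseline
#'   removed; the baseline itself is stored in `meta$baseline`.
#' @export
subtract_background <- function(s, method = c("linear-endpoints", "polynomial"),
                                window = range(s$wavenumber), degree = 2,
                                edge_frac = 0.1) {
  method <- match.arg(method)
  stopifnot(inherits(s, "raman_spectrum"))
  if (window[1] < min(s$wavenumber) - 1e-9 || window[2] > max(s$wavenumber) + 1e-9)
    stop("background window lies outside the wavenumber axis", call. = FALSE)
  sel <- s$wavenumber >= window[1] & s$wavenumber <= window[2]
  if (sum(sel) < 3) stop("background window shorter than 3 samples", call. = FALSE)
  wn <- s$wavenumber[sel]
  y <- s$intensity[sel]
  span <- diff(range(wn))
  edge <- wn <= wn[1] + edge_frac * span | wn >= wn[length(wn)] - edge_frac * span
  if (method == "linear-endpoints") {
    lo <- wn <= wn[1] + edge_frac * span
    hi <- wn >= wn[length(wn)] - edge_frac * span
    x1 <- mean(wn[lo]); y1 <- mean(y[lo])
    x2 <- mean(wn[hi]); y2 <- mean(y[hi])
    if (x2 == x1) stop("degenerate window", call. = FALSE)
    base <- y1 + (y2 - y1) / (x2 - x1) * (wn - x1)
  } else {
    fit <- stats::lm(y[edge] ~ stats::poly(wn[edge], degree, raw = TRUE))
    base <- drop(cbind(1, stats::poly(wn, degree, raw = TRUE)) %*% stats::coef(fit))
  }
  out <- raman_spectrum(wn, y - base, s$meta)
  out$meta$baseline <- base
  out
}

#' Low-pass smooth a spectrum with an ideal FFT filter
#'
#' Zeroes all Fourier components above `cutoff` times the Nyquist
#' frequency. The DC component is untouched, so the mean intensity is
#' preserved exactly. The axis must be uniformly sampled; non-uniform axes
#' are first linearly resampled to the median spacing when
#' `resample = TRUE`, otherwise they are an error.
#'
#' @param s a [raman_spectrum].
#' @param cutoff fraction of Nyquist in (0, 1]; `1` is an all-pass.
#' @param resample logical; linearly resample a non-uniform axis to its
#'   median spacing before filtering.
#' @return The smoothed [raman_spectrum].
#' @export
smooth_fft <- function(s, cutoff, resample = FALSE) {
  stopifnot(inherits(s, "raman_spectrum"))
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff > 1)
    stop("cutoff must lie in (0, 1]", call. = FALSE)
  d <- diff(s$wavenumber)
  uniform <- max(d) - min(d) < 1e-8 * stats::median(d)
  if (!uniform) {
    if (!resample)
      stop("non-uniform wavenumber axis: set resample = TRUE", call. = FALSE)
    h <- stats::median(d)
    grid <- seq(s$wavenumber[1], s$wavenumber[length(s$wavenumber)], by = h)
    y <- stats::approx(s$wavenumber, s$intensity, xout = grid)$y
    s <- raman_spectrum(grid, y, s$meta)
  }
  n <- length(s$intensity)
  sp <- stats::fft(s$intensity)
  # frequency index of bin k (0-based) in cycles/sample, Nyquist = 0.5
  k <- seq_len(n) - 1
  freq <- pmin(k, n - k) / n
  sp[freq > cutoff * 0.5 + 1e-12] <- 0
  out <- s
  out$intensity <- Re(stats::fft(sp, inverse = TRUE)) / n
  out
}
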