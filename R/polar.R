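#' Polarization configuration for backscattering Porto geometries
#'
#' The incident polarization is fixed along the laboratory y-axis; the
#' analyzer passes either the parallel (z(yy)z-bar) or the perpendicular
#' (z(xy)z-bar) component of the scattered light:
#' `e_i = (0, 1, 0)` always, `e_s = (0, 1, 0)` for `"parallel"` and
#' `e_s = (1, 0, 0)` for `"cross"`.
#'
#' @param geometry `"parallel"` or `"cross"`.
#' @return A `polarization_config`: list with unit vectors `e_i`, `e_s`
#'   and the `geometry` tag.
#' @export
polarization_config <- function(geometry = c("parallel", "cross")) {
  geometry <- match.arg(geometry)
  e_i <- c(0, 1, 0)
  e_s <- if (geometry == "parallel") c(0, 1, 0) else c(1, 0, 0)
  structure(list(e_i = e_i, e_s = e_s, geometry = geometry),
            class = "polarization_config")
}

#' Euler orientation of the mean apatite c-axis
#'
#' `theta` is the out-of-plane polar angle between the mean c-axis and the
#' laboratory z-axis (the Haversian canal axis); `psi` is the in-plane
#' azimuth, measured from the laboratory y-axis (the fixed incident
#' polarization direction at zero stage rotation). The third Euler angle
#' `phi` describes rotation about the c-axis itself; the nu1 Raman tensor
#' is transversely isotropic, which makes `phi` unobservable, so it is
#' carried for completeness but fixed at 0 by the fitter.
#'
#' @param theta degrees in `[0, 90]`.
#' @param psi degrees; reported wrapped into `(-90, 90]` (c-axis director
#'   symmetry).
#' @param phi degrees (default 0).
#' @return An `euler_orientation` object.
#' @export
euler_orientation <- function(theta, psi, phi = 0) {
  if (theta < 0 || theta > 90)
    stop("theta must lie in [0, 90] degrees", call. = FALSE)
  structure(list(theta = theta, psi = wrap_psi(psi), phi = phi),
            class = "euler_orientation")
}

#' Uniaxial Raman tensor for the apatite nu1 mode
#'
#' In the crystal frame the totally symmetric phosphate stretching tensor
#' is diagonal, `diag(a, a, b)`, with the distinct element `b` along the
#' c-axis. Only the ratio `b/a` affects relative polarized intensities,
#' so `a` defaults to 1.
#'
#' @param b_over_a tensor anisotropy ratio, > 0.
#' @param a in-plane element (default 1).
#' @return A `raman_tensor` object with fields `a`, `b`.
#' @export
raman_tensor <- function(b_over_a, a = 1) {
  if (!is.finite(b_over_a) || b_over_a <= 0)
    stop("b/a must be positive", call. = FALSE)
  structure(list(a = a, b = a * b_over_a, b_over_a = b_over_a),
            class = "raman_tensor")
}

# Direction of a c-axis with polar angle theta (from lab z) and in-plane
# azimuth alpha measured from the lab y-axis (radians).
c_axis_dir <- function(theta, alpha) {
  c(sin(theta) * sin(alpha), sin(theta) * cos(alpha), cos(theta))
}

# Orthonormal frame carried by the mean axis: columns (e_theta, e_alpha, n)
mean_axis_frame <- function(theta, alpha) {
  st <- sin(theta); ct <- cos(theta); sa <- sin(alpha); ca <- cos(alpha)
  cbind(c(ct * sa, ct * ca, -st),
        c(ca, -sa, 0),
        c(st * sa, st * ca, ct))
}

#' Polarized nu1 intensity of a single crystallite
#'
#' For the uniaxial tensor `T = a I + (b - a) c c^T` (with `c` the unit
#' c-axis direction in the laboratory frame) the scattered intensity is
#' `I = (e_s . T e_i)^2 = (a (e_s . e_i) + (b - a)(e_s . c)(e_i . c))^2`.
#' The in-plane stage rotation `rot` adds to the azimuth `psi`, so the
#' intensity is periodic in `rot` with period 180 degrees.
#'
#' @param orient an [euler_orientation()].
#' @param cfg a [polarization_config()].
#' @param tensor a [raman_tensor()].
#' @param rot in-plane rotation angle(s), degrees.
#' @return Intensity vector (arbitrary units, >= 0), one value per `rot`.
#' @export
single_crystal_intensity <- function(orient, cfg, tensor, rot) {
  th <- deg2rad(orient$theta)
  al <- deg2rad(orient$psi + rot)
  a <- tensor$a; b <- tensor$b
  ese_i <- sum(cfg$e_s * cfg$e_i)
  vapply(al, function(alp) {
    cc <- c_axis_dir(th, alp)
    (a * ese_i + (b - a) * sum(cfg$e_s * cc) * sum(cfg$e_i * cc))^2
  }, numeric(1))
}

# Quadrature nodes for the orientation average: Gauss-Legendre in
# x = cos(beta) on [0, 1] and a uniform (trapezoidal, periodic) azimuth
# grid about the mean axis.
population_quadrature <- function(n_beta = 64, n_azimuth = 32) {
  gl <- pracma::gaussLegendre(n_beta, 0, 1)
  gamma <- seq(0, 2 * pi, length.out = n_azimuth + 1)[-(n_azimuth + 1)]
  x <- gl$x
  sb <- sqrt(pmax(0, 1 - x^2))
  # misoriented c-axis in the mean-axis frame, 3 x (n_beta * n_azimuth)
  U <- rbind(as.vector(outer(sb, cos(gamma))),
             as.vector(outer(sb, sin(gamma))),
             as.vector(outer(x, rep(1, n_azimuth))))
  list(x = x, w_beta = gl$w, U = U, n_beta = n_beta, n_azimuth = n_azimuth)
}

#' Polarized nu1 intensity of an ODF-distributed crystallite population
#'
#' Averages [single_crystal_intensity()] over crystallite misorientations
#' `(beta, gamma)` about the mean axis: `beta` weighted by the
#' maximum-entropy ODF `f(beta) sin(beta)`, the azimuth `gamma` uniform
#' (transversely isotropic population). The average uses Gauss-Legendre
#' quadrature in `cos(beta)` and a uniform periodic grid in `gamma`; node
#' counts are doubled once if the two resolutions disagree by more than
#' 1e-6 relative.
#'
#' @param orient an [euler_orientation()] for the mean axis.
#' @param odf an [odf_params()] (or list with `lambda2`, `lambda4`).
#' @param cfg a [polarization_config()].
#' @param tensor a [raman_tensor()].
#' @param rot vector of in-plane rotation angles, degrees (>= 2 values).
#' @param normalize divide by the curve maximum ("relative Raman
#'   intensity", default `TRUE`).
#' @param n_beta,n_azimuth quadrature orders (defaults 64 and 32).
#' @param check_convergence verify against doubled node counts.
#' @return Intensity vector over `rot`; normalized to max 1 when
#'   `normalize = TRUE`.
#' @export
population_intensity <- function(orient, odf, cfg, tensor, rot,
                                 normalize = TRUE, n_beta = 64,
                                 n_azimuth = 32, check_convergence = FALSE) {
  if (length(rot) < 2) stop("rot must hold at least 2 angles", call. = FALSE)
  ev <- function(nb, na) {
    q <- population_quadrature(nb, na)
    population_intensity_raw(orient, odf, cfg, tensor, rot, q)
  }
  out <- ev(n_beta, n_azimuth)
  if (check_convergence) {
    out2 <- ev(2 * n_beta, 2 * n_azimuth)
    rel <- max(abs(out - out2)) / max(abs(out2))
    if (rel > 1e-6) out <- out2
  }
  if (normalize) out <- out / max(out)
  out
}

population_intensity_raw <- function(orient, odf, cfg, tensor, rot, q) {
  lk <- odf_log_kernel(q$x, odf$lambda2, odf$lambda4)
  w <- exp(lk - max(lk)) * q$w_beta
  w <- rep(w, q$n_azimuth)
  w <- w / sum(w)
  th <- deg2rad(orient$theta)
  a <- tensor$a; b <- tensor$b
  ese_i <- sum(cfg$e_s * cfg$e_i)
  vapply(deg2rad(orient$psi + rot), function(alp) {
    Rm <- mean_axis_frame(th, alp)
    vi <- drop(crossprod(Rm, cfg$e_i))
    vs <- drop(crossprod(Rm, cfg$e_s))
    di <- drop(vi %*% q$U)
    ds <- drop(vs %*% q$U)
    sum(w * (a * ese_i + (b - a) * ds * di)^2)
  }, numeric(1))
}

#' Construct an angular intensity series
#'
#' @param angle in-plane rotation angles, degrees; should cover at least
#'   180 degrees for fitting.
#' @param intensity measured band intensities; stored normalized to the
#'   series maximum ("relative Raman intensity").
#' @param polarization `"parallel"` or `"cross"`.
#' @param z focal depth, micrometres.
#' @return An `angular_series` object.
#' @export
angular_series <- function(angle, intensity,
                           polarization = c("parallel", "cross"), z = 0) {
  polarization <- match.arg(polarization)
  if (length(angle) != length(intensity))
    stop("angle and intensity must have equal length", call. = FALSE)
  if (any(!is.finite(intensity)) || max(intensity) <= 0)
    stop("intensities must be finite with a positive maximum", call. = FALSE)
  structure(list(angle = as.numeric(angle),
                 intensity = as.numeric(intensity) / max(intensity),
                 polarization = polarization, z = z),
            class = "angular_series")
}

#' Fit polarized angular series with the ODF orientation model
#'
#' Joint nonlinear least squares of the parallel and cross rotation series
#' against [population_intensity()], over the mean-axis Euler angles
#' `(theta, psi)`, the ODF multipliers `(lambda2, lambda4)` and one free
#' scale per series (absorbing acquisition differences; each model curve,
#' like the data, is normalized to its own maximum first). Multi-start
#' over a theta grid and two psi candidates derived from the
#' parallel-series extremum; `psi` is reported wrapped into `(-90, 90]`
#' and Hermans moments are attached via [hermans_moments()].
#'
#' The tensor anisotropy `b/a` should normally be supplied
#' (`b_over_a` numeric): relative polarized intensities constrain only a
#' combination of tilt, ODF spread and tensor anisotropy, so with `b/a`
#' free the out-of-plane angle `theta` sits on a near-flat likelihood
#' ridge and is effectively unidentifiable from a single angular-series
#' pair — the practical workflow takes the nu1 tensor ratio from
#' single-crystal selection-rule calibrations and fits orientation and
#' ODF only. Passing `b_over_a = NULL` frees the ratio; the report then
#' carries `tensor_free = TRUE` and `theta` should be interpreted with
#' caution. When the fitted ODF is nearly isotropic (`P2 < 0.05`) the
#' Euler angles are unidentifiable and the report flags the degeneracy
#' instead of endorsing arbitrary angles.
#'
#' @param parallel,cross [angular_series()] objects of the two geometries
#'   (both required, >= 8 angles each, spanning >= 180 degrees minus one
#'   step).
#' @param b_over_a known tensor ratio (default 2.5, a typical apatite nu1
#'   anisotropy), or `NULL` to fit it.
#' @param init optional named list overriding start values (`theta`,
#'   `psi`, `lambda2`, `lambda4`, `b_over_a`).
#' @param n_beta,n_azimuth quadrature orders for the orientation average.
#' @param seed RNG seed for start jitter.
#' @return An `angular_fit`: list with `orientation`
#'   ([euler_orientation()]), `odf` ([odf_params()]), `tensor`
#'   ([raman_tensor()]), `scales`, `residual_rms`, `degenerate`,
#'   `tensor_free`, `converged`, `n_starts_tried`.
#' @export
fit_angular_series <- function(parallel, cross, b_over_a = 2.5, init = NULL,
                               n_beta = 64, n_azimuth = 32, seed = 1L) {
  if (is.null(parallel) || is.null(cross))
    stop("both parallel and cross series are required", call. = FALSE)
  stopifnot(inherits(parallel, "angular_series"),
            inherits(cross, "angular_series"))
  if (parallel$polarization != "parallel" || cross$polarization != "cross")
    stop("series polarization tags do not match their roles", call. = FALSE)
  if (length(parallel$angle) < 8 || length(cross$angle) < 8)
    stop("each series needs at least 8 angles", call. = FALSE)

  cfg_par <- polarization_config("parallel")
  cfg_cross <- polarization_config("cross")
  q <- population_quadrature(n_beta, n_azimuth)
  y <- c(parallel$intensity, cross$intensity)
  n_par <- length(parallel$angle)

  free_ba <- is.null(b_over_a)
  model <- function(p) {
    orient <- list(theta = p[1], psi = p[2])
    odf <- list(lambda2 = p[3], lambda4 = p[4])
    tensor <- list(a = 1, b = if (free_ba) p[5] else b_over_a)
    mp <- population_intensity_raw(orient, odf, cfg_par, tensor,
                                   parallel$angle, q)
    mc <- population_intensity_raw(orient, odf, cfg_cross, tensor,
                                   cross$angle, q)
    ns <- length(p)
    c(p[ns - 1] * mp / max(mp), p[ns] * mc / max(mc))
  }
  if (free_ba) {
    lower <- c(0, -180, -30, -30, 0.05, 0.2, 0.2)
    upper <- c(90, 180, 5, 5, 20, 5, 5)
  } else {
    lower <- c(0, -180, -30, -30, 0.2, 0.2)
    upper <- c(90, 180, 5, 5, 5, 5)
  }

  # data-driven psi starts: at the parallel-series extremum the incident
  # polarization aligns with the c-axis projection (b > a) or is normal
  # to it (b < a)
  psi_hat <- -parallel$angle[which.max(parallel$intensity)]
  starts <- list()
  for (th0 in c(15, 45, 75))
    for (ps0 in c(psi_hat, psi_hat + 90))
      starts[[length(starts) + 1]] <-
        if (free_ba) c(th0, wrap_psi(ps0), -4, -2, 2, 1, 1)
        else c(th0, wrap_psi(ps0), -4, -2, 1, 1)
  if (!is.null(init)) {
    ov <- c(theta = NA, psi = NA, lambda2 = NA, lambda4 = NA, b_over_a = NA)
    for (nm in names(init)) ov[nm] <- init[[nm]]
    s0 <- starts[[1]]
    npar <- if (free_ba) 5 else 4
    s0[1:npar] <- ifelse(is.na(ov[1:npar]), s0[1:npar], ov[1:npar])
    starts <- c(list(s0), starts)
  }

  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, lower, upper, function(p) model(p) - y,
                         control = minpack.lm::nls.lm.control(maxiter = 150)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rms <- sqrt(mean(fit$fvec^2))
    if (is.null(best) || rms < best$rms) best <- list(fit = fit, rms = rms)
    if (best$rms < 1e-10) break
  }
  if (is.null(best))
    stop("angular fit failed to converge from any start", call. = FALSE)

  p <- best$fit$par
  ns <- length(p)
  odf <- odf_params(p[3], p[4])
  # angles are unidentifiable when the fitted curves carry no angular
  # modulation: either a near-isotropic ODF, or a mean axis so close to
  # the canal axis that rotation changes nothing
  mhat <- model(p)
  mp <- mhat[seq_len(n_par)]
  mc <- mhat[-seq_len(n_par)]
  modulation <- max(diff(range(mp)) / max(mp), diff(range(mc)) / max(mc))
  # flat-model comparison: when per-series constants explain the data
  # almost as well, the angular information content is nil
  flat_rms <- sqrt(mean(c(parallel$intensity - mean(parallel$intensity),
                          cross$intensity - mean(cross$intensity))^2))
  degenerate <- odf$P2 < 0.05 || modulation < 0.02 ||
    flat_rms < 2 * best$rms
  structure(list(
    orientation = euler_orientation(p[1], p[2]),
    odf = odf,
    tensor = raman_tensor(if (free_ba) p[5] else b_over_a),
    scales = c(parallel = p[ns - 1], cross = p[ns]),
    residual_rms = best$rms,
    degenerate = degenerate,
    tensor_free = free_ba,
    converged = best$fit$info %in% 1:4,
    n_starts_tried = length(starts)), class = "angular_fit")
}

#' @export
print.angular_fit <- function(x, ...) {
  cat(sprintf("<angular_fit> theta = %.2f deg, psi = %.2f deg | lambda2 = %.2f, lambda4 = %.2f | P2 = %.3f, P4 = %.3f | b/a = %.2f | rms = %.3g\n",
              x$orientation$theta, x$orientation$psi, x$odf$lambda2,
              x$odf$lambda4, x$odf$P2, x$odf$P4, x$tensor$b_over_a,
              x$residual_rms))
  if (x$degenerate)
    cat("  note: near-isotropic ODF -- Euler angles unidentifiable\n")
  invisible(x)
}
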