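#' Legendre polynomials P2 and P4
#'
#' @param x argument, typically `cos(beta)`.
#' @return Polynomial values.
#' @keywords internal
#' @export
legendre_p2 <- function(x) (3 * x^2 - 1) / 2

#' @rdname legendre_p2
#' @export
legendre_p4 <- function(x) (35 * x^4 - 30 * x^2 + 3) / 8

# log of the unnormalized maximum-entropy ODF at x = cos(beta)
odf_log_kernel <- function(x, lambda2, lambda4) {
  -lambda2 * legendre_p2(x) - lambda4 * legendre_p4(x)
}

#' Maximum-entropy orientation distribution density
#'
#' The crystallite misorientation angle `beta` (between an individual
#' apatite c-axis and the population's mean axis) is modelled by the
#' maximum-entropy ODF
#' `f(beta) = A * exp(-lambda2 * P2(cos beta) - lambda4 * P4(cos beta))`,
#' with the normalization constant `A` chosen so that
#' `integral_0^{pi/2} f(beta) sin(beta) d(beta) = 1`. With this sign
#' convention, negative Lagrange multipliers produce alignment (density
#' peaked at `beta = 0`); strongly textured bone apatite shows multipliers
#' in the range of roughly -10 to 0.
#'
#' @param beta misorientation angle(s), radians, in `[0, pi/2]`.
#' @param lambda2,lambda4 Lagrange multipliers (dimensionless).
#' @return Density values `f(beta)` (per unit `sin(beta) d(beta)` measure).
#' @seealso [hermans_moments()], [odf_normalization()]
#' @export
odf_density <- function(beta, lambda2, lambda4 = 0) {
  A <- odf_normalization(lambda2, lambda4)
  x <- cos(beta)
  s <- max(odf_log_kernel(seq(0, 1, length.out = 2001), lambda2, lambda4))
  A$scaled * exp(odf_log_kernel(x, lambda2, lambda4) - s)
}

#' Normalization constant of the maximum-entropy ODF
#'
#' Returns `A = 1 / integral_0^{pi/2} exp(-lambda2 P2 - lambda4 P4) sin(beta) d(beta)`.
#' Because the exponent can be large, the integral is computed with the
#' maximum exponent subtracted; both the raw `A` and the overflow-safe
#' scaled version are returned.
#'
#' @inheritParams odf_density
#' @return List with `A` (raw constant), `scaled` (constant for the
#'   max-subtracted kernel) and `log_shift` (the subtracted maximum).
#' @export
odf_normalization <- function(lambda2, lambda4 = 0) {
  s <- max(odf_log_kernel(seq(0, 1, length.out = 2001), lambda2, lambda4))
  # substitute x = cos(beta): integral over beta with sin(beta) weight
  # becomes a plain integral over x in [0, 1]
  Z <- stats::integrate(function(x) exp(odf_log_kernel(x, lambda2, lambda4) - s),
                        0, 1, rel.tol = 1e-10, abs.tol = 1e-12)$value
  list(A = exp(-s) / Z, scaled = 1 / Z, log_shift = s)
}

#' Hermans orientation parameters of the maximum-entropy ODF
#'
#' Computes the ODF-averaged Legendre moments
#' `Pn<cos beta> = integral_0^1 Pn(x) f(x) dx / integral_0^1 f(x) dx`
#' with `f(x) = exp(-lambda2 P2(x) - lambda4 P4(x))`, by adaptive
#' quadrature (absolute tolerance below 1e-8). `P2<cos beta>` is the
#' primary Hermans parameter: 1 for perfect alignment of the crystallite
#' c-axes with the mean axis, 0 for an isotropic population, -0.5 for
#' perfect perpendicular alignment.
#'
#' @inheritParams odf_density
#' @return Named numeric vector `c(P2 = ..., P4 = ...)`.
#' @examples
#' hermans_moments(0, 0)        # isotropic: both moments 0
#' hermans_moments(-7, -8.5)    # strong alignment: P2 ~ 0.97
#' @export
hermans_moments <- function(lambda2, lambda4 = 0) {
  s <- max(odf_log_kernel(seq(0, 1, length.out = 2001), lambda2, lambda4))
  f <- function(x) exp(odf_log_kernel(x, lambda2, lambda4) - s)
  Z <- stats::integrate(f, 0, 1, rel.tol = 1e-10, abs.tol = 1e-12)$value
  m2 <- stats::integrate(function(x) legendre_p2(x) * f(x), 0, 1,
                         rel.tol = 1e-10, abs.tol = 1e-12)$value
  m4 <- stats::integrate(function(x) legendre_p4(x) * f(x), 0, 1,
                         rel.tol = 1e-10, abs.tol = 1e-12)$value
  c(P2 = m2 / Z, P4 = m4 / Z)
}

#' Bundle ODF parameters with their implied Hermans moments
#'
#' @inheritParams odf_density
#' @return An `odf_params` object: list with `lambda2`, `lambda4`, `A`
#'   (reciprocal normalization integral), `P2`, `P4`.
#' @export
odf_params <- function(lambda2, lambda4 = 0) {
  mom <- hermans_moments(lambda2, lambda4)
  structure(list(lambda2 = lambda2, lambda4 = lambda4,
                 A = odf_normalization(lambda2, lambda4)$A,
                 P2 = unname(mom["P2"]), P4 = unname(mom["P4"])),
            class = "odf_params")
}

#' @export
print.odf_params <- function(x, ...) {
  cat(sprintf("<odf_params> lambda2 = %g, lambda4 = %g | P2 = %.3f, P4 = %.3f, A = %.3g\n",
              x$lambda2, x$lambda4, x$P2, x$P4, x$A))
  invisible(x)
}
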