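# Independent oracles used across the suite. These deliberately avoid the
# package's own numerical paths: Monte-Carlo sampling instead of
# quadrature, dense Riemann sums instead of the anchored-grid convolution,
# closed forms where they exist.

# Monte-Carlo estimate of the Hermans moments: inverse-CDF sampling of
# x = cos(beta) from the density prop. to exp(-l2 P2(x) - l4 P4(x)) on
# [0, 1] (the sin(beta) solid-angle weight is absorbed by the x
# substitution). Returns estimates and their standard errors.
mc_hermans <- function(lambda2, lambda4, n = 1e6, seed = 1) {
  P2 <- function(x) (3 * x^2 - 1) / 2
  P4 <- function(x) (35 * x^4 - 30 * x^2 + 3) / 8
  grid <- seq(0, 1, length.out = 2^16 + 1)
  lk <- -lambda2 * P2(grid) - lambda4 * P4(grid)
  dens <- exp(lk - max(lk))
  cdf <- cumsum(dens)
  cdf <- (cdf - cdf[1]) / (cdf[length(cdf)] - cdf[1])
  set.seed(seed)
  u <- stats::runif(n)
  x <- stats::approx(cdf, grid, xout = u, ties = "ordered")$y
  p2 <- P2(x); p4 <- P4(x)
  list(P2 = mean(p2), P4 = mean(p4),
       se_P2 = stats::sd(p2) / sqrt(n), se_P4 = stats::sd(p4) / sqrt(n))
}

# Brute-force Monte-Carlo orientation average of the polarized intensity:
# draws crystallite axes about the mean direction and averages the
# single-crystal response, bypassing the package quadrature entirely.
mc_population_intensity <- function(orient, odf, cfg, tensor, rot,
                                    n = 1e5, seed = 1) {
  P2 <- function(x) (3 * x^2 - 1) / 2
  P4 <- function(x) (35 * x^4 - 30 * x^2 + 3) / 8
  grid <- seq(0, 1, length.out = 2^16 + 1)
  lk <- -odf$lambda2 * P2(grid) - odf$lambda4 * P4(grid)
  dens <- exp(lk - max(lk))
  cdf <- cumsum(dens); cdf <- (cdf - cdf[1]) / (cdf[length(cdf)] - cdf[1])
  set.seed(seed)
  cb <- stats::approx(cdf, grid, xout = stats::runif(n), ties = "ordered")$y
  sb <- sqrt(pmax(0, 1 - cb^2))
  gam <- stats::runif(n, 0, 2 * pi)
  U <- rbind(sb * cos(gam), sb * sin(gam), cb)
  th <- orient$theta * pi / 180
  a <- tensor$a; b <- tensor$b
  ese_i <- sum(cfg$e_s * cfg$e_i)
  vapply((orient$psi + rot) * pi / 180, function(alp) {
    st <- sin(th); ct <- cos(th); sa <- sin(alp); ca <- cos(alp)
    Rm <- cbind(c(ct * sa, ct * ca, -st), c(ca, -sa, 0),
                c(st * sa, st * ca, ct))
    C <- Rm %*% U
    di <- drop(cfg$e_i %*% C); ds <- drop(cfg$e_s %*% C)
    mean((a * ese_i + (b - a) * ds * di)^2)
  }, numeric(1))
}

# Dense mid-point quadrature of the Gaussian-probe convolution of a
# function on the real line (no anchored grid, no renormalization games).
quad_convolve <- function(fn, R, x0, halfwidth = 6 * R, n = 4001) {
  vapply(x0, function(x) {
    xs <- seq(x - halfwidth, x + halfwidth, length.out = n)
    w <- exp(-2 * (xs - x)^2 / R^2)
    sum(w * fn(xs)) / sum(w)
  }, numeric(1))
}

# smallest signed angular difference under the 180-degree director symmetry
wrap_delta <- function(d) {
  d <- (d + 90) %% 180 - 90
  ifelse(d == -90, 90, d)
}
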