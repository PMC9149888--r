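# Internal: an isolated RNG stream. Fitting routines use deterministic
# jitter without disturbing the caller's .Random.seed.
get_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  swap_in <- function(state) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    assign(".Random.seed", state, envir = globalenv())
    old
  }
  swap_out <- function(old) {
    env$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  swap_out(old)
  wrap <- function(fn) {
    force(fn)
    function(...) {
      old <- swap_in(env$state)
      on.exit(swap_out(old))
      fn(...)
    }
  }
  list(runif = wrap(stats::runif), rnorm = wrap(stats::rnorm),
       sample = wrap(base::sample))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Wrap an in-plane azimuth into (-90, 90]; the apatite c-axis is a
# director, so psi and psi + 180 are the same orientation.
wrap_psi <- function(psi) {
  p <- (psi + 90) %% 180 - 90
  p[p <= -90] <- p[p <= -90] + 180
  ifelse(p == -90, 90, p)
}
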