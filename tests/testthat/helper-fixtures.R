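# shared fixtures: fields, numeric differentiation

# smooth, band-limited test field (Gaussian envelope with a mild phase tilt)
band_limited_field <- function(n = 32, wl = 632.8e-9, pitch = wl, seed = 1) {
  withr::with_seed(seed, {
    xs <- seq(-1, 1, length.out = n)
    env <- exp(-outer(xs^2, xs^2, `+`) * 6)
    complex_field(env * exp(1i * 0.3 * outer(xs, xs)), pitch, wl)
  })
}

random_field <- function(n = 16, wl = 632.8e-9, pitch = wl, seed = 1) {
  withr::with_seed(seed, {
    v <- matrix(complex(
      real = rnorm(n^2), imaginary = rnorm(n^2)
    ), n, n)
    complex_field(v, pitch, wl)
  })
}

# central finite differences of a scalar function over a matrix argument
num_grad <- function(f, x, h = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x
    xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

max_rel_err <- function(a, b) max(abs(a - b)) / max(abs(b), 1e-12)
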