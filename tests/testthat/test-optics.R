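test_that("zero-distance propagation is the identity", {
  f <- band_limited_field(16)
  out <- propagate(f, 0)
  expect_identical(out$values, f$values)
})

test_that("a unit plane wave is an eigenfunction of free-space propagation", {
  wl <- 632.8e-9
  pw <- complex_field(matrix(1 + 0i, 32, 32), wl, wl)
  out <- propagate(pw, 100 * wl, pad = FALSE)
  expect_lt(max(abs(Mod(out$values) - 1)), 1e-10)
})

test_that("propagation conserves power for band-limited fields", {
  f <- band_limited_field(32)
  for (d in c(10, 40, 200) * f$wavelength) {
    out <- propagate(f, d, pad = FALSE)
    expect_lt(
      abs(field_power(out) - field_power(f)) / field_power(f), 1e-6
    )
  }
})

test_that("propagation satisfies the semigroup property", {
  f <- band_limited_field(32)
  d <- 40 * f$wavelength
  two_hops <- propagate(propagate(f, d, pad = FALSE), d, pad = FALSE)
  one_hop <- propagate(f, 2 * d, pad = FALSE)
  expect_lt(max_rel_err(two_hops$values, one_hop$values), 1e-6)
})

test_that("propagation is linear in the input field", {
  f1 <- random_field(16, seed = 1)
  f2 <- random_field(16, seed = 2)
  d <- 40 * f1$wavelength
  a <- 2.5 - 1i
  b <- -0.7 + 0.3i
  mix <- complex_field(a * f1$values + b * f2$values, f1$pitch, f1$wavelength)
  lhs <- propagate(mix, d)$values
  rhs <- a * propagate(f1, d)$values + b * propagate(f2, d)$values
  expect_lt(max_rel_err(lhs, rhs), 1e-6)
})

test_that("propagate validates its inputs", {
  f <- band_limited_field(16)
  expect_error(propagate(f, -1), "nonnegative")
  expect_error(complex_field(matrix(1 + 0i, 2, 3)), "square")
  expect_error(complex_field(matrix(1 + 0i, 4, 4), pitch = 0), "positive")
})

test_that("modulation multiplies by a unit-modulus phasor", {
  f <- random_field(16, seed = 3)
  expect_equal(modulate(f, matrix(0, 16, 16))$values, f$values)
  expect_equal(
    modulate(f, matrix(pi, 16, 16))$values, -f$values,
    tolerance = 1e-12
  )
  ph <- matrix(runif(256, -10, 10), 16, 16)
  out <- modulate(f, ph)
  expect_lt(max(abs(Mod(out$values) - Mod(f$values))), 1e-12)
  expect_error(modulate(f, matrix(0, 8, 8)), "shape")
})

test_that("phase-image encoding gives unit amplitude and phase pi*image", {
  img <- matrix(runif(256), 16, 16)
  f <- field_from_phase_image(img)
  expect_lt(max(abs(Mod(f$values) - 1)), 1e-12)
  expect_lt(max(abs(Arg(f$values) - pi * img)), 1e-12)
  expect_equal(
    field_from_phase_image(matrix(0, 4, 4))$values,
    matrix(1 + 0i, 4, 4)
  )
  expect_equal(
    field_from_phase_image(matrix(1, 4, 4))$values[1, 1], -1 + 0i,
    tolerance = 1e-12
  )
  expect_error(field_from_phase_image(matrix(1.2, 4, 4)), "\\[0, 1\\]")
})

test_that("fields round-trip through TIFF and JSON containers", {
  f <- random_field(8, seed = 9)
  tdir <- withr::local_tempdir()
  pt <- file.path(tdir, "field.tif")
  write_field_tiff(f, pt)
  back <- read_field_tiff(pt)
  expect_lt(max(abs(back$values - f$values)), 1e-6) # float-32 storage
  expect_equal(back$pitch, f$pitch)
  pj <- file.path(tdir, "field.json")
  write_field_json(f, pj)
  backj <- read_field_json(pj)
  expect_lt(max(abs(backj$values - f$values)), 1e-12)
})

test_that("propagation gradients match finite differences", {
  # real scalar loss of the propagated field; adjoint vs central differences
  n <- 8
  f <- random_field(n, seed = 4)
  d <- 40 * f$wavelength
  prop <- optiqat:::.make_propagator(n, f$pitch, f$wavelength, d, pad = TRUE)
  target <- matrix(runif(n^2), n, n)
  loss_of <- function(re_part) {
    v <- re_part + 1i * Im(f$values)
    out <- prop$forward(v)
    sum((Mod(out)^2 - target)^2)
  }
  out <- prop$forward(f$values)
  dLdI <- 2 * (Mod(out)^2 - target)
  g <- prop$adjoint(dLdI * out)
  analytic <- 2 * Re(g) # d/d(Re E_in) = 2 Re(dL/dE*)
  numeric <- num_grad(loss_of, Re(f$values), h = 1e-6)
  expect_lt(max_rel_err(analytic, numeric), 1e-6)
})
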