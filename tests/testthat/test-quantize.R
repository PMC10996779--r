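g4 <- quant_grid(0, 1.99 * pi, 4)

test_that("the 4-level phase grid reproduces the printed levels", {
  expect_equal(
    round(quant_levels(g4) / pi, 3),
    c(0, 0.663, 1.327, 1.990)
  )
  expect_equal(quant_levels(g4)[1], 0)
  expect_equal(quant_levels(g4)[4], 1.99 * pi)
  g2 <- quant_grid(0, pi, 2)
  expect_equal(quant_levels(g2), c(0, pi))
  expect_error(quant_grid(1, 1, 4), "exceed")
  expect_error(quant_grid(0, 1, 1), ">= 2")
})

test_that("hard quantization clamps and rounds to the nearest level", {
  expect_equal(hard_quantize(-1, g4), 0)
  expect_equal(hard_quantize(100, g4), 1.99 * pi)
  # 0.5*pi is nearer the second level than the first
  lev <- quant_levels(g4)
  nearest <- lev[which.min(abs(lev - 0.5 * pi))]
  expect_equal(hard_quantize(0.5 * pi, g4), nearest)
  expect_equal(nearest, 0.663 * pi, tolerance = 1e-3)
  # idempotence and membership on random inputs
  x <- withr::with_seed(1, runif(500, -2, 9))
  q <- hard_quantize(x, g4)
  expect_identical(hard_quantize(q, g4), q)
  expect_true(all(vapply(q, function(v) min(abs(lev - v)) < 1e-12, logical(1))))
})

test_that("psq collapses to the range midpoint as tau -> 0", {
  x <- c(-5, 0, 2, 9)
  expect_equal(
    psq(x, 1e-10, g4), rep((g4$l + g4$u) / 2, 4),
    tolerance = 1e-8
  )
  # single-transition grid: the transition midpoint maps to l + delta/2
  g2 <- quant_grid(0, 1, 2)
  expect_equal(psq(0.5, 500, g2), 0.5, tolerance = 1e-9)
})

test_that("psq is strictly monotone and bounded in (l, u)", {
  x <- withr::with_seed(2, sort(runif(400, -3, 10)))
  for (tau in c(0.5, 3)) {
    y <- psq(x, tau, g4)
    expect_true(all(diff(y) > 0))
    expect_true(all(y > g4$l & y < g4$u))
  }
  # at high temperature the sigmoids saturate to machine precision, so the
  # strict ordering degrades to nondecreasing within the bounds
  y30 <- psq(x, 30, g4)
  expect_true(all(diff(y30) >= 0))
  expect_true(all(y30 >= g4$l & y30 <= g4$u))
})

test_that("psq approaches hard quantization away from transitions as tau grows", {
  x <- seq(-0.5, 2 * pi + 0.5, by = 0.011)
  trans <- g4$l + g4$delta / 2 + (0:2) * g4$delta
  away <- vapply(
    x, function(v) all(abs(v - trans) >= 0.05 * g4$delta), logical(1)
  )
  gap <- function(tau) {
    max(abs(psq(x[away], tau, g4) - hard_quantize(x[away], g4)))
  }
  taus <- c(2, 5, 10, 20, 50, 200 / g4$delta, 500 / g4$delta)
  gaps <- vapply(taus, gap, numeric(1))
  expect_true(all(diff(gaps) < 0)) # sup-norm distance monotone in tau
  expect_lt(gap(200 / g4$delta), 0.01 * g4$delta)
})

test_that("psq is odd-symmetric about the range center", {
  x <- withr::with_seed(3, runif(100, -2, 9))
  for (tau in c(1, 7)) {
    expect_equal(
      psq(g4$l + g4$u - x, tau, g4),
      g4$l + g4$u - psq(x, tau, g4),
      tolerance = 1e-10
    )
  }
})

test_that("psq analytic gradients match central differences", {
  x <- withr::with_seed(4, runif(40, -1, 8))
  for (tau in c(0.5, 5, 50)) {
    g <- psq_grad(x, tau, g4)
    num_dx <- (psq(x + 1e-6, tau, g4) - psq(x - 1e-6, tau, g4)) / 2e-6
    expect_lt(max_rel_err(g$dx, num_dx), 1e-5)
    num_dtau <- (psq(x, tau + 1e-6, g4) - psq(x, tau - 1e-6, g4)) / 2e-6
    expect_lt(max_rel_err(g$dtau, num_dtau), 1e-5)
  }
  expect_error(psq(1, -1, g4), "positive")
  expect_error(psq_grad(1, 0, g4), "positive")
})

test_that("psq stays finite for extreme arguments", {
  expect_true(all(is.finite(psq(c(-1e4, 1e4), 1000, g4))))
  expect_true(all(is.finite(psq_grad(c(-1e4, 1e4), 1000, g4)$dx)))
})

test_that("dsq fixes endpoints, cell midpoints, and clamps outside the range", {
  expect_equal(dsq(g4$l, 2, g4), g4$l, tolerance = 1e-12)
  expect_equal(dsq(g4$u, 2, g4), g4$u, tolerance = 1e-12)
  mids <- g4$l + (0:2 + 0.5) * g4$delta
  expect_equal(dsq(mids, 3, g4), mids, tolerance = 1e-10)
  expect_equal(dsq(c(-10, 100), 3, g4), c(g4$l, g4$u))
  # interior level points map to themselves in the large-tau limit
  lev <- quant_levels(g4)
  expect_equal(dsq(lev, 80, g4), lev, tolerance = 1e-6)
  # large-tau agreement with hard quantization away from transitions
  x <- seq(0, 1.99 * pi, by = 0.013)
  trans <- g4$l + g4$delta / 2 + (0:2) * g4$delta
  away <- vapply(
    x, function(v) all(abs(v - trans) >= 0.1 * g4$delta), logical(1)
  )
  expect_lt(
    max(abs(dsq(x[away], 60, g4) - hard_quantize(x[away], g4))),
    0.01 * g4$delta
  )
})

test_that("dsq analytic gradient matches central differences inside cells", {
  x <- withr::with_seed(5, runif(40, 0.05, 1.99 * pi - 0.05))
  for (tau in c(1, 8)) {
    num <- (dsq(x + 1e-7, tau, g4) - dsq(x - 1e-7, tau, g4)) / 2e-7
    expect_lt(max_rel_err(dsq_grad(x, tau, g4), num), 1e-4)
  }
  expect_equal(dsq_grad(c(-5, 20), 2, g4), c(0, 0))
})

test_that("ste forward equals hard quantization with an identity Jacobian", {
  x <- withr::with_seed(6, matrix(runif(64, -1, 8), 8, 8))
  expect_identical(ste_quantize(x, g4), hard_quantize(x, g4))
  expect_identical(ste_grad(x, g4), x * 0 + 1)
})

test_that("gumbel quantization is a convex combination of levels", {
  x <- withr::with_seed(7, matrix(runif(64, 0, 2 * pi), 8, 8))
  r <- gumbel_quantize(x, temperature = 5, g4, seed = 11)
  expect_true(all(r$value >= g4$l & r$value <= g4$u))
  # determinism under a fixed seed
  r2 <- gumbel_quantize(x, temperature = 5, g4, seed = 11)
  expect_identical(r$value, r2$value)
  # zero noise + vanishing temperature -> nearest level (away from the
  # transition midpoints, where the relaxation mixes the two nearest levels)
  trans <- g4$l + g4$delta / 2 + (0:2) * g4$delta
  away <- apply(abs(outer(as.vector(x), trans, `-`)) >= 0.05 * g4$delta, 1, all)
  r0 <- gumbel_quantize(as.vector(x)[away], temperature = 1e-3, g4, noise = 0)
  expect_equal(r0$value, hard_quantize(as.vector(x)[away], g4), tolerance = 1e-6)
  # gradient (noise held fixed) matches finite differences
  xv <- as.vector(x)[1:10]
  rg <- gumbel_quantize(xv, 2, g4, noise = 0)
  num <- (gumbel_quantize(xv + 1e-6, 2, g4, noise = 0)$value -
    gumbel_quantize(xv - 1e-6, 2, g4, noise = 0)$value) / 2e-6
  expect_lt(max_rel_err(rg$dx, num), 1e-5)
  expect_error(gumbel_quantize(x, 0, g4), "positive")
})

test_that("phase wrapping maps into [0, 2*pi)", {
  expect_equal(wrap_phase(2 * pi), 0)
  expect_equal(wrap_phase(-0.5 * pi), 1.5 * pi)
  x <- withr::with_seed(8, runif(100, -20, 20))
  w <- wrap_phase(x)
  expect_true(all(w >= 0 & w < 2 * pi))
  expect_lt(max(abs(exp(1i * w) - exp(1i * x))), 1e-12)
})

test_that("post-quantization puts every phase on the level grid", {
  model <- d2nn(n_layers = 2, grid_size = 8, quant_kind = "fp", seed = 10)
  model$phi[[1]] <- model$phi[[1]] + 5 # push some phases out of one cycle
  pq <- post_quantize(model, g4)
  lev <- quant_levels(g4)
  for (p in pq$phi) {
    expect_true(all(vapply(
      as.vector(p), function(v) min(abs(lev - v)) < 1e-9, logical(1)
    )))
  }
  # idempotent on an already-quantized model
  pq2 <- post_quantize(pq, g4)
  expect_equal(pq2$phi, pq$phi, tolerance = 1e-12)
  # and its output differs from the FP model's for a generic model
  img <- withr::with_seed(11, matrix(runif(64), 8, 8))
  f <- field_from_phase_image(img)
  i_fp <- detector_intensity(d2nn_forward(model, f))
  i_pq <- detector_intensity(d2nn_forward(pq, f))
  expect_gt(mean((i_fp - i_pq)^2), 0)
})
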