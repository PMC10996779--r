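test_that("a trivial one-layer network is the identity", {
  m <- d2nn(
    n_layers = 1, grid_size = 16, d_in = 0, d_layer = 0, d_out = 0,
    quant_kind = "fp", init = "zero"
  )
  f <- random_field(16, seed = 1)
  out <- d2nn_forward(m, f)
  expect_equal(out$values, f$values, tolerance = 1e-12)
})

test_that("pass-through quantization equals a quantizer-free stack", {
  m <- d2nn(n_layers = 3, grid_size = 16, quant_kind = "fp", seed = 2)
  img <- withr::with_seed(3, matrix(runif(256), 16, 16))
  f <- field_from_phase_image(img)
  out <- d2nn_forward(m, f)
  # hand-built composition with the raw phases
  props <- optiqat:::.d2nn_props(m)
  E <- props$p_in$forward(f$values)
  for (n in 1:3) {
    prop <- if (n == 3) props$p_out else props$p_mid
    E <- prop$forward(E * exp(1i * m$phi[[n]]))
  }
  expect_equal(out$values, E, tolerance = 1e-12)
})

test_that("forward is deterministic and intensity nonnegative", {
  m <- d2nn(n_layers = 2, grid_size = 16, quant_kind = "psq", tau = 4, seed = 4)
  img <- withr::with_seed(5, matrix(runif(256), 16, 16))
  f <- field_from_phase_image(img)
  i1 <- detector_intensity(d2nn_forward(m, f))
  i2 <- detector_intensity(d2nn_forward(m, f))
  expect_identical(i1, i2)
  expect_true(all(i1 >= 0))
  expect_error(d2nn_forward(m, random_field(8)), "grid")
})

test_that("detector intensity is |E|^2 with the expected identities", {
  f <- random_field(16, seed = 6)
  I <- detector_intensity(f)
  expect_equal(I, Mod(f$values)^2)
  f2 <- complex_field(2 * f$values, f$pitch, f$wavelength)
  expect_equal(detector_intensity(f2), 4 * I, tolerance = 1e-12)
  expect_equal(sum(I) * f$pitch^2, field_power(f))
  pw <- complex_field(matrix(1 + 0i, 8, 8))
  expect_equal(detector_intensity(pw), matrix(1, 8, 8))
})

test_that("patch readout classifies by highest mean patch intensity", {
  ro <- patch_readout(32)
  expect_length(ro$patches, 10)
  # patches are disjoint and inside the grid
  occupancy <- matrix(0, 32, 32)
  for (p in ro$patches) {
    expect_true(all(p$rows >= 1 & p$rows <= 32))
    expect_true(all(p$cols >= 1 & p$cols <= 32))
    occupancy[p$rows, p$cols] <- occupancy[p$rows, p$cols] + 1
  }
  expect_lte(max(occupancy), 1)
  # light concentrated on patch 3 -> class 3
  I <- matrix(0, 32, 32)
  p3 <- ro$patches[[4]]
  I[p3$rows, p3$cols] <- 1
  expect_equal(classify_intensity(I, ro), 3L)
  expect_equal(classify_intensity(5 * I, ro), 3L) # scale invariance
  # uniform intensity -> tie broken to class 0
  expect_equal(classify_intensity(matrix(1, 32, 32), ro), 0L)
})

test_that("label maps are 1 exactly on the class patch", {
  ro <- patch_readout(32)
  Y <- label_map(7, ro)
  p <- ro$patches[[8]]
  expect_equal(sum(Y), length(p$rows) * length(p$cols))
  expect_true(all(Y[p$rows, p$cols] == 1))
  expect_error(label_map(10, ro), "range")
})

test_that("full-model gradients flow through psq but not hard quantization", {
  img <- withr::with_seed(7, matrix(runif(64), 8, 8))
  f <- field_from_phase_image(img)
  target <- img
  grad_norm <- function(kind, tau = 4) {
    m <- d2nn(n_layers = 2, grid_size = 8, quant_kind = kind, tau = tau, seed = 8)
    props <- optiqat:::.d2nn_props(m)
    cache <- optiqat:::.d2nn_forward_cache(m, f$values, props)
    I <- Mod(cache$out)^2
    g <- optiqat:::.d2nn_backward(
      m, cache, berhu_loss_grad(I, target, 0.1), props
    )
    max(abs(g$dphi[[1]]))
  }
  expect_gt(grad_norm("psq"), 1e-8)
  expect_equal(grad_norm("hard"), 0)
})

test_that("checkpoints round-trip through JSON", {
  m <- d2nn(n_layers = 2, grid_size = 8, quant_kind = "psq", tau = c(2, 3), seed = 9)
  m$k <- c(0.4, 0.2)
  m$gamma <- 0.05
  tdir <- withr::local_tempdir()
  p <- file.path(tdir, "ckpt.json")
  save_checkpoint(m, p)
  back <- load_checkpoint(p)
  expect_equal(back$phi, m$phi, tolerance = 1e-12)
  expect_equal(back$tau, m$tau)
  expect_equal(back$k, m$k)
  expect_equal(back$quant$grid$u, m$quant$grid$u)
  f <- random_field(8, seed = 10)
  expect_equal(
    d2nn_forward(back, f)$values, d2nn_forward(m, f)$values,
    tolerance = 1e-12
  )
})

test_that("exported masks lie on the level grid", {
  g4 <- quant_grid(0, 1.99 * pi, 4)
  m <- d2nn(n_layers = 2, grid_size = 8, quant_kind = "psq", grid = g4, seed = 11)
  tdir <- withr::local_tempdir()
  manifest <- export_masks(m, tdir)
  lev <- quant_levels(g4)
  masks <- effective_phases(m, mode = "deploy")
  for (p in masks) {
    expect_true(all(vapply(
      as.vector(p), function(v) min(abs(lev - v)) < 1e-9, logical(1)
    )))
  }
  idx <- as.matrix(utils::read.csv(
    file.path(tdir, "layer01_levels.csv"),
    header = FALSE
  ))
  expect_true(all(idx %in% 0:3))
  expect_equal(lev[idx + 1], as.vector(masks[[1]]), tolerance = 1e-9)
})
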