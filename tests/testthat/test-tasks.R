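test_that("weighted classification loss matches hand evaluation", {
  # 2x2 toy: one wrongly lit pixel outside the target, one dark target pixel
  Y <- matrix(c(1, 0, 0, 0), 2, 2)
  I <- matrix(c(0, 1, 0, 0), 2, 2)
  expect_equal(
    classification_loss(Y, I, c_w = 10 / 11),
    (1 * (1 / 11) + 1 * 1) / 4
  )
  expect_equal(classification_loss(Y, I, c_w = 10 / 11), 3 / 11, tolerance = 1e-12)
  # c_w = 0 reduces to plain MSE
  expect_equal(classification_loss(Y, I, c_w = 0), mean((Y - I)^2))
  # perfect prediction -> zero
  expect_equal(classification_loss(Y, Y), 0)
  expect_error(classification_loss(Y, matrix(0, 3, 3)), "shape")
})

test_that("classification loss gradient matches central differences", {
  withr::with_seed(1, {
    Y <- label_map(2, patch_readout(8, rows = 2, cols = 5))
    I <- matrix(runif(64), 8, 8)
  })
  g <- classification_loss_grad(Y, I)
  num <- num_grad(function(v) classification_loss(Y, v), I, h = 1e-6)
  expect_lt(max_rel_err(g, num), 1e-6)
})

test_that("berHu loss branches agree at the threshold and evaluate correctly", {
  one <- function(e, c) berhu_loss(matrix(e, 1, 1), matrix(0, 1, 1), c)
  c <- 0.3
  expect_equal(one(c, c), c) # both branches give c
  expect_equal(one(2 * c, c), 2.5 * c) # quadratic branch: (4c^2+c^2)/(2c)
  expect_equal(one(0.5 * c, c), 0.5 * c) # linear branch
  expect_equal(berhu_loss(matrix(1, 4, 4), matrix(1, 4, 4), 0.2), 0)
  expect_error(berhu_loss(matrix(1, 2, 2), matrix(0, 2, 2), c = 0), "positive")
  expect_error(berhu_loss(matrix(1, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("berHu gradient matches finite differences and is continuous at |e| = c", {
  withr::with_seed(2, {
    target <- matrix(runif(36), 6, 6)
    pred <- target + matrix(rnorm(36, 0, 0.3), 6, 6)
  })
  c <- 0.2
  g <- berhu_loss_grad(pred, target, c)
  num <- num_grad(function(v) berhu_loss(v, target, c), pred, h = 1e-7)
  expect_lt(max_rel_err(g, num), 1e-5)
  # continuity of the derivative across the branch point
  eps <- 1e-9
  gm <- berhu_loss_grad(matrix(c - eps, 1, 1), matrix(0, 1, 1), c)
  gp <- berhu_loss_grad(matrix(c + eps, 1, 1), matrix(0, 1, 1), c)
  expect_lt(abs(gm - gp), 1e-7)
})

test_that("adaptive berHu threshold follows the max-residual convention", {
  pred <- matrix(c(0, 0.5), 1, 2)
  target <- matrix(0, 1, 2)
  expect_equal(berhu_threshold(pred, target), 0.1)
  expect_equal(berhu_threshold(target, target), 1e-3) # degenerate fallback
})

test_that("losses are nonnegative and zero only at the target", {
  withr::with_seed(3, {
    a <- matrix(runif(64), 8, 8)
    b <- matrix(runif(64), 8, 8)
  })
  expect_gt(berhu_loss(a, b, 0.2), 0)
  expect_gt(classification_loss(round(a), b), 0)
  expect_equal(berhu_loss(a, a, 0.2), 0)
})
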