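test_that("generated images are bounded, sized and reproducible", {
  for (kind in c("blob", "digit_like", "rbc_like", "flat", "checker")) {
    b <- synth_phase_objects(6, kind, size = 24, seed = 5)
    expect_equal(nrow(b), 6)
    for (img in b$image) {
      expect_equal(dim(img), c(24, 24))
      expect_true(all(img >= 0 & img <= 1))
    }
    b2 <- synth_phase_objects(6, kind, size = 24, seed = 5)
    expect_identical(b$image, b2$image)
    b3 <- synth_phase_objects(6, kind, size = 24, seed = 6)
    if (kind %in% c("blob", "digit_like", "rbc_like")) {
      expect_false(identical(b$image, b3$image))
    }
  }
  expect_error(synth_phase_objects(3, "nope"), "arg")
})

test_that("flat and checker controls are analytic", {
  f <- synth_phase_objects(1, "flat", size = 16, value = 0.25)$image[[1]]
  expect_equal(f, matrix(0.25, 16, 16))
  ck <- synth_phase_objects(1, "checker", size = 16, block = 4)$image[[1]]
  expect_setequal(unique(as.vector(ck)), c(0, 1))
  expect_equal(ck[1, 1], ck[1, 9]) # period 2 blocks
  expect_equal(ck[1, 1], 1 - ck[1, 5])
})

test_that("rbc-like objects have a bright rim and a central dip", {
  b <- synth_phase_objects(8, "rbc_like", size = 48, seed = 9)
  for (img in b$image) {
    expect_equal(min(img), 0) # background
    expect_lte(max(img), 1)
    peak <- which(img == max(img), arr.ind = TRUE)[1, ]
    # the maximum (rim) must not sit at the cell center: the center is dipped
    center <- which(img > 0, arr.ind = TRUE)
    cr <- mean(range(center[, 1]))
    cc <- mean(range(center[, 2]))
    rim_r <- sqrt((peak[1] - cr)^2 + (peak[2] - cc)^2)
    expect_gt(rim_r, 2) # rim peak is off-center
    # center value below rim value
    expect_lt(img[round(cr), round(cc)], max(img))
  }
})

test_that("digit-like classes are separable by a nearest-centroid classifier", {
  train <- synth_phase_objects(200, "digit_like", size = 24, seed = 21)
  test <- synth_phase_objects(100, "digit_like", size = 24, seed = 22)
  flat <- function(b) t(vapply(b$image, as.vector, numeric(24^2)))
  Xtr <- flat(train)
  Xte <- flat(test)
  centroids <- vapply(
    0:9,
    function(d) colMeans(Xtr[train$label == d, , drop = FALSE]),
    numeric(24^2)
  )
  pred <- apply(Xte, 1, function(v) {
    which.min(colSums((centroids - v)^2)) - 1L
  })
  acc <- mean(pred == test$label)
  expect_gt(acc, 0.6)
})

test_that("phase-object folders round-trip through TIFF + manifest", {
  b <- synth_phase_objects(4, "digit_like", size = 16, seed = 3)
  tdir <- withr::local_tempdir()
  write_phase_objects(b, tdir)
  back <- read_phase_objects(tdir)
  expect_equal(back$label, b$label)
  for (i in 1:4) {
    expect_lt(max(abs(back$image[[i]] - b$image[[i]])), 1e-6)
  }
})
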