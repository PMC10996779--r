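#' Synthetic phase objects
#'
#' Generates smooth grayscale images in `[0, 1]` that emulate the phase
#' objects the optical tasks consume once mapped to phase via
#' [field_from_phase_image()] (phase range `[0, pi]`, unit amplitude):
#'
#' * `"blob"` — band-limited Gaussian random fields, min-max normalized:
#'   generic smooth phase specimens for the quantitative-phase-imaging task.
#' * `"digit_like"` — ten stroke-built digit archetypes (lines/arcs) with
#'   random affine jitter and additive noise; carries a class label `0..9`,
#'   a download-free stand-in for handwritten-digit phase objects.
#' * `"rbc_like"` — biconcave disk with a bright rim and central dip at a
#'   random position and radius, the morphology of a red blood cell in
#'   quantitative phase imaging.
#' * `"flat"` — constant image (analytic control).
#' * `"checker"` — checkerboard (analytic control).
#'
#' @param n Number of images, `>= 1`.
#' @param kind One of `"blob"`, `"digit_like"`, `"rbc_like"`, `"flat"`,
#'   `"checker"`.
#' @param size Image side in pixels.
#' @param seed Integer seed; batches are reproducible per seed.
#' @param value Constant level for `"flat"`.
#' @param block Block side in pixels for `"checker"`.
#' @param smooth Correlation scale for `"blob"`, as a fraction of the side.
#' @return Tibble with columns `id`, `kind`, `label` (integer `0..9` for
#'   `digit_like`, `NA` otherwise) and `image` (list of `size x size`
#'   matrices in `[0, 1]`).
#' @examples
#' batch <- synth_phase_objects(4, "rbc_like", size = 32, seed = 7)
#' range(batch$image[[1]])
#' @export
synth_phase_objects <- function(n, kind = c(
                                  "blob", "digit_like", "rbc_like",
                                  "flat", "checker"
                                ),
                                size = 32L, seed = 1L, value = 0.5,
                                block = 4L, smooth = 0.15) {
  kind <- match.arg(kind)
  stopifnot(n >= 1, size >= 8)
  withr::with_seed(as.integer(seed), {
    labels <- rep(NA_integer_, n)
    imgs <- vector("list", n)
    for (i in seq_len(n)) {
      imgs[[i]] <- switch(kind,
        flat = matrix(value, size, size),
        checker = .synth_checker(size, block),
        blob = .synth_blob(size, smooth),
        rbc_like = .synth_rbc(size),
        digit_like = {
          labels[i] <- (i - 1L) %% 10L
          .synth_digit(size, labels[i])
        }
      )
    }
    tibble::tibble(
      id = seq_len(n), kind = kind, label = labels, image = imgs
    )
  })
}

.synth_checker <- function(size, block) {
  idx <- (seq_len(size) - 1L) %/% block
  (outer(idx, idx, `+`) %% 2L) * 1.0
}

# compact smooth specimens: a few Gaussian bumps on a dark background with
# mild band-limited texture, the generic stand-in for sparse phase objects
.synth_blob <- function(size, smooth) {
  xs <- (seq_len(size) - 0.5) / size
  img <- matrix(0, size, size)
  n_bumps <- sample(2:5, 1)
  for (b in seq_len(n_bumps)) {
    cx <- stats::runif(1, 0.2, 0.8)
    cy <- stats::runif(1, 0.2, 0.8)
    sg <- stats::runif(1, 0.08, 0.18)
    amp <- stats::runif(1, 0.5, 1)
    img <- img + amp * exp(-outer((xs - cy)^2, (xs - cx)^2, `+`) / (2 * sg^2))
  }
  # low-pass random texture modulating the bumps
  z <- matrix(stats::rnorm(size^2), size, size)
  k <- 0:(size - 1L)
  f <- ifelse(k < size / 2, k, k - size) / size
  filt <- exp(-outer(f^2, f^2, `+`) / (2 * (smooth / 2)^2))
  tex <- Re(stats::fft(stats::fft(z) * filt, inverse = TRUE)) / size^2
  tex <- tex / max(abs(tex), 1e-12)
  img <- img * (1 + 0.2 * tex)
  pmin(pmax(img / max(img), 0), 1)
}

# biconcave disk: thickness profile sqrt(1-u^2)(a + b u^2), rim brighter
# than the center dip, zero background
.synth_rbc <- function(size) {
  cx <- 0.5 + stats::runif(1, -0.12, 0.12)
  cy <- 0.5 + stats::runif(1, -0.12, 0.12)
  R <- stats::runif(1, 0.22, 0.35)
  xs <- (seq_len(size) - 0.5) / size
  u <- sqrt(outer((xs - cy)^2, (xs - cx)^2, `+`)) / R
  prof <- ifelse(u <= 1, sqrt(pmax(0, 1 - u^2)) * (0.4 + 1.6 * u^2), 0)
  img <- prof / max(prof)
  pmin(pmax(img, 0), 1)
}

# stroke sets in the unit square per digit archetype; (x1,y1,x2,y2) segments
# and (cx,cy,r,a0,a1) arcs (angles ccw from +x, radians)
.digit_strokes <- function(d) {
  seg <- function(...) list(type = "seg", p = c(...))
  arc <- function(...) list(type = "arc", p = c(...))
  switch(as.character(d),
    "0" = list(arc(0.5, 0.5, 0.28, 0, 2 * pi)),
    "1" = list(seg(0.5, 0.15, 0.5, 0.85), seg(0.38, 0.3, 0.5, 0.15)),
    "2" = list(
      arc(0.5, 0.32, 0.18, pi, 2 * pi + pi / 2),
      seg(0.66, 0.42, 0.3, 0.85), seg(0.3, 0.85, 0.72, 0.85)
    ),
    "3" = list(
      arc(0.47, 0.32, 0.17, pi * 0.8, 2 * pi + pi / 2),
      arc(0.47, 0.67, 0.18, 1.5 * pi, 2 * pi + 1.2 * pi)
    ),
    "4" = list(
      seg(0.62, 0.15, 0.62, 0.85), seg(0.62, 0.15, 0.28, 0.6),
      seg(0.28, 0.6, 0.78, 0.6)
    ),
    "5" = list(
      seg(0.68, 0.15, 0.35, 0.15), seg(0.35, 0.15, 0.33, 0.48),
      arc(0.48, 0.64, 0.2, pi * 0.9, 2 * pi + pi * 0.6)
    ),
    "6" = list(
      arc(0.48, 0.64, 0.2, 0, 2 * pi),
      arc(0.62, 0.35, 0.42, pi * 0.55, pi * 0.95)
    ),
    "7" = list(seg(0.28, 0.15, 0.72, 0.15), seg(0.72, 0.15, 0.42, 0.85)),
    "8" = list(
      arc(0.5, 0.31, 0.16, 0, 2 * pi), arc(0.5, 0.67, 0.2, 0, 2 * pi)
    ),
    "9" = list(
      arc(0.52, 0.36, 0.2, 0, 2 * pi),
      arc(0.38, 0.65, 0.42, -pi * 0.45, -pi * 0.05)
    ),
    stop("no archetype for digit ", d)
  )
}

.dist_seg <- function(px, py, s) {
  x1 <- s[1]; y1 <- s[2]; x2 <- s[3]; y2 <- s[4]
  vx <- x2 - x1; vy <- y2 - y1
  L2 <- vx^2 + vy^2
  t <- pmin(pmax(((px - x1) * vx + (py - y1) * vy) / L2, 0), 1)
  sqrt((px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2)
}

.dist_arc <- function(px, py, a) {
  cx <- a[1]; cy <- a[2]; r <- a[3]; a0 <- a[4]; a1 <- a[5]
  dx <- px - cx; dy <- py - cy
  rho <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx)
  # inside the angular span (mod 2 pi)?
  span <- (ang - a0) %% (2 * pi) <= ((a1 - a0) %% (2 * pi)) | (a1 - a0) >= 2 * pi
  d_on <- abs(rho - r)
  e0 <- sqrt((px - (cx + r * cos(a0)))^2 + (py - (cy + r * sin(a0)))^2)
  e1 <- sqrt((px - (cx + r * cos(a1)))^2 + (py - (cy + r * sin(a1)))^2)
  ifelse(span, d_on, pmin(e0, e1))
}

.synth_digit <- function(size, digit, stroke_w = 0.045) {
  strokes <- .digit_strokes(digit)
  # random affine jitter: rotation, isotropic scale, translation
  th <- stats::runif(1, -0.12, 0.12)
  sc <- stats::runif(1, 0.9, 1.1)
  tx <- stats::runif(1, -0.04, 0.04)
  ty <- stats::runif(1, -0.04, 0.04)
  xs <- (seq_len(size) - 0.5) / size
  # pixel (row=y, col=x); inverse-map pixel coords into archetype frame
  PX <- matrix(rep(xs, each = size), size, size) # col -> x
  PY <- matrix(rep(xs, times = size), size, size) # row -> y
  qx <- (cos(-th) * (PX - 0.5 - tx) - sin(-th) * (PY - 0.5 - ty)) / sc + 0.5
  qy <- (sin(-th) * (PX - 0.5 - tx) + cos(-th) * (PY - 0.5 - ty)) / sc + 0.5
  d <- matrix(Inf, size, size)
  for (s in strokes) {
    ds <- if (s$type == "seg") {
      .dist_seg(qx, qy, s$p)
    } else {
      .dist_arc(qx, qy, s$p)
    }
    d <- pmin(d, ds)
  }
  img <- exp(-(d / stroke_w)^2)
  img <- img + matrix(stats::rnorm(size^2, 0, 0.02), size, size)
  pmin(pmax(img / max(img), 0), 1)
}

#' Write a synthetic batch to disk
#'
#' Saves each image as a float TIFF plus a CSV manifest (`id`, `kind`,
#' `label`, `file`), mirroring how an imaging dataset would arrive on disk.
#'
#' @param batch Tibble from [synth_phase_objects()].
#' @param dir Output directory (created if missing).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_phase_objects <- function(batch, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(nrow(batch))
  for (i in seq_len(nrow(batch))) {
    files[i] <- file.path(dir, sprintf("%s_%04d.tif", batch$kind[i], batch$id[i]))
    tiff::writeTIFF(batch$image[[i]], files[i], bits.per.sample = 32L)
  }
  manifest <- dplyr::mutate(dplyr::select(batch, -"image"), file = files)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a phase-object folder written by [write_phase_objects()]
#'
#' @param dir Directory containing `manifest.csv` and the TIFF images.
#' @return Tibble in the same shape as [synth_phase_objects()] output.
#' @export
read_phase_objects <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  tibble::tibble(
    id = manifest$id,
    kind = manifest$kind,
    label = as.integer(manifest$label),
    image = lapply(manifest$file, function(f) {
      m <- tiff::readTIFF(f)
      if (length(dim(m)) == 3L) m <- m[, , 1L]
      m
    })
  )
}
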