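#' Structural similarity index (SSIM)
#'
#' The standard single-scale SSIM with an 11 x 11 Gaussian window
#' (sigma = 1.5) and stabilizers `C1 = (0.01 * L)^2`, `C2 = (0.03 * L)^2`
#' for data range `L`. Local means, variances and covariance are Gaussian-
#' weighted (population form, no sample-size correction) and the SSIM map is
#' averaged over the valid region — pixels whose window lies fully inside the
#' image.
#'
#' @param x,y Real matrices of equal shape, at least 11 x 11.
#' @param data_range Dynamic range `L` of the data (1 for images in `[0, 1]`).
#' @param win_size Odd window side, default 11.
#' @param sigma Gaussian window sigma, default 1.5.
#' @return Scalar in `[-1, 1]`; 1 for identical images.
#' @export
ssim <- function(x, y, data_range = 1, win_size = 11L, sigma = 1.5) {
  if (!all(dim(x) == dim(y))) stop("ssim: image shapes differ")
  if (win_size %% 2L != 1L) stop("ssim: win_size must be odd")
  if (nrow(x) < win_size || ncol(x) < win_size) {
    stop("ssim: images smaller than the window")
  }
  w <- .gauss_kernel(win_size, sigma)
  mu_x <- .conv_valid(x, w)
  mu_y <- .conv_valid(y, w)
  sxx <- .conv_valid(x * x, w) - mu_x^2
  syy <- .conv_valid(y * y, w) - mu_y^2
  sxy <- .conv_valid(x * y, w) - mu_x * mu_y
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  s <- ((2 * mu_x * mu_y + c1) * (2 * sxy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (sxx + syy + c2))
  mean(s)
}

.gauss_kernel <- function(win_size, sigma) {
  r <- (win_size - 1L) / 2
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# 'valid' 2D correlation: output (n - win + 1)^2, every window fully inside
.conv_valid <- function(img, kernel) {
  kw <- nrow(kernel)
  n <- nrow(img)
  m <- ncol(img)
  out <- matrix(0, n - kw + 1L, m - kw + 1L)
  for (i in seq_len(kw)) {
    for (j in seq_len(kw)) {
      out <- out + kernel[i, j] *
        img[i:(i + n - kw), j:(j + m - kw)]
    }
  }
  out
}

#' Phase-error curve for all-optical QPI
#'
#' Bins the ground-truth phase values into equal-width bins over `[0, pi]`
#' and reports, per bin, the mean absolute error between the phase read off
#' the detector (`intensity * pi`) and the true phase. Flat curves near zero
#' indicate quantitatively faithful phase imaging across the whole phase
#' range; soft-quantized models typically degrade first at high phase values.
#'
#' @param intensity Detector intensity matrix (the QPI prediction, `~ phi/pi`).
#' @param phase Ground-truth phase matrix in `[0, pi]` (rad).
#' @param n_bins Number of equal bins over `[0, pi]`.
#' @return Tibble with `bin`, `phase_mid` (bin center, rad), `mae` (rad),
#'   and `n` (pixels in bin; `mae` is `NA` for empty bins).
#' @export
phase_error_curve <- function(intensity, phase, n_bins = 20L) {
  if (!all(dim(intensity) == dim(phase))) {
    stop("phase_error_curve: shapes differ")
  }
  edges <- seq(0, pi, length.out = n_bins + 1L)
  idx <- pmin(pmax(findInterval(phase, edges, rightmost.closed = TRUE), 1L), n_bins)
  err <- abs(intensity * pi - phase)
  tibble::tibble(
    bin = seq_len(n_bins),
    phase_mid = (edges[-1] + edges[-(n_bins + 1L)]) / 2,
    mae = vapply(seq_len(n_bins), function(b) {
      v <- err[idx == b]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1)),
    n = vapply(seq_len(n_bins), function(b) sum(idx == b), numeric(1))
  )
}
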