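#' Sampled complex optical field
#'
#' A monochromatic scalar field sampled on a square grid: complex amplitudes
#' plus the physical sampling pitch and the wavelength. These three pieces are
#' all the angular-spectrum propagator needs.
#'
#' @param values Square complex (or real, promoted) matrix, side `>= 2`.
#' @param pitch Grid spacing in meters, positive.
#' @param wavelength Wavelength in meters, positive.
#' @return A `complex_field` object.
#' @examples
#' f <- complex_field(matrix(1 + 0i, 8, 8), pitch = 633e-9, wavelength = 633e-9)
#' field_power(f)
#' @export
complex_field <- function(values, pitch = 632.8e-9, wavelength = 632.8e-9) {
  if (!is.matrix(values)) stop("complex_field: values must be a matrix")
  if (nrow(values) != ncol(values) || nrow(values) < 2L) {
    stop("complex_field: grid must be square with side >= 2")
  }
  if (!(pitch > 0) || !(wavelength > 0)) {
    stop("complex_field: pitch and wavelength must be positive")
  }
  if (!is.complex(values)) values <- values + 0i
  structure(
    list(values = values, pitch = pitch, wavelength = wavelength),
    class = "complex_field"
  )
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf(
    "<complex_field> %dx%d, pitch %.3g m, wavelength %.3g m, power %.4g\n",
    nrow(x$values), ncol(x$values), x$pitch, x$wavelength, field_power(x)
  ))
  invisible(x)
}

#' Field intensity and power
#'
#' Intensity is the squared modulus `|E|^2` per pixel — what a detector in
#' the output plane records. Power integrates intensity over the sampled
#' aperture, `sum(|E|^2) * pitch^2`.
#'
#' @param field A [complex_field()].
#' @return `field_intensity()`: a nonnegative real matrix;
#'   `field_power()`: a scalar.
#' @export
field_intensity <- function(field) {
  stopifnot(inherits(field, "complex_field"))
  Mod(field$values)^2
}

#' @rdname field_intensity
#' @export
field_power <- function(field) {
  stopifnot(inherits(field, "complex_field"))
  sum(Mod(field$values)^2) * field$pitch^2
}

# Band-limited angular-spectrum propagator between parallel planes.
# H(fx, fy) = exp(i 2 pi d sqrt(1/lambda^2 - fx^2 - fy^2)) on the propagating
# band, 0 on the evanescent band. Returns forward and adjoint closures on the
# (optionally 2x zero-padded) grid; the adjoint is the same operator with
# conj(H), i.e. band-limited back-propagation, used by the backward pass.
.make_propagator <- function(n, pitch, wavelength, distance, pad = TRUE) {
  if (distance == 0) {
    idf <- function(v) v
    return(list(forward = idf, adjoint = idf, distance = distance))
  }
  m <- if (pad) 2L * n else n
  idx0 <- (m - n) %/% 2L
  sel <- (idx0 + 1L):(idx0 + n)
  k <- 0:(m - 1L)
  f <- ifelse(k < m / 2, k, k - m) / (m * pitch)
  f2 <- outer(f^2, f^2, `+`) # fy^2 + fx^2 over (row, col)
  arg <- 1 / wavelength^2 - f2
  band <- arg > 0
  kz <- sqrt(pmax(arg, 0))
  H <- exp(2i * pi * distance * kz) * band
  Hc <- Conj(H)
  mm <- m * m
  apply_h <- function(v, h) {
    if (pad) {
      P <- matrix(0i, m, m)
      P[sel, sel] <- v
    } else {
      P <- v
    }
    out <- stats::fft(stats::fft(P) * h, inverse = TRUE) / mm
    if (pad) out[sel, sel] else out
  }
  list(
    forward = function(v) apply_h(v, H),
    adjoint = function(v) apply_h(v, Hc),
    distance = distance
  )
}

#' Free-space propagation (band-limited angular spectrum)
#'
#' Propagates the field to a parallel plane `distance` meters downstream using
#' the angular-spectrum method: FFT to spatial frequencies, multiplication by
#' the transfer function `exp(i 2 pi d sqrt(1/lambda^2 - fx^2 - fy^2))` on the
#' propagating band (evanescent components are dropped), inverse FFT. This is
#' the exact scalar solution of free-space diffraction between parallel
#' planes, is linear in the field, and — because `|H| = 1` on the band — is
#' power-preserving for band-limited fields when no padding crop intervenes.
#'
#' @param field A [complex_field()].
#' @param distance Propagation distance in meters, `>= 0`.
#' @param pad Zero-pad the grid to twice its side before the FFT to suppress
#'   periodic wrap-around, cropping back afterwards (default `TRUE`). Disable
#'   for strict unitarity on the periodic grid.
#' @return A [complex_field()] on the same grid.
#' @export
propagate <- function(field, distance, pad = TRUE) {
  stopifnot(inherits(field, "complex_field"))
  if (!is.numeric(distance) || length(distance) != 1L || distance < 0) {
    stop("propagate: distance must be a nonnegative scalar")
  }
  p <- .make_propagator(
    nrow(field$values), field$pitch, field$wavelength, distance, pad
  )
  complex_field(p$forward(field$values), field$pitch, field$wavelength)
}

#' Phase modulation by a diffractive layer
#'
#' Multiplies the field elementwise by `exp(i * phase)`: a thin phase-only
#' layer delays the wavefront without absorbing it, so the amplitude is
#' preserved pixelwise.
#'
#' @param field A [complex_field()].
#' @param phase Real matrix of phase delays (rad), same shape as the field.
#' @return A [complex_field()].
#' @export
modulate <- function(field, phase) {
  stopifnot(inherits(field, "complex_field"))
  if (!is.matrix(phase) || !all(dim(phase) == dim(field$values))) {
    stop("modulate: phase grid shape must match the field grid")
  }
  complex_field(
    field$values * exp(1i * phase), field$pitch, field$wavelength
  )
}

#' Phase-object input field
#'
#' Encodes a grayscale image as a pure phase object: unit amplitude
#' everywhere, phase `pi * image`. This is how transparent specimens (and the
#' phase-encoded benchmark images standing in for them) enter the optical
#' network — the information is carried entirely in the phase, over `[0, pi]`.
#'
#' @param image Real matrix with values in `[0, 1]`; callers normalize first.
#' @param pitch,wavelength Physical sampling, see [complex_field()].
#' @return A [complex_field()] with `|E| = 1` and `Arg(E) = pi * image`.
#' @export
field_from_phase_image <- function(image, pitch = 632.8e-9,
                                   wavelength = 632.8e-9) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("field_from_phase_image: image must be a numeric matrix")
  }
  if (any(image < 0) || any(image > 1)) {
    stop("field_from_phase_image: image values must lie in [0, 1]")
  }
  complex_field(exp(1i * pi * image), pitch, wavelength)
}

#' Serialize a field to TIFF (+ JSON sidecar) or plain JSON
#'
#' `write_field_tiff()` writes a two-plane 32-bit float TIFF (real part, then
#' imaginary part), each plane affinely rescaled to `[0, 1]`; the exact
#' ranges, pitch and wavelength go to a JSON sidecar at `<path>.json` so the
#' round-trip is lossless up to float-32. `write_field_json()` writes a single
#' self-contained double-precision JSON container.
#'
#' @param field A [complex_field()].
#' @param path Output path (`.tif` recommended for the TIFF variant).
#' @return The path, invisibly; readers return a [complex_field()].
#' @export
write_field_tiff <- function(field, path) {
  stopifnot(inherits(field, "complex_field"))
  planes <- list(Re(field$values), Im(field$values))
  meta <- list(pitch = field$pitch, wavelength = field$wavelength)
  scaled <- vector("list", 2L)
  for (i in 1:2) {
    lo <- min(planes[[i]])
    hi <- max(planes[[i]])
    span <- if (hi > lo) hi - lo else 1
    scaled[[i]] <- (planes[[i]] - lo) / span
    meta[[c("re_range", "im_range")[i]]] <- c(lo, lo + span)
  }
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
  jsonlite::write_json(meta, paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_field_tiff
#' @export
read_field_tiff <- function(path) {
  planes <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  rg <- list(meta$re_range, meta$im_range)
  for (i in 1:2) {
    planes[[i]] <- planes[[i]] * (rg[[i]][2] - rg[[i]][1]) + rg[[i]][1]
  }
  complex_field(
    planes[[1]] + 1i * planes[[2]],
    pitch = meta$pitch, wavelength = meta$wavelength
  )
}

#' @rdname write_field_tiff
#' @export
write_field_json <- function(field, path) {
  stopifnot(inherits(field, "complex_field"))
  jsonlite::write_json(
    list(
      re = Re(field$values), im = Im(field$values),
      pitch = field$pitch, wavelength = field$wavelength
    ),
    path,
    auto_unbox = TRUE, digits = NA, matrix = "rowmajor"
  )
  invisible(path)
}

#' @rdname write_field_tiff
#' @export
read_field_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  complex_field(
    x$re + 1i * x$im,
    pitch = x$pitch, wavelength = x$wavelength
  )
}
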