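#' Construct a diffractive deep neural network (D2NN)
#'
#' A D2NN is an ordered stack of phase-only diffractive layers separated by
#' free-space propagation: the input field propagates to the first layer, is
#' phase-modulated by that layer's (possibly soft-quantized) coefficients,
#' propagates to the next layer, and so on until a final propagation to the
#' detector plane. Every pixel of every layer is a learnable "optical neuron"
#' holding one raw phase coefficient.
#'
#' @param n_layers Number of diffractive layers, `>= 1`.
#' @param grid_size Side of the square simulation grid in pixels.
#' @param wavelength Operating wavelength in meters.
#' @param pitch Neuron pitch in meters; diffractive neurons are on the order
#'   of the wavelength, default one wavelength.
#' @param d_in,d_layer,d_out Propagation distances (m): input plane to first
#'   layer, between consecutive layers, last layer to detector. Default 40
#'   wavelengths each.
#' @param pad Zero-pad propagations to twice the grid (see [propagate()]).
#' @param quant_kind Quantizer applied to the raw phases in the forward pass:
#'   `"fp"` (full precision, pass-through), `"hard"`, `"ste"`, `"psq"`,
#'   `"dsq"`, or `"gs"`.
#' @param grid A [quant_grid()] (ignored for `"fp"`).
#' @param tau Initial per-layer temperature(s) for soft quantizers, recycled
#'   to `n_layers`.
#' @param init Phase initialization: `"uniform"` draws each coefficient from
#'   `[0, 2 * pi)`, `"zero"` starts flat.
#' @param seed Optional integer seed for the initialization draw.
#' @return A `d2nn` object.
#' @examples
#' m <- d2nn(n_layers = 2, grid_size = 16, quant_kind = "fp", seed = 1)
#' img <- matrix(runif(256), 16, 16)
#' out <- d2nn_forward(m, field_from_phase_image(img))
#' range(detector_intensity(out))
#' @export
d2nn <- function(n_layers = 2L, grid_size = 32L,
                 wavelength = 632.8e-9, pitch = wavelength,
                 d_in = 40 * wavelength, d_layer = 40 * wavelength,
                 d_out = 40 * wavelength, pad = TRUE,
                 quant_kind = "fp", grid = quant_grid(),
                 tau = 1, init = c("uniform", "zero"), seed = NULL) {
  n_layers <- as.integer(n_layers)
  stopifnot(n_layers >= 1L, grid_size >= 2L, d_in >= 0, d_layer >= 0, d_out >= 0)
  init <- match.arg(init)
  quant_kind <- match.arg(quant_kind, c("fp", "hard", "ste", "psq", "dsq", "gs"))
  draw <- function() {
    if (init == "zero") {
      matrix(0, grid_size, grid_size)
    } else {
      matrix(stats::runif(grid_size^2, 0, 2 * pi), grid_size, grid_size)
    }
  }
  phi <- if (!is.null(seed)) {
    withr::with_seed(as.integer(seed), replicate(n_layers, draw(), simplify = FALSE))
  } else {
    replicate(n_layers, draw(), simplify = FALSE)
  }
  structure(
    list(
      phi = phi,
      quant = list(kind = quant_kind, grid = grid),
      tau = rep_len(tau, n_layers),
      k = NULL, gamma = NULL, # set by train_qat() under the learnable scheme
      geom = list(
        grid_size = grid_size, wavelength = wavelength, pitch = pitch,
        d_in = d_in, d_layer = d_layer, d_out = d_out, pad = pad
      )
    ),
    class = "d2nn"
  )
}

#' @export
print.d2nn <- function(x, ...) {
  cat(sprintf(
    "<d2nn> %d phase layer(s) of %dx%d neurons, quantizer '%s'",
    length(x$phi), x$geom$grid_size, x$geom$grid_size, x$quant$kind
  ))
  if (x$quant$kind %in% c("psq", "dsq", "gs")) {
    cat(sprintf(", tau = %s", paste(signif(x$tau, 3), collapse = "/")))
  }
  cat("\n")
  invisible(x)
}

# propagators reused across samples/epochs; built once per model geometry
.d2nn_props <- function(model) {
  g <- model$geom
  mk <- function(d) .make_propagator(g$grid_size, g$pitch, g$wavelength, d, g$pad)
  list(p_in = mk(g$d_in), p_mid = mk(g$d_layer), p_out = mk(g$d_out))
}

.layer_prop <- function(props, n, n_layers) {
  if (n == n_layers) props$p_out else props$p_mid
}

#' Effective layer phases
#'
#' The phases the model actually applies. In `"train"` mode this is the
#' quantizer's forward output on the raw coefficients (pass-through for
#' `"fp"`). In `"deploy"` mode it is the fabrication condition: raw phases
#' wrapped to `[0, 2 * pi)` and hard-quantized onto the level grid (for
#' `"fp"` models, just the wrapped phases).
#'
#' @param model A [d2nn()].
#' @param mode `"train"` or `"deploy"`.
#' @param noise Optional list of per-layer Gumbel noise matrices (kind `"gs"`).
#' @return List of phase matrices, one per layer.
#' @export
effective_phases <- function(model, mode = c("train", "deploy"), noise = NULL) {
  mode <- match.arg(mode)
  if (mode == "deploy") {
    if (model$quant$kind == "fp") {
      return(lapply(model$phi, wrap_phase))
    }
    return(lapply(model$phi, function(p) {
      hard_quantize(wrap_phase(p), model$quant$grid)
    }))
  }
  lapply(seq_along(model$phi), function(n) {
    .quant_eval(
      model$quant$kind, model$phi[[n]], model$quant$grid,
      tau = model$tau[[n]], noise = noise[[n]]
    )$value
  })
}

#' Forward pass through a D2NN
#'
#' Applies the composition: propagate to layer 1, modulate, propagate, ...,
#' modulate at layer N, propagate to the detector.
#'
#' @param model A [d2nn()].
#' @param input A [complex_field()] on the model grid.
#' @param mode Quantization mode for the layer phases, see
#'   [effective_phases()].
#' @param noise Optional per-layer Gumbel noise (kind `"gs"`).
#' @param props Optional precomputed propagators (internal reuse).
#' @return The output [complex_field()] at the detector plane.
#' @export
d2nn_forward <- function(model, input, mode = "train", noise = NULL,
                         props = NULL) {
  stopifnot(inherits(model, "d2nn"), inherits(input, "complex_field"))
  if (nrow(input$values) != model$geom$grid_size) {
    stop("d2nn_forward: input grid does not match the model grid")
  }
  props <- props %||% .d2nn_props(model)
  phases <- effective_phases(model, mode = mode, noise = noise)
  nl <- length(model$phi)
  E <- props$p_in$forward(input$values)
  for (n in seq_len(nl)) {
    E <- .layer_prop(props, n, nl)$forward(E * exp(1i * phases[[n]]))
  }
  complex_field(E, input$pitch, input$wavelength)
}

# Forward with cache for backprop: keeps, per layer, the field entering the
# layer (A), the field leaving it (B = A * exp(i theta)), and the quantizer
# value/derivatives at the raw phases.
.d2nn_forward_cache <- function(model, values, props, noise = NULL) {
  nl <- length(model$phi)
  qs <- vector("list", nl)
  A <- vector("list", nl)
  B <- vector("list", nl)
  E <- props$p_in$forward(values)
  for (n in seq_len(nl)) {
    qs[[n]] <- .quant_eval(
      model$quant$kind, model$phi[[n]], model$quant$grid,
      tau = model$tau[[n]], noise = noise[[n]]
    )
    A[[n]] <- E
    B[[n]] <- E * exp(1i * qs[[n]]$value)
    E <- .layer_prop(props, n, nl)$forward(B[[n]])
  }
  list(out = E, A = A, B = B, qs = qs, nl = nl)
}

# Backward pass: dLdI is the gradient of a real scalar loss with respect to
# the detector intensity. Wirtinger adjoints: g = dL/dE*; through the
# intensity g = dLdI * E_out; through propagation the adjoint propagator
# (conjugate transfer function); through modulation g <- g * conj(exp(i
# theta)); the real-parameter gradient at each layer is
# dL/dtheta = 2 Im(g_B * conj(B)).
.d2nn_backward <- function(model, cache, dLdI, props) {
  nl <- cache$nl
  g <- dLdI * cache$out
  dphi <- vector("list", nl)
  dtau <- numeric(nl)
  for (n in rev(seq_len(nl))) {
    gB <- .layer_prop(props, n, nl)$adjoint(g)
    dtheta <- 2 * Im(gB * Conj(cache$B[[n]]))
    dphi[[n]] <- dtheta * cache$qs[[n]]$dx
    if (!is.null(cache$qs[[n]]$dtau)) {
      dtau[n] <- sum(dtheta * cache$qs[[n]]$dtau)
    }
    t_n <- cache$B[[n]] / cache$A[[n]] # exp(i theta), unit modulus
    g <- gB * Conj(t_n)
  }
  list(dphi = dphi, dtau = dtau)
}

#' Detector intensity
#'
#' The intensity pattern `|E_out|^2` a camera placed at the output plane
#' records; all task readouts operate on this.
#'
#' @param field The output [complex_field()].
#' @return Nonnegative real matrix.
#' @export
detector_intensity <- function(field) field_intensity(field)

#' Detector patch layout for 10-class readout
#'
#' Ten disjoint square patches arranged on a regular 2 x 5 grid over the
#' detector plane; the class decision is the patch collecting the highest
#' mean intensity. Any disjoint layout satisfies that readout rule; the
#' regular grid is the configurable default.
#'
#' @param grid_size Detector side in pixels.
#' @param rows,cols Patch grid arrangement (`rows * cols` = 10 classes).
#' @param patch_frac Side of each square patch as a fraction of its cell.
#' @return A `patch_readout` object: list of 10 index-range patches.
#' @export
patch_readout <- function(grid_size, rows = 2L, cols = 5L, patch_frac = 0.5) {
  stopifnot(grid_size >= rows, grid_size >= cols, patch_frac > 0, patch_frac <= 1)
  cell_h <- grid_size / rows
  cell_w <- grid_size / cols
  side <- max(1L, floor(min(cell_h, cell_w) * patch_frac))
  patches <- list()
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      cy <- (r - 0.5) * cell_h
      cx <- (c - 0.5) * cell_w
      r0 <- max(1L, floor(cy - side / 2) + 1L)
      c0 <- max(1L, floor(cx - side / 2) + 1L)
      r1 <- min(grid_size, r0 + side - 1L)
      c1 <- min(grid_size, c0 + side - 1L)
      patches[[length(patches) + 1L]] <- list(rows = r0:r1, cols = c0:c1)
    }
  }
  structure(
    list(patches = patches, grid_size = grid_size),
    class = "patch_readout"
  )
}

#' @export
print.patch_readout <- function(x, ...) {
  cat(sprintf(
    "<patch_readout> %d patches on a %dx%d detector\n",
    length(x$patches), x$grid_size, x$grid_size
  ))
  invisible(x)
}

#' Mean intensity per readout patch
#'
#' @param intensity Detector intensity matrix.
#' @param readout A [patch_readout()].
#' @return Numeric vector, one mean per patch.
#' @export
patch_means <- function(intensity, readout) {
  stopifnot(inherits(readout, "patch_readout"))
  if (nrow(intensity) != readout$grid_size) {
    stop("patch_means: intensity grid does not match the readout")
  }
  vapply(
    readout$patches,
    function(p) mean(intensity[p$rows, p$cols]),
    numeric(1)
  )
}

#' Classify a detector intensity pattern
#'
#' The class is the patch with the highest mean intensity (0-based class
#' index); exact ties resolve to the lowest index. The decision is invariant
#' under global rescaling of the intensity.
#'
#' @inheritParams patch_means
#' @return Integer class in `0 .. n_patches - 1`.
#' @export
classify_intensity <- function(intensity, readout) {
  which.max(patch_means(intensity, readout)) - 1L
}

#' Label map for a target class
#'
#' Binary detector-plane image that is 1 exactly on the readout patch of the
#' ground-truth class and 0 elsewhere — the regression target of the
#' classification objective.
#'
#' @param class Integer class in `0 .. n_patches - 1`.
#' @param readout A [patch_readout()].
#' @return 0/1 matrix of side `grid_size`.
#' @export
label_map <- function(class, readout) {
  stopifnot(inherits(readout, "patch_readout"))
  if (class < 0 || class >= length(readout$patches)) {
    stop("label_map: class out of range")
  }
  Y <- matrix(0, readout$grid_size, readout$grid_size)
  p <- readout$patches[[class + 1L]]
  Y[p$rows, p$cols] <- 1
  Y
}

#' Save / load a model checkpoint (JSON)
#'
#' Text checkpoints carrying all raw phase grids, the quantizer state
#' (kind, grid, per-layer temperatures, learnable `k`/`gamma` when present)
#' and the physical geometry.
#'
#' @param model A [d2nn()].
#' @param path File path.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "d2nn"))
  jsonlite::write_json(
    list(
      phi = model$phi,
      quant = list(
        kind = model$quant$kind,
        grid = unclass(model$quant$grid)[c("l", "u", "n_levels")]
      ),
      tau = model$tau, k = model$k, gamma = model$gamma,
      geom = model$geom
    ),
    path,
    auto_unbox = TRUE, digits = NA, matrix = "rowmajor"
  )
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  phi <- if (is.list(x$phi)) x$phi else {
    lapply(seq_len(dim(x$phi)[1]), function(i) x$phi[i, , ])
  }
  m <- d2nn(
    n_layers = length(phi), grid_size = x$geom$grid_size,
    wavelength = x$geom$wavelength, pitch = x$geom$pitch,
    d_in = x$geom$d_in, d_layer = x$geom$d_layer, d_out = x$geom$d_out,
    pad = x$geom$pad, quant_kind = x$quant$kind,
    grid = quant_grid(x$quant$grid$l, x$quant$grid$u, x$quant$grid$n_levels),
    tau = x$tau, init = "zero"
  )
  m$phi <- lapply(phi, as.matrix)
  m$tau <- x$tau
  if (!is.null(x$k) && length(x$k)) m$k <- x$k
  if (!is.null(x$gamma) && length(x$gamma)) m$gamma <- x$gamma
  m
}

#' Export fabrication-facing phase masks
#'
#' Writes each layer's deploy-condition phase mask (wrapped, hard-quantized)
#' as a float TIFF and/or a CSV of integer level indices — the artifact a
#' fabrication process consumes.
#'
#' @param model A trained [d2nn()].
#' @param dir Output directory (created if missing).
#' @param format `"tiff"`, `"csv"`, or both.
#' @return Tibble manifest of written files, invisibly.
#' @export
export_masks <- function(model, dir, format = c("tiff", "csv")) {
  stopifnot(inherits(model, "d2nn"))
  format <- match.arg(format, several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  masks <- effective_phases(model, mode = "deploy")
  lev <- if (model$quant$kind == "fp") NULL else quant_levels(model$quant$grid)
  files <- list()
  for (n in seq_along(masks)) {
    if ("tiff" %in% format) {
      p <- file.path(dir, sprintf("layer%02d_phase.tif", n))
      tiff::writeTIFF(masks[[n]] / (2 * pi), p, bits.per.sample = 32L)
      files[[length(files) + 1L]] <- tibble::tibble(
        layer = n, kind = "tiff", path = p
      )
    }
    if ("csv" %in% format && !is.null(lev)) {
      idx <- matrix(
        vapply(as.vector(masks[[n]]), function(v) which.min(abs(lev - v)) - 1L,
          integer(1)
        ),
        nrow(masks[[n]])
      )
      p <- file.path(dir, sprintf("layer%02d_levels.csv", n))
      utils::write.table(idx, p,
        sep = ",", row.names = FALSE, col.names = FALSE
      )
      files[[length(files) + 1L]] <- tibble::tibble(
        layer = n, kind = "csv", path = p
      )
    }
  }
  invisible(dplyr::bind_rows(files))
}
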