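#' Weighted squared-error classification loss
#'
#' Mean over detector pixels of `(Y - I)^2 * w`, where `Y` is the binary
#' label map, `I` the detector intensity, and the weight is `w = 1 - c_w * Y`:
#' non-target pixels carry full weight 1 while target-patch pixels are
#' down-weighted to `1 - c_w`. Penalizing the non-target region harder
#' discourages light from scattering outside the ground-truth patch. The
#' default `c_w = 10/11` gives target pixels weight `1/11`.
#'
#' @param Y Binary label-map matrix (see [label_map()]).
#' @param intensity Detector intensity matrix, same shape.
#' @param c_w Target down-weighting in `[0, 1)`; `c_w = 0` is plain MSE.
#' @return Nonnegative scalar.
#' @export
classification_loss <- function(Y, intensity, c_w = 10 / 11) {
  if (!all(dim(Y) == dim(intensity))) {
    stop("classification_loss: label map and intensity shapes differ")
  }
  stopifnot(c_w >= 0, c_w < 1)
  w <- 1 - c_w * Y
  mean((Y - intensity)^2 * w)
}

#' @rdname classification_loss
#' @return `classification_loss_grad()` returns `dL/dI`, shaped like
#'   `intensity`.
#' @export
classification_loss_grad <- function(Y, intensity, c_w = 10 / 11) {
  if (!all(dim(Y) == dim(intensity))) {
    stop("classification_loss_grad: label map and intensity shapes differ")
  }
  w <- 1 - c_w * Y
  -2 * w * (Y - intensity) / length(Y)
}

#' Reverse Huber (berHu) loss
#'
#' Per-pixel error `e = pred - target` contributes `|e|` when `|e| <= c` and
#' `(e^2 + c^2) / (2c)` otherwise, averaged over pixels. The two branches and
#' their derivatives agree at `|e| = c`, so the loss is C1; small residuals
#' get the robust L1 treatment while large ones are penalized quadratically —
#' the usual choice for dense image regression such as all-optical
#' quantitative phase imaging.
#'
#' @param pred,target Real matrices of equal shape.
#' @param c Positive branch threshold; see [berhu_threshold()] for the
#'   adaptive convention.
#' @return Nonnegative scalar.
#' @export
berhu_loss <- function(pred, target, c = 0.2) {
  if (!all(dim(pred) == dim(target))) {
    stop("berhu_loss: prediction and target shapes differ")
  }
  if (!(c > 0)) stop("berhu_loss: threshold c must be positive")
  e <- abs(pred - target)
  mean(ifelse(e <= c, e, (e^2 + c^2) / (2 * c)))
}

#' @rdname berhu_loss
#' @return `berhu_loss_grad()` returns `dL/dpred`, shaped like `pred`.
#' @export
berhu_loss_grad <- function(pred, target, c = 0.2) {
  if (!all(dim(pred) == dim(target))) {
    stop("berhu_loss_grad: prediction and target shapes differ")
  }
  if (!(c > 0)) stop("berhu_loss_grad: threshold c must be positive")
  e <- pred - target
  g <- ifelse(abs(e) <= c, sign(e), e / c)
  g / length(pred)
}

#' Adaptive berHu threshold
#'
#' The common convention: one fifth of the largest absolute residual in the
#' batch, `c = 0.2 * max|pred - target|` (treated as a constant in the
#' gradient). Falls back to `fallback` when the residuals vanish.
#'
#' @inheritParams berhu_loss
#' @param frac Fraction of the max residual, default 0.2.
#' @param fallback Threshold used when all residuals are zero.
#' @export
berhu_threshold <- function(pred, target, frac = 0.2, fallback = 1e-3) {
  m <- max(abs(pred - target))
  if (m > 0) frac * m else fallback
}

#' Task specifications
#'
#' Bundles the objective and the readout for the two physics-based tasks.
#' `task_classify()`: phase-object classification with the weighted
#' squared-error loss and a 10-patch detector readout. `task_qpi()`:
#' all-optical quantitative phase imaging — the detector intensity is trained
#' to reproduce the input phase scaled to `[0, 1]` (`phi / pi`), under the
#' berHu loss.
#'
#' @param readout A [patch_readout()]; built from `grid_size` if omitted.
#' @param grid_size Detector side, used when `readout` is `NULL`.
#' @param c_w Target down-weighting of [classification_loss()].
#' @param berhu_c Fixed berHu threshold, or `NULL` for the adaptive
#'   per-batch convention of [berhu_threshold()].
#' @return A `task_spec` object.
#' @export
task_classify <- function(readout = NULL, grid_size = NULL, c_w = 10 / 11) {
  if (is.null(readout)) {
    if (is.null(grid_size)) stop("task_classify: give a readout or grid_size")
    readout <- patch_readout(grid_size)
  }
  structure(
    list(kind = "classify", readout = readout, c_w = c_w),
    class = "task_spec"
  )
}

#' @rdname task_classify
#' @export
task_qpi <- function(berhu_c = NULL) {
  structure(
    list(kind = "qpi", berhu_c = berhu_c),
    class = "task_spec"
  )
}

#' @export
print.task_spec <- function(x, ...) {
  cat("<task_spec>", x$kind, "\n")
  invisible(x)
}

# target image for one sample under a task: label map for classification,
# phi / pi (= the normalized input image) for QPI
.task_target <- function(task, sample_image, sample_label) {
  if (task$kind == "classify") {
    label_map(sample_label, task$readout)
  } else {
    sample_image
  }
}

# loss value and dL/dI for one sample
.task_loss <- function(task, target, intensity, berhu_c = NULL) {
  if (task$kind == "classify") {
    list(
      value = classification_loss(target, intensity, task$c_w),
      grad = classification_loss_grad(target, intensity, task$c_w)
    )
  } else {
    c_use <- berhu_c %||% task$berhu_c %||% berhu_threshold(intensity, target)
    list(
      value = berhu_loss(intensity, target, c_use),
      grad = berhu_loss_grad(intensity, target, c_use)
    )
  }
}
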