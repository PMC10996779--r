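#' Uniform quantization grid
#'
#' Describes the discrete set of values a fabricated optical-neuron parameter
#' may take: `N` evenly spaced levels between a lower bound `l` and an upper
#' bound `u` (radians, for phase coefficients), with step
#' `delta = (u - l) / (N - 1)`.
#'
#' The default grid spans `[0, 1.99 * pi]`: 0 and `2 * pi` are the same phase
#' shift, so the top level stops just short of a full cycle. Two-level
#' classification grids conventionally use `l = 0, u = pi` instead.
#'
#' @param l Lower bound (rad).
#' @param u Upper bound (rad); must exceed `l`.
#' @param n_levels Integer number of levels, at least 2.
#' @return A `quant_grid` object (list with `l`, `u`, `n_levels`, `delta`).
#' @examples
#' g <- quant_grid(0, 1.99 * pi, 4)
#' quant_levels(g) / pi # 0.000 0.663 1.327 1.990
#' @export
quant_grid <- function(l = 0, u = 1.99 * pi, n_levels = 4L) {
  stopifnot(is.numeric(l), is.numeric(u), length(l) == 1L, length(u) == 1L)
  if (!(u > l)) stop("quant_grid: upper bound must exceed lower bound")
  n_levels <- as.integer(n_levels)
  if (is.na(n_levels) || n_levels < 2L) stop("quant_grid: n_levels must be >= 2")
  structure(
    list(l = l, u = u, n_levels = n_levels, delta = (u - l) / (n_levels - 1)),
    class = "quant_grid"
  )
}

#' @export
print.quant_grid <- function(x, ...) {
  cat(sprintf(
    "<quant_grid> %d levels on [%.4g, %.4g], step %.4g\n",
    x$n_levels, x$l, x$u, x$delta
  ))
  invisible(x)
}

#' Quantization levels of a grid
#'
#' @param grid A [quant_grid()].
#' @return Numeric vector of the `N` levels, first exactly `l`, last exactly `u`.
#' @export
quant_levels <- function(grid) {
  stopifnot(inherits(grid, "quant_grid"))
  lev <- grid$l + seq_len(grid$n_levels - 1L) * grid$delta
  c(grid$l, lev[-length(lev)], grid$u)
}

#' Hard (round-to-nearest) quantization
#'
#' Maps each value to its nearest quantization level; values below `l` clamp
#' to `l` and values at or above `u` clamp to `u`. Its derivative is zero
#' almost everywhere, which is why gradient-based training needs the soft
#' surrogates below.
#'
#' @param x Numeric vector/matrix.
#' @param grid A [quant_grid()].
#' @return Object shaped like `x` with every value on the level grid.
#' @export
hard_quantize <- function(x, grid) {
  stopifnot(inherits(grid, "quant_grid"))
  q <- round((x - grid$l) / grid$delta) * grid$delta + grid$l
  q[x < grid$l] <- grid$l
  q[x >= grid$u] <- grid$u
  q
}

# numerically stable logistic, no overflow for large |z|
.sigmoid <- function(z) {
  out <- z
  pos <- z >= 0
  out[pos] <- 1 / (1 + exp(-z[pos]))
  ez <- exp(z[!pos])
  out[!pos] <- ez / (1 + ez)
  out
}

# transition points of the hard quantizer: midpoints between adjacent levels
.psq_thresholds <- function(grid) {
  grid$l + grid$delta / 2 + (seq_len(grid$n_levels - 1L) - 1L) * grid$delta
}

#' Progressive sigmoid quantization (PSQ)
#'
#' Differentiable surrogate for [hard_quantize()]: a sum of shifted logistic
#' steps, `Q(x, tau) = l + sum_i delta * sigmoid(tau * (x - l - delta/2 - i*delta))`,
#' one step per transition between adjacent levels. The temperature `tau`
#' controls the steepness; as `tau` grows the surrogate converges to the hard
#' quantizer. Unlike DSQ, no clamping is applied outside `[l, u]`, so
#' out-of-range parameters keep a nonzero gradient and can be pulled back into
#' range during training.
#'
#' @param x Numeric vector/matrix.
#' @param tau Positive temperature.
#' @param grid A [quant_grid()].
#' @return Soft-quantized values, strictly increasing in `x`, bounded in `(l, u)`.
#' @seealso [psq_grad()] for the analytic derivative.
#' @export
psq <- function(x, tau, grid) {
  stopifnot(inherits(grid, "quant_grid"))
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) {
    stop("psq: temperature must be a positive scalar")
  }
  th <- .psq_thresholds(grid)
  out <- array(grid$l, dim = dim(x) %||% length(x))
  for (t_i in th) out <- out + grid$delta * .sigmoid(tau * (x - t_i))
  if (is.null(dim(x))) out <- as.vector(out)
  out
}

#' Analytic derivatives of PSQ
#'
#' Elementwise derivative of [psq()] with respect to the input (`dx`) and the
#' temperature (`dtau`): `dQ/dx = sum_i delta * tau * s_i * (1 - s_i)` and
#' `dQ/dtau = sum_i delta * (x - t_i) * s_i * (1 - s_i)` with
#' `s_i = sigmoid(tau * (x - t_i))`.
#'
#' @inheritParams psq
#' @return List with elements `dx` and `dtau`, each shaped like `x`.
#' @export
psq_grad <- function(x, tau, grid) {
  stopifnot(inherits(grid, "quant_grid"))
  if (tau <= 0) stop("psq_grad: temperature must be positive")
  th <- .psq_thresholds(grid)
  dx <- x * 0
  dtau <- x * 0
  for (t_i in th) {
    s <- .sigmoid(tau * (x - t_i))
    sp <- s * (1 - s)
    dx <- dx + grid$delta * tau * sp
    dtau <- dtau + grid$delta * (x - t_i) * sp
  }
  list(dx = dx, dtau = dtau)
}

#' Differentiable soft quantization (DSQ), fixed bounds
#'
#' Tanh-based soft quantizer: within each cell between adjacent levels the
#' curve is `m + (delta/2) * tanh(tau * (x - m)) / tanh(tau * delta / 2)` with
#' `m` the cell midpoint, so cell endpoints map to themselves. Values outside
#' `[l, u]` are clamped to the bounds (zero gradient there) — phase
#' coefficients live in a fixed range, so the quantization bounds are not
#' learned.
#'
#' @inheritParams psq
#' @export
dsq <- function(x, tau, grid) {
  stopifnot(inherits(grid, "quant_grid"))
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) {
    stop("dsq: temperature must be a positive scalar")
  }
  xc <- pmin(pmax(x, grid$l), grid$u)
  cell <- pmin(floor((xc - grid$l) / grid$delta), grid$n_levels - 2L)
  m <- grid$l + (cell + 0.5) * grid$delta
  out <- m + (grid$delta / 2) * tanh(tau * (xc - m)) / tanh(tau * grid$delta / 2)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

#' Analytic input derivative of DSQ
#'
#' @inheritParams psq
#' @return Elementwise `dQ/dx`, zero outside `[l, u]` (clamped region).
#' @export
dsq_grad <- function(x, tau, grid) {
  stopifnot(inherits(grid, "quant_grid"))
  if (tau <= 0) stop("dsq_grad: temperature must be positive")
  inside <- x >= grid$l & x <= grid$u
  xc <- pmin(pmax(x, grid$l), grid$u)
  cell <- pmin(floor((xc - grid$l) / grid$delta), grid$n_levels - 2L)
  m <- grid$l + (cell + 0.5) * grid$delta
  th <- tanh(tau * (xc - m))
  d <- (grid$delta / 2) * tau * (1 - th^2) / tanh(tau * grid$delta / 2)
  d * inside
}

#' Straight-through estimator (STE)
#'
#' Forward pass is exactly [hard_quantize()]; the backward pass pretends the
#' quantizer is the identity, i.e. the Jacobian is 1 everywhere. The gradient
#' counterpart is [ste_grad()], used by the training loop.
#'
#' @inheritParams hard_quantize
#' @export
ste_quantize <- function(x, grid) hard_quantize(x, grid)

#' @rdname ste_quantize
#' @return `ste_grad()` returns an all-ones array shaped like `x`.
#' @export
ste_grad <- function(x, grid) {
  out <- x * 0 + 1
  out
}

#' Gumbel-Softmax relaxed quantization
#'
#' Treats quantization as a categorical choice among the levels: per element,
#' logits are the negative squared distances to each level (scaled by
#' `1/delta^2`), perturbed by Gumbel(0, 1) noise and pushed through a softmax
#' at the given temperature. The output is the softmax-weighted average of the
#' levels, hence always inside `[l, u]` and fully differentiable. As the
#' temperature approaches zero (and with the noise suppressed) the weights
#' collapse onto the nearest level.
#'
#' @param x Numeric vector/matrix.
#' @param temperature Positive softmax temperature.
#' @param grid A [quant_grid()].
#' @param seed Integer seed making the Gumbel noise reproducible. Ignored when
#'   `noise` is supplied.
#' @param noise Optional pre-drawn Gumbel noise, an array of dim
#'   `c(length(x), n_levels)`; pass 0 to evaluate the noiseless relaxation.
#' @return List with `value` (shaped like `x`), `dx` (elementwise derivative
#'   holding the noise fixed), and the `noise` used.
#' @export
gumbel_quantize <- function(x, temperature, grid, seed = NULL, noise = NULL) {
  stopifnot(inherits(grid, "quant_grid"))
  if (!is.numeric(temperature) || length(temperature) != 1L || temperature <= 0) {
    stop("gumbel_quantize: temperature must be a positive scalar")
  }
  lev <- quant_levels(grid)
  np <- length(x)
  if (is.null(noise)) {
    if (!is.null(seed)) {
      noise <- withr::with_seed(as.integer(seed), {
        matrix(-log(-log(stats::runif(np * grid$n_levels))), np, grid$n_levels)
      })
    } else {
      noise <- matrix(-log(-log(stats::runif(np * grid$n_levels))), np, grid$n_levels)
    }
  } else if (length(noise) == 1L) {
    noise <- matrix(noise, np, grid$n_levels)
  }
  xv <- as.vector(x)
  logits <- -outer(xv, lev, function(a, b) (a - b)^2) / grid$delta^2
  z <- (logits + noise) / temperature
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  w <- ez / rowSums(ez)
  value <- drop(w %*% lev)
  # d logits / dx, softmax Jacobian contracted with the level vector
  dlog <- -2 * outer(xv, lev, function(a, b) (a - b)) / grid$delta^2
  wd <- rowSums(w * dlog)
  dwdx <- w * (dlog - wd) / temperature
  dx <- drop(dwdx %*% lev)
  if (!is.null(dim(x))) {
    dim(value) <- dim(x)
    dim(dx) <- dim(x)
  }
  list(value = value, dx = dx, noise = noise)
}

#' Wrap phases into one optical cycle
#'
#' Phase shifts are defined modulo `2 * pi`; wrapping trained full-precision
#' coefficients into `[0, 2 * pi)` before quantization-aware fine-tuning
#' leaves the forward model unchanged while keeping the coefficients inside
#' the quantization range.
#'
#' @param x Numeric vector/matrix of phases (rad).
#' @return `x` mod `2 * pi`, in `[0, 2 * pi)`.
#' @export
wrap_phase <- function(x) x %% (2 * pi)

# One entry point for the training loop: value + derivatives for every
# quantizer kind. `noise` is only consulted by the Gumbel kind.
.quant_eval <- function(kind, x, grid, tau = NULL, noise = NULL) {
  switch(kind,
    fp = list(value = x, dx = x * 0 + 1, dtau = NULL),
    hard = list(value = hard_quantize(x, grid), dx = x * 0, dtau = NULL),
    ste = list(value = hard_quantize(x, grid), dx = ste_grad(x, grid), dtau = NULL),
    psq = {
      g <- psq_grad(x, tau, grid)
      list(value = psq(x, tau, grid), dx = g$dx, dtau = g$dtau)
    },
    dsq = list(value = dsq(x, tau, grid), dx = dsq_grad(x, tau, grid), dtau = NULL),
    gs = {
      r <- gumbel_quantize(x, tau, grid, noise = noise)
      list(value = r$value, dx = r$dx, dtau = NULL)
    },
    stop("unknown quantizer kind: ", kind)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
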