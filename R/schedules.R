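#' Linearly increasing temperature schedule
#'
#' Temperature at epoch `t`: `tau0 + (delta_tau / delta_t) * t`. Starting soft
#' and hardening the quantizer linearly over training is the simplest
#' progressive scheme (PSQ-LI).
#'
#' @param t Epoch index, `>= 0` (vectorized).
#' @param tau0 Initial temperature, positive.
#' @param delta_tau Increment step size, `>= 0`.
#' @param delta_t Epochs between consecutive increments, integer `>= 1`.
#' @return Temperature(s), nondecreasing in `t`.
#' @export
tau_linear <- function(t, tau0 = 1, delta_tau = 1, delta_t = 1) {
  if (any(t < 0)) stop("tau_linear: epoch index must be >= 0")
  stopifnot(tau0 > 0, delta_tau >= 0, delta_t >= 1)
  tau0 + (delta_tau / delta_t) * t
}

#' Temperature from a learnable raw parameter
#'
#' Under the learnable scheme (PSQ-LT) each quantization instance (here: each
#' diffractive layer) carries a raw nonnegative parameter `k`; its temperature
#' is `tau = 1 / (k + gamma)`. The constant `gamma > 0` caps the temperature
#' at `1 / gamma`, and `k` is optimized by gradient descent alongside the
#' phase coefficients.
#'
#' @param k Nonnegative raw parameter (vectorized).
#' @param gamma Positive constant; the temperature ceiling is `1 / gamma`.
#' @export
tau_from_k <- function(k, gamma = 0.05) {
  if (gamma <= 0) stop("tau_from_k: gamma must be positive")
  if (any(k < 0)) stop("tau_from_k: k must be nonnegative")
  1 / (k + gamma)
}

#' Progressive regularizer for learnable temperatures
#'
#' `R_t(k) = lambda1 * (s_t * ||k||^2 - lambda2)^2` with `s_t = 2^floor(t / beta)`.
#' The regularizer is zero when `||k||^2 = lambda2 / s_t`; since `s_t` doubles
#' every `beta` epochs, the target squared norm of `k` halves on the same
#' clock, which pushes the temperatures `1 / (k + gamma)` upward as training
#' progresses while leaving them free to adapt through backpropagation.
#'
#' @param k Numeric vector of raw parameters, one per quantization instance.
#' @param t Epoch index, `>= 0`.
#' @param lambda1,lambda2 Regularization weights, `lambda1 > 0`.
#' @param beta Epochs per doubling of `s_t`, integer `>= 1`.
#' @return Nonnegative scalar.
#' @export
tau_regularizer <- function(k, t, lambda1 = 1, lambda2 = 1, beta = 10) {
  stopifnot(lambda1 > 0, beta >= 1, t >= 0)
  s_t <- 2^floor(t / beta)
  lambda1 * (s_t * sum(k^2) - lambda2)^2
}

#' @rdname tau_regularizer
#' @return `tau_regularizer_grad()` returns `dR/dk`, a vector like `k`.
#' @export
tau_regularizer_grad <- function(k, t, lambda1 = 1, lambda2 = 1, beta = 10) {
  stopifnot(lambda1 > 0, beta >= 1, t >= 0)
  s_t <- 2^floor(t / beta)
  4 * lambda1 * s_t * k * (s_t * sum(k^2) - lambda2)
}

#' Total training loss
#'
#' Task loss plus the progressive regularizer — the latter only when the
#' temperature is learnable.
#'
#' @param task_loss Finite scalar task loss.
#' @param reg Scalar regularizer value (ignored unless `learnable`).
#' @param learnable Logical; is the temperature being optimized?
#' @export
total_loss <- function(task_loss, reg = 0, learnable = FALSE) {
  if (!is.finite(task_loss) || (learnable && !is.finite(reg))) {
    stop("total_loss: non-finite loss component")
  }
  if (learnable) task_loss + reg else task_loss
}

#' Temperature schedule specifications
#'
#' Constructors for the three progressive-training schemes: fixed temperature
#' (PSQ-FT), linear increase (PSQ-LI), and learnable temperature (PSQ-LT).
#' The returned objects are consumed by [train_qat()].
#'
#' @param tau Fixed temperature (PSQ-FT).
#' @param tau0,delta_tau,delta_t Linear-schedule hyperparameters, see
#'   [tau_linear()].
#' @param gamma,lambda1,lambda2,beta Learnable-schedule hyperparameters, see
#'   [tau_from_k()] and [tau_regularizer()].
#' @param k0 Initial raw parameter per layer; the default `1 - gamma` starts
#'   every temperature at 1.
#' @return A `tau_schedule` object.
#' @export
sched_fixed <- function(tau = 10) {
  stopifnot(tau > 0)
  structure(list(kind = "fixed", tau = tau), class = "tau_schedule")
}

#' @rdname sched_fixed
#' @export
sched_linear <- function(tau0 = 1, delta_tau = 1, delta_t = 1) {
  stopifnot(tau0 > 0, delta_tau >= 0, delta_t >= 1)
  structure(
    list(kind = "linear", tau0 = tau0, delta_tau = delta_tau, delta_t = delta_t),
    class = "tau_schedule"
  )
}

#' @rdname sched_fixed
#' @export
sched_learnable <- function(gamma = 0.05, lambda1 = 1, lambda2 = 1, beta = 10,
                            k0 = 1 - gamma) {
  stopifnot(gamma > 0, lambda1 > 0, beta >= 1, k0 >= 0)
  structure(
    list(
      kind = "learnable", gamma = gamma, lambda1 = lambda1,
      lambda2 = lambda2, beta = beta, k0 = k0
    ),
    class = "tau_schedule"
  )
}

#' @rdname sched_fixed
#' @param start,step,floor Gumbel-Softmax annealing: temperature
#'   `max(floor, start + step * t)`; the conventional schedule starts at 50
#'   and decreases by 0.5 per epoch.
#' @export
sched_gs_anneal <- function(start = 50, step = -0.5, floor = 0.5) {
  stopifnot(start > 0, floor > 0)
  structure(
    list(kind = "gs_anneal", start = start, step = step, floor = floor),
    class = "tau_schedule"
  )
}

#' @export
print.tau_schedule <- function(x, ...) {
  cat("<tau_schedule>", x$kind, "\n")
  invisible(x)
}

# per-epoch temperatures for an n_layer model; learnable kind is resolved
# from the current k vector by the caller instead.
.sched_tau <- function(sched, t) {
  switch(sched$kind,
    fixed = sched$tau,
    linear = tau_linear(t, sched$tau0, sched$delta_tau, sched$delta_t),
    gs_anneal = max(sched$floor, sched$start + sched$step * t),
    stop("schedule kind ", sched$kind, " has no closed-form temperature")
  )
}
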