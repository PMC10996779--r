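# --- Adam optimizer (per-parameter adaptive steps) -------------------------

.adam_new <- function() list(m = NULL, v = NULL, t = 0)

.adam_step <- function(state, grad, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(state$m)) {
    state$m <- grad * 0
    state$v <- grad * 0
  }
  state$t <- state$t + 1
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(delta = -lr * mhat / (sqrt(vhat) + eps), state = state)
}

# --- data plumbing ----------------------------------------------------------

# accepts the tibble from synth_phase_objects() (image list-col + label) or a
# plain list of matrices; returns list(values = list of complex input grids,
# images, labels)
.prepare_data <- function(data, model) {
  if (tibble::is_tibble(data) || is.data.frame(data)) {
    images <- data$image
    labels <- if ("label" %in% names(data)) data$label else rep(NA_integer_, length(images))
  } else if (is.list(data)) {
    images <- data
    labels <- rep(NA_integer_, length(images))
  } else {
    stop("expected a tibble with an `image` list-column or a list of matrices")
  }
  if (!length(images)) stop("empty dataset")
  n <- model$geom$grid_size
  ok <- vapply(images, function(m) is.matrix(m) && all(dim(m) == n), logical(1))
  if (!all(ok)) stop("all images must be ", n, "x", n, " matrices matching the model grid")
  list(
    values = lapply(images, function(m) exp(1i * pi * m)),
    images = images, labels = labels
  )
}

# --- core training loop -----------------------------------------------------

# One engine for both stages. `schedule` NULL means no temperature bookkeeping
# (fp / hard / ste). The learnable scheme optimizes k alongside the phases and
# projects k >= 0 after each step.
.train_core <- function(model, data, task, epochs, lr = 1e-2, lr_k = 1e-3,
                        batch_size = 32L, seed = 1L, schedule = NULL,
                        epoch_offset = 0L) {
  prep <- .prepare_data(data, model)
  props <- .d2nn_props(model)
  nl <- length(model$phi)
  ns <- length(prep$values)
  batch_size <- min(batch_size, ns)
  learnable <- !is.null(schedule) && schedule$kind == "learnable"
  if (learnable && is.null(model$k)) {
    model$k <- rep(schedule$k0, nl)
    model$gamma <- schedule$gamma
  }
  opt_phi <- lapply(seq_len(nl), function(i) .adam_new())
  opt_k <- .adam_new()
  history <- vector("list", max(epochs, 0L))
  targets <- lapply(seq_len(ns), function(i) {
    .task_target(task, prep$images[[i]], prep$labels[[i]])
  })
  withr::with_seed(as.integer(seed), for (ep in seq_len(epochs)) {
    t_epoch <- epoch_offset + ep - 1L # schedule clock, 0-based
    if (learnable) {
      model$tau <- tau_from_k(model$k, schedule$gamma)
    } else if (!is.null(schedule)) {
      model$tau <- rep(.sched_tau(schedule, t_epoch), nl)
    }
    ord <- sample.int(ns)
    ep_loss <- 0
    nb <- 0L
    for (b0 in seq(1L, ns, by = batch_size)) {
      idx <- ord[b0:min(b0 + batch_size - 1L, ns)]
      gphi <- lapply(model$phi, function(p) p * 0)
      gtau <- numeric(nl)
      bloss <- 0
      noise <- NULL
      if (model$quant$kind == "gs") {
        noise <- lapply(seq_len(nl), function(i) {
          matrix(
            -log(-log(stats::runif(model$geom$grid_size^2 * model$quant$grid$n_levels))),
            model$geom$grid_size^2, model$quant$grid$n_levels
          )
        })
      }
      for (i in idx) {
        cache <- .d2nn_forward_cache(model, prep$values[[i]], props, noise = noise)
        intensity <- Mod(cache$out)^2
        tl <- .task_loss(task, targets[[i]], intensity)
        bloss <- bloss + tl$value
        grads <- .d2nn_backward(model, cache, tl$grad / length(idx), props)
        for (n in seq_len(nl)) gphi[[n]] <- gphi[[n]] + grads$dphi[[n]]
        gtau <- gtau + grads$dtau
      }
      bloss <- bloss / length(idx)
      for (n in seq_len(nl)) {
        st <- .adam_step(opt_phi[[n]], gphi[[n]], lr)
        model$phi[[n]] <- model$phi[[n]] + st$delta
        opt_phi[[n]] <- st$state
      }
      if (learnable) {
        # chain through tau = 1 / (k + gamma), plus the progressive regularizer
        dk <- gtau * (-1 / (model$k + schedule$gamma)^2) +
          tau_regularizer_grad(
            model$k, t_epoch,
            schedule$lambda1, schedule$lambda2, schedule$beta
          )
        st <- .adam_step(opt_k, dk, lr_k)
        model$k <- pmax(model$k + st$delta, 0)
        opt_k <- st$state
        model$tau <- tau_from_k(model$k, schedule$gamma)
      }
      ep_loss <- ep_loss + bloss
      nb <- nb + 1L
    }
    reg <- if (learnable) {
      tau_regularizer(
        model$k, t_epoch,
        schedule$lambda1, schedule$lambda2, schedule$beta
      )
    } else {
      0
    }
    history[[ep]] <- tibble::tibble(
      epoch = t_epoch,
      task_loss = ep_loss / nb,
      reg = reg,
      total = total_loss(ep_loss / nb, reg, learnable),
      tau = list(model$tau),
      k = list(if (learnable) model$k else NULL)
    )
    if (any(!is.finite(model$phi[[1]]))) {
      stop("training diverged: non-finite phase coefficients at epoch ", t_epoch)
    }
  })
  list(model = model, history = dplyr::bind_rows(history))
}

#' Full-precision pre-training
#'
#' Stage one of the two-stage protocol: train the D2NN with unconstrained
#' (pass-through) phase coefficients. The resulting full-precision model is
#' both the performance reference and the initialization for
#' quantization-aware fine-tuning ([train_qat()]).
#'
#' @param model A [d2nn()] (its quantizer is forced to `"fp"` for this stage).
#' @param data Tibble with an `image` list-column (and `label` for
#'   classification), e.g. from [synth_phase_objects()].
#' @param task A [task_classify()] or [task_qpi()].
#' @param epochs Training epochs; 0 returns the initialization unchanged.
#' @param lr Adam learning rate for the phase coefficients.
#' @param batch_size Mini-batch size.
#' @param seed Integer seed driving shuffling (and any quantizer noise).
#' @return A `d2nn_fit`: list with `model`, `history` (tibble of per-epoch
#'   loss and temperatures), `task` and `stage`.
#' @export
train_fp <- function(model, data, task, epochs = 100L, lr = 1e-2,
                     batch_size = 32L, seed = 1L) {
  stopifnot(inherits(model, "d2nn"), inherits(task, "task_spec"), epochs >= 0)
  model$quant$kind <- "fp"
  res <- .train_core(model, data, task,
    epochs = epochs, lr = lr,
    batch_size = batch_size, seed = seed, schedule = NULL
  )
  structure(
    list(model = res$model, history = res$history, task = task, stage = "fp"),
    class = "d2nn_fit"
  )
}

#' Wrap a model's phases into one optical cycle
#'
#' Maps every raw phase coefficient to `[0, 2 * pi)` (mod `2 * pi`). The
#' forward model is exactly invariant — `exp(i * phi)` does not see `2 * pi`
#' shifts — but wrapped coefficients start quantization-aware fine-tuning
#' inside the quantization range instead of being clamped to its ends.
#'
#' @param x A [d2nn()] or `d2nn_fit`.
#' @return Same type as `x`, phases wrapped.
#' @export
wrap_phases <- function(x) {
  if (inherits(x, "d2nn_fit")) {
    x$model <- wrap_phases(x$model)
    return(x)
  }
  stopifnot(inherits(x, "d2nn"))
  x$phi <- lapply(x$phi, wrap_phase)
  x
}

#' Quantization-aware fine-tuning
#'
#' Stage two: starting from (wrapped) full-precision weights, train with the
#' chosen quantizer in the forward pass so the deployed hard-quantized model
#' matches what was trained. Temperatures follow the given schedule; under
#' the learnable scheme the per-layer raw parameters `k` are optimized too
#' and the progressive regularizer is added to the loss.
#'
#' @param fp A full-precision `d2nn_fit` or [d2nn()] (typically after
#'   [wrap_phases()]; applied automatically here).
#' @param data,task,epochs,lr,batch_size,seed As in [train_fp()].
#' @param quant_kind `"psq"`, `"dsq"`, `"ste"`, or `"gs"`.
#' @param grid A [quant_grid()].
#' @param schedule A `tau_schedule` ([sched_fixed()], [sched_linear()],
#'   [sched_learnable()], [sched_gs_anneal()]); ignored for `"ste"`.
#' @param lr_k Adam learning rate for the learnable-temperature parameters.
#' @return A `d2nn_fit` with `stage = "qat"`.
#' @export
train_qat <- function(fp, data, task, quant_kind = "psq",
                      grid = quant_grid(), schedule = sched_fixed(),
                      epochs = 100L, lr = 1e-2, lr_k = 1e-3,
                      batch_size = 32L, seed = 1L) {
  model <- if (inherits(fp, "d2nn_fit")) fp$model else fp
  stopifnot(inherits(model, "d2nn"), inherits(task, "task_spec"), epochs >= 0)
  quant_kind <- match.arg(quant_kind, c("psq", "dsq", "ste", "gs"))
  model <- wrap_phases(model)
  model$quant <- list(kind = quant_kind, grid = grid)
  sched <- if (quant_kind == "ste") NULL else schedule
  if (!is.null(sched) && sched$kind == "learnable" && quant_kind != "psq") {
    stop("train_qat: the learnable-temperature scheme requires the psq quantizer")
  }
  res <- .train_core(model, data, task,
    epochs = epochs, lr = lr, lr_k = lr_k,
    batch_size = batch_size, seed = seed, schedule = sched
  )
  structure(
    list(model = res$model, history = res$history, task = task, stage = "qat"),
    class = "d2nn_fit"
  )
}

#' Post-quantization of a full-precision model
#'
#' The no-retraining baseline: wrap the trained full-precision phases to
#' `[0, 2 * pi)` and hard-quantize them onto the level grid. The returned
#' model carries the `"hard"` quantizer, so its train- and deploy-condition
#' forward passes coincide.
#'
#' @param fp A full-precision `d2nn_fit` or [d2nn()].
#' @param grid A [quant_grid()].
#' @return A [d2nn()] with phases on the level grid.
#' @export
post_quantize <- function(fp, grid = quant_grid()) {
  model <- if (inherits(fp, "d2nn_fit")) fp$model else fp
  stopifnot(inherits(model, "d2nn"))
  model$phi <- lapply(model$phi, function(p) hard_quantize(wrap_phase(p), grid))
  model$quant <- list(kind = "hard", grid = grid)
  model
}

#' @export
print.d2nn_fit <- function(x, ...) {
  cat(sprintf(
    "<d2nn_fit> stage %s, %d epoch(s), final loss %.4g\n",
    x$stage, nrow(x$history),
    if (nrow(x$history)) x$history$total[nrow(x$history)] else NA
  ))
  print(x$model)
  invisible(x)
}

#' Evaluate a model under deployment conditions
#'
#' Runs the forward model with the deploy-condition phases — wrapped and
#' hard-quantized for any quantized model (the fabricated device cannot carry
#' soft phases), wrapped full-precision phases otherwise — and scores the
#' task: classification accuracy under the patch readout, or mean SSIM
#' between the detector intensity and the normalized input phase plus the
#' binned absolute-phase-error curve for quantitative phase imaging.
#'
#' @param object A `d2nn_fit` or [d2nn()].
#' @param data Evaluation tibble (as in [train_fp()]).
#' @param task A `task_spec`.
#' @param mode `"deploy"` (default) or `"train"` (soft/pass-through phases).
#' @return A `d2nn_eval`: list with `metrics` (one-row tibble), `samples`
#'   (per-sample tibble) and, for QPI, `phase_error` (binned curve tibble).
#' @export
evaluate_model <- function(object, data, task, mode = "deploy") {
  model <- if (inherits(object, "d2nn_fit")) object$model else object
  stopifnot(inherits(model, "d2nn"), inherits(task, "task_spec"))
  prep <- .prepare_data(data, model)
  props <- .d2nn_props(model)
  phases <- effective_phases(model, mode = mode)
  nl <- length(model$phi)
  fwd <- function(v) {
    E <- props$p_in$forward(v)
    for (n in seq_len(nl)) {
      E <- .layer_prop(props, n, nl)$forward(E * exp(1i * phases[[n]]))
    }
    Mod(E)^2
  }
  ns <- length(prep$values)
  if (task$kind == "classify") {
    pred <- integer(ns)
    for (i in seq_len(ns)) {
      pred[i] <- classify_intensity(fwd(prep$values[[i]]), task$readout)
    }
    samples <- tibble::tibble(id = seq_len(ns), label = prep$labels, pred = pred)
    metrics <- tibble::tibble(
      n = ns, accuracy = mean(pred == prep$labels, na.rm = TRUE)
    )
    out <- list(metrics = metrics, samples = samples, task = "classify")
  } else {
    ssims <- numeric(ns)
    err_sum <- NULL
    err_n <- NULL
    for (i in seq_len(ns)) {
      intensity <- fwd(prep$values[[i]])
      target <- prep$images[[i]]
      ssims[i] <- ssim(intensity, target, data_range = 1)
      pec <- phase_error_curve(intensity, pi * target)
      if (is.null(err_sum)) {
        err_sum <- ifelse(is.na(pec$mae), 0, pec$mae) * pec$n
        err_n <- pec$n
        mids <- pec$phase_mid
      } else {
        err_sum <- err_sum + ifelse(is.na(pec$mae), 0, pec$mae) * pec$n
        err_n <- err_n + pec$n
      }
    }
    samples <- tibble::tibble(id = seq_len(ns), ssim = ssims)
    metrics <- tibble::tibble(n = ns, mean_ssim = mean(ssims))
    curve <- tibble::tibble(
      bin = seq_along(mids), phase_mid = mids,
      mae = ifelse(err_n > 0, err_sum / err_n, NA_real_), n = err_n
    )
    out <- list(
      metrics = metrics, samples = samples, phase_error = curve, task = "qpi"
    )
  }
  structure(out, class = "d2nn_eval")
}

#' @export
print.d2nn_eval <- function(x, ...) {
  cat("<d2nn_eval>", x$task, "\n")
  print(x$metrics)
  invisible(x)
}

# --- broom-style accessors --------------------------------------------------

#' Tidy training history
#'
#' `tidy()` on a fit returns the per-epoch log in long-friendly form: loss
#' components plus one temperature column per layer. `glance()` returns a
#' one-row summary.
#'
#' @param x A `d2nn_fit`.
#' @param ... Unused.
#' @export
tidy.d2nn_fit <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) return(h)
  taus <- do.call(rbind, h$tau)
  colnames(taus) <- paste0("tau_layer", seq_len(ncol(taus)))
  dplyr::bind_cols(
    dplyr::select(h, "epoch", "task_loss", "reg", "total"),
    tibble::as_tibble(taus)
  )
}

#' @rdname tidy.d2nn_fit
#' @export
glance.d2nn_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    stage = x$stage,
    epochs = nrow(h),
    final_loss = if (nrow(h)) h$total[nrow(h)] else NA_real_,
    final_mean_tau = if (nrow(h)) mean(h$tau[[nrow(h)]]) else NA_real_,
    n_layers = length(x$model$phi),
    quant_kind = x$model$quant$kind
  )
}

#' @rdname tidy.d2nn_fit
#' @export
tidy.d2nn_eval <- function(x, ...) x$samples

#' @rdname tidy.d2nn_fit
#' @export
glance.d2nn_eval <- function(x, ...) x$metrics

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
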