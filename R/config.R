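#' Run configuration
#'
#' Assembles (or loads from YAML) the full description of one training run:
#' task, data, model geometry, quantizer, temperature schedule and optimizer
#' settings. [run_pipeline()] executes it end to end.
#'
#' @param task List: `kind` (`"qpi"` or `"classify"`), optional `c_w`,
#'   `berhu_c`.
#' @param data List: `kind` (a [synth_phase_objects()] kind), `n_images`,
#'   `size`, `train_frac`. (The field is named `n_images` rather than `n`
#'   because YAML 1.1 parses a bare `n` key as a boolean.)
#' @param model List: `n_layers`, `grid_size`, `wavelength_m`, `pitch_m`,
#'   `layer_spacing_m`, `pad`.
#' @param quant List: `kind` in `fp`, `pq`, `ste`, `gs`, `dsq`, `psq`;
#'   `n_levels`, `l`, `u`.
#' @param schedule List: `kind` in `fixed`, `linear`, `learnable`,
#'   `gs_anneal` plus that scheme's hyperparameters.
#' @param train List: `fp_epochs`, `qat_epochs`, `lr`, `lr_k`, `batch_size`.
#' @param seed Integer master seed for the whole run.
#' @param out_dir Output directory for logs, checkpoints and metrics.
#' @return A `run_config` object (validated nested list).
#' @export
run_config <- function(task = list(kind = "qpi"),
                       data = list(kind = "blob", n_images = 300, size = 32,
                                   train_frac = 0.8),
                       model = list(n_layers = 2, grid_size = 32),
                       quant = list(kind = "psq", n_levels = 4),
                       schedule = list(kind = "fixed"),
                       train = list(fp_epochs = 30, qat_epochs = 30),
                       seed = 1L, out_dir = NULL) {
  defaults <- list(
    task = list(kind = "qpi", c_w = 10 / 11, berhu_c = NULL),
    data = list(kind = "blob", n_images = 300, size = 32, train_frac = 0.8),
    model = list(
      n_layers = 2, grid_size = 32, wavelength_m = 632.8e-9,
      pitch_m = NULL, layer_spacing_m = NULL, pad = TRUE
    ),
    quant = list(kind = "psq", n_levels = 4, l = 0, u = 1.99 * pi),
    schedule = list(
      kind = "fixed", tau = 10, tau0 = 1, delta_tau = 1, delta_t = 1,
      gamma = 0.05, lambda1 = 1, lambda2 = 1, beta = 10,
      start = 50, step = -0.5, floor = 0.5
    ),
    train = list(
      fp_epochs = 30, qat_epochs = 30, lr = 1e-2, lr_k = 1e-3,
      batch_size = 32
    )
  )
  merge1 <- function(d, u) {
    for (nm in names(u)) d[[nm]] <- u[[nm]]
    d
  }
  # tolerate the YAML-1.1 quirk (bare `n` key parsed as FALSE) and the
  # shorthand `n` for n_images
  for (alias in c("n", "FALSE")) {
    if (!is.null(data[[alias]])) {
      data$n_images <- data[[alias]]
      data[[alias]] <- NULL
    }
  }
  cfg <- list(
    task = merge1(defaults$task, task),
    data = merge1(defaults$data, data),
    model = merge1(defaults$model, model),
    quant = merge1(defaults$quant, quant),
    schedule = merge1(defaults$schedule, schedule),
    train = merge1(defaults$train, train),
    seed = as.integer(seed), out_dir = out_dir
  )
  cfg$quant$kind <- match.arg(
    cfg$quant$kind, c("fp", "pq", "ste", "gs", "dsq", "psq")
  )
  cfg$task$kind <- match.arg(cfg$task$kind, c("qpi", "classify"))
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with the same nested blocks.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y[intersect(
    names(y),
    c("task", "data", "model", "quant", "schedule", "train", "seed", "out_dir")
  )])
}

# schedule list -> tau_schedule object
.build_schedule <- function(s) {
  switch(s$kind,
    fixed = sched_fixed(s$tau),
    linear = sched_linear(s$tau0, s$delta_tau, s$delta_t),
    learnable = sched_learnable(s$gamma, s$lambda1, s$lambda2, s$beta),
    gs_anneal = sched_gs_anneal(s$start, s$step, s$floor),
    stop("unknown schedule kind: ", s$kind)
  )
}

.build_task <- function(t, grid_size) {
  if (t$kind == "classify") {
    task_classify(grid_size = grid_size, c_w = t$c_w)
  } else {
    task_qpi(berhu_c = t$berhu_c)
  }
}

#' Execute a configured training run
#'
#' Generates the synthetic dataset, splits it, pre-trains the full-precision
#' model, applies the configured quantization method (none, post-quantization
#' or QAT fine-tuning after phase wrapping), and evaluates under deployment
#' conditions. When `out_dir` is set, per-epoch CSV logs, JSON checkpoints,
#' a metrics JSON and the exported masks are written there.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return List with `fp_fit`, `fit` (final fit or model), `eval`
#'   (a `d2nn_eval`) and `config`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  cfg <- config
  wl <- cfg$model$wavelength_m
  pitch <- cfg$model$pitch_m %||% wl
  dz <- cfg$model$layer_spacing_m %||% (40 * wl)
  qgrid <- quant_grid(cfg$quant$l, cfg$quant$u, cfg$quant$n_levels)

  batch <- synth_phase_objects(
    cfg$data$n_images, cfg$data$kind,
    size = cfg$data$size, seed = cfg$seed
  )
  n_train <- max(1L, floor(cfg$data$train_frac * nrow(batch)))
  train_set <- batch[seq_len(n_train), ]
  test_set <- if (n_train < nrow(batch)) {
    batch[(n_train + 1L):nrow(batch), ]
  } else {
    train_set
  }
  task <- .build_task(cfg$task, cfg$model$grid_size)

  model <- d2nn(
    n_layers = cfg$model$n_layers, grid_size = cfg$model$grid_size,
    wavelength = wl, pitch = pitch,
    d_in = dz, d_layer = dz, d_out = dz, pad = isTRUE(cfg$model$pad),
    quant_kind = "fp", grid = qgrid, seed = cfg$seed
  )

  say("FP pre-training (", cfg$train$fp_epochs, " epochs)")
  fp_fit <- train_fp(model, train_set, task,
    epochs = cfg$train$fp_epochs, lr = cfg$train$lr,
    batch_size = cfg$train$batch_size, seed = cfg$seed
  )

  fit <- switch(cfg$quant$kind,
    fp = fp_fit,
    pq = post_quantize(fp_fit, qgrid),
    {
      say("QAT fine-tuning [", cfg$quant$kind, "] (",
        cfg$train$qat_epochs, " epochs)")
      train_qat(fp_fit, train_set, task,
        quant_kind = cfg$quant$kind, grid = qgrid,
        schedule = .build_schedule(cfg$schedule),
        epochs = cfg$train$qat_epochs, lr = cfg$train$lr,
        lr_k = cfg$train$lr_k, batch_size = cfg$train$batch_size,
        seed = cfg$seed + 1L
      )
    }
  )

  ev <- evaluate_model(fit, test_set, task)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tidy(fp_fit),
      file.path(cfg$out_dir, "fp_history.csv"),
      row.names = FALSE
    )
    if (inherits(fit, "d2nn_fit") && fit$stage == "qat") {
      utils::write.csv(tidy(fit),
        file.path(cfg$out_dir, "qat_history.csv"),
        row.names = FALSE
      )
    }
    final_model <- if (inherits(fit, "d2nn_fit")) fit$model else fit
    save_checkpoint(final_model, file.path(cfg$out_dir, "checkpoint.json"))
    jsonlite::write_json(
      as.list(ev$metrics),
      file.path(cfg$out_dir, "metrics.json"),
      auto_unbox = TRUE, digits = NA
    )
    export_masks(final_model, file.path(cfg$out_dir, "masks"))
  }
  list(fp_fit = fp_fit, fit = fit, eval = ev, config = cfg)
}
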