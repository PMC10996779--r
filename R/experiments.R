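#' Desk-scale method-ranking experiment
#'
#' Runs the quantization-method comparison on the synthetic
#' quantitative-phase-imaging task at desk scale: for each seed, a
#' full-precision D2NN is pre-trained on smooth blob phase objects, then (a)
#' post-quantized directly, (b) fine-tuned with PSQ at a fixed temperature,
#' and (c) fine-tuned with PSQ under the learnable-temperature scheme. Each
#' resulting model is evaluated under deployment conditions (hard-quantized
#' phases) by mean SSIM on a held-out split. This probes, at a size a laptop
#' handles, the qualitative claim that quantization-aware training beats
#' post-quantization at low bit depth, and how the progressive schedule
#' compares to a fixed temperature under a short training budget.
#'
#' @param seeds Integer vector of independent replicate seeds.
#' @param n Total synthetic blob images per replicate (80/20 train/test split).
#' @param size Grid side in pixels.
#' @param n_layers Diffractive layers.
#' @param fp_epochs,qat_epochs Epochs for the two training stages.
#' @param n_levels Quantization levels (default 4, the regime where method
#'   differences are largest).
#' @param tau_fixed Fixed temperature for the PSQ-FT arm.
#' @param methods Subset of `c("fp", "pq", "psq_ft", "psq_lt")` to run.
#' @param lr,batch_size Optimizer settings shared by both stages.
#' @param lr_k Adam learning rate for the learnable-temperature parameters,
#'   default one tenth of `lr`.
#' @param quiet Suppress progress messages.
#' @return Tibble with columns `method`, `seed`, `mean_ssim`.
#' @export
method_ranking_experiment <- function(seeds = 1:3, n = 300, size = 32,
                                      n_layers = 2, fp_epochs = 30,
                                      qat_epochs = 30, n_levels = 4,
                                      tau_fixed = 10,
                                      methods = c("fp", "pq", "psq_ft", "psq_lt"),
                                      lr = 0.1, lr_k = lr / 10, batch_size = 32,
                                      quiet = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  qgrid <- quant_grid(0, 1.99 * pi, n_levels)
  task <- task_qpi()
  rows <- list()
  for (seed in seeds) {
    batch <- synth_phase_objects(n, "blob", size = size, seed = seed)
    n_train <- floor(0.8 * n)
    train_set <- batch[seq_len(n_train), ]
    test_set <- batch[(n_train + 1L):n, ]
    model <- d2nn(
      n_layers = n_layers, grid_size = size, quant_kind = "fp",
      grid = qgrid, seed = seed
    )
    if (!quiet) message("seed ", seed, ": FP pre-training")
    fp_fit <- train_fp(model, train_set, task,
      epochs = fp_epochs, lr = lr, batch_size = batch_size, seed = seed
    )
    score <- function(obj) evaluate_model(obj, test_set, task)$metrics$mean_ssim
    for (meth in methods) {
      if (!quiet && meth != "fp") message("seed ", seed, ": ", meth)
      s <- switch(meth,
        fp = score(fp_fit),
        pq = score(post_quantize(fp_fit, qgrid)),
        psq_ft = score(train_qat(fp_fit, train_set, task,
          quant_kind = "psq", grid = qgrid,
          schedule = sched_fixed(tau_fixed),
          epochs = qat_epochs, lr = lr,
          batch_size = batch_size, seed = seed + 1000L
        )),
        psq_lt = score(train_qat(fp_fit, train_set, task,
          quant_kind = "psq", grid = qgrid,
          # doubling period scaled so the shortened run keeps ten
          # regularizer windows, the shape the default beta = 10 gives a
          # 100-epoch schedule
          schedule = sched_learnable(beta = max(1L, round(qat_epochs / 10))),
          epochs = qat_epochs, lr = lr, lr_k = lr_k,
          batch_size = batch_size, seed = seed + 1000L
        ))
      )
      rows[[length(rows) + 1L]] <- tibble::tibble(
        method = meth, seed = seed, mean_ssim = s
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Summarize a ranking experiment
#'
#' @param results Tibble from [method_ranking_experiment()].
#' @return Tibble with per-method mean and seed-to-seed standard deviation.
#' @export
summarize_ranking <- function(results) {
  dplyr::summarise(
    dplyr::group_by(results, .data$method),
    sd_ssim = stats::sd(.data$mean_ssim),
    mean_ssim = mean(.data$mean_ssim),
    n_seeds = dplyr::n(),
    .groups = "drop"
  )
}
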