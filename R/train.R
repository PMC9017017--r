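# Training and evaluation harness: per-task recipes, seeded determinism,
# validation split, and the k-fold runner.

#' Training configuration with per-task defaults
#'
#' Defaults follow the study recipes: classification uses SGD (learning rate
#' 0.001, momentum 0.9, weight decay 1e-4) with cross-entropy, 100 epochs,
#' batch 32; segmentation uses Adam (2e-4) with soft-Dice loss and batch 16;
#' detection uses Adam (2e-4) with MSE loss and batch 64.  Every field can
#' be overridden.
#'
#' @param task `"classify"`, `"segment"` or `"detect"`.
#' @param optimizer `"sgd"` or `"adam"`.
#' @param learning_rate non-negative step size.
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty added to the gradients.
#' @param loss `"cross-entropy"`, `"dice"` or `"mse"`.
#' @param epochs,batch_size training length and minibatch size.
#' @param seed seed for initialization, splits and shuffling.
#' @param folds folds for [run_crossval()].
#' @param val_fraction fraction of the training samples held out for
#'   validation inside [run_training()].
#' @return an object of class `train_config`.
#' @export
train_config <- function(task = c("classify", "segment", "detect"),
                         optimizer = NULL, learning_rate = NULL,
                         momentum = 0.9, weight_decay = NULL, loss = NULL,
                         epochs = NULL, batch_size = NULL, seed = 1L,
                         folds = 5L, val_fraction = 0.1) {
  task <- match.arg(task)
  def <- switch(task,
    classify = list(optimizer = "sgd", learning_rate = 0.001,
                    weight_decay = 1e-4, loss = "cross-entropy",
                    epochs = 100L, batch_size = 32L),
    segment  = list(optimizer = "adam", learning_rate = 2e-4,
                    weight_decay = 0, loss = "dice",
                    epochs = 250L, batch_size = 16L),
    detect   = list(optimizer = "adam", learning_rate = 2e-4,
                    weight_decay = 0, loss = "mse",
                    epochs = 500L, batch_size = 64L))
  cfg <- list(task = task,
              optimizer = optimizer %||% def$optimizer,
              learning_rate = learning_rate %||% def$learning_rate,
              momentum = momentum,
              weight_decay = weight_decay %||% def$weight_decay,
              loss = loss %||% def$loss,
              epochs = as.integer(epochs %||% def$epochs),
              batch_size = as.integer(batch_size %||% def$batch_size),
              seed = as.integer(seed), folds = as.integer(folds),
              val_fraction = val_fraction)
  if (cfg$learning_rate < 0) stop("learning_rate must be non-negative")
  if (!cfg$optimizer %in% c("sgd", "adam")) stop("unknown optimizer")
  if (!cfg$loss %in% c("cross-entropy", "dice", "mse")) stop("unknown loss")
  structure(cfg, class = "train_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize / parse a training configuration (YAML)
#'
#' `read_train_config(write_train_config(cfg, path))` is the identity.
#'
#' @param cfg a [train_config()].
#' @param path file path.
#' @export
write_train_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "train_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_train_config
#' @export
read_train_config <- function(path) {
  y <- yaml::read_yaml(path)
  train_config(task = y$task, optimizer = y$optimizer,
               learning_rate = y$learning_rate, momentum = y$momentum,
               weight_decay = y$weight_decay, loss = y$loss,
               epochs = y$epochs, batch_size = y$batch_size, seed = y$seed,
               folds = y$folds, val_fraction = y$val_fraction)
}

# ---- dataset containers ------------------------------------------------

#' Prepare training data from synthetic generator output
#'
#' `prepare_classification_data()` takes the output of
#' [generate_classification_set()]; the scene-based preparers take a list of
#' [generate_scene()] results.  Images are converted to the network input
#' scale (0-1); segmentation/detection inputs are converted to grayscale.
#'
#' @param set output of [generate_classification_set()].
#' @return a `nk_dataset` list with elements `x`, `y`, `task` (and
#'   `points` for detection data).
#' @export
prepare_classification_data <- function(set) {
  n <- dim(set$x)[1L]
  structure(list(x = set$x / 255, y = as.integer(set$labels),
                 levels = levels(set$labels), task = "classify"),
            class = "nk_dataset")
}

#' @rdname prepare_classification_data
#' @param scenes list of `synthetic_scene` objects.
#' @export
prepare_segmentation_data <- function(scenes) {
  n <- length(scenes)
  sz <- dim(scenes[[1]]$mask)
  x <- array(0, c(n, sz[1L], sz[2L], 1L))
  y <- array(0, c(n, sz[1L], sz[2L], 1L))
  for (i in seq_len(n)) {
    x[i, , , 1L] <- to_grayscale(scenes[[i]]$image) / 255
    y[i, , , 1L] <- scenes[[i]]$mask
  }
  structure(list(x = x, y = y, task = "segment"), class = "nk_dataset")
}

#' @rdname prepare_classification_data
#' @param sigma,combine_mode density-surface parameters, see
#'   [make_density_target()].
#' @export
prepare_detection_data <- function(scenes, sigma = 2.0, combine_mode = "max") {
  n <- length(scenes)
  sz <- dim(scenes[[1]]$mask)
  x <- array(0, c(n, sz[1L], sz[2L], 1L))
  y <- array(0, c(n, sz[1L], sz[2L], 1L))
  pts <- vector("list", n)
  for (i in seq_len(n)) {
    x[i, , , 1L] <- to_grayscale(scenes[[i]]$image) / 255
    y[i, , , 1L] <- make_density_target(scenes[[i]]$points, sz, sigma,
                                        combine_mode)
    pts[[i]] <- scenes[[i]]$points
  }
  structure(list(x = x, y = y, points = pts, sigma = sigma, task = "detect"),
            class = "nk_dataset")
}

ds_n <- function(data) dim(data$x)[1L]

ds_subset <- function(data, idx) {
  out <- data
  out$x <- data$x[idx, , , , drop = FALSE]
  out$y <- if (data$task == "classify") data$y[idx]
           else data$y[idx, , , , drop = FALSE]
  if (!is.null(data$points)) out$points <- data$points[idx]
  out
}

default_spec_for <- function(cfg, data, variant = NULL) {
  d <- dim(data$x)
  switch(cfg$task,
    classify = model_spec(variant %||% "dcrn",
                          input_shape = d[2:4],
                          num_outputs = length(data$levels %||%
                                               unique(data$y))),
    segment = model_spec(variant %||% "r2unet"),
    detect = model_spec(variant %||% "udnet"))
}

#' Evaluate a model on a dataset
#'
#' Classification reports accuracy; segmentation reports the Dice
#' coefficient of the 0.5-thresholded maps plus MSE; detection reports MSE
#' of the density maps and, when ground-truth points are available,
#' cell-level precision/recall/F1 through [detect_peaks()] and
#' [match_detections()].
#'
#' @param model an `nk_model`.
#' @param data a `nk_dataset`.
#' @param threshold threshold for masks / density peaks.
#' @param radius match radius for detection F1.
#' @return named list of metrics.
#' @export
evaluate_model <- function(model, data, threshold = 0.5, radius = 6) {
  pr <- predict(model, data$x, batch_size = 8L)
  if (data$task == "classify") {
    cls <- max.col(pr)
    return(list(accuracy = mean(cls == data$y)))
  }
  if (data$task == "segment") {
    d <- mapply(function(i) dice_coefficient(data$y[i, , , 1L],
                                             (pr[i, , , 1L] > threshold) * 1L),
                seq_len(ds_n(data)))
    m <- mean_squared_error(data$y, pr)
    return(list(dice = mean(d), mse = m))
  }
  m <- mean_squared_error(data$y, pr)
  out <- list(mse = m)
  if (!is.null(data$points)) {
    tot <- c(TP = 0L, FP = 0L, FN = 0L)
    for (i in seq_len(ds_n(data))) {
      det <- detect_peaks(pr[i, , , 1L], threshold = threshold)
      cts <- match_detections(det, data$points[[i]], radius = radius)
      tot <- tot + c(cts$TP, cts$FP, cts$FN)
    }
    prf <- precision_recall_f1(list(TP = tot[1L], FP = tot[2L], FN = tot[3L]))
    out <- c(out, as.list(prf))
  }
  out
}

task_loss <- function(cfg, logits, yb) {
  if (cfg$task == "classify") {
    l <- loss_softmax_ce(logits, yb)
    return(list(loss = l$loss, dout = l$grad))
  }
  p <- sigmoid(logits)
  l <- switch(cfg$loss,
              dice = loss_soft_dice(p, yb),
              mse = loss_mse(p, yb),
              `cross-entropy` = stop("cross-entropy is for classification"))
  list(loss = l$loss, dout = l$grad * p * (1 - p))
}

#' Train a model
#'
#' Runs the configured recipe on a `nk_dataset`, holding out a seeded
#' validation split, and records a per-epoch trace.  Rerunning with the same
#' configuration and seed reproduces the run.
#'
#' @param cfg a [train_config()].
#' @param data a `nk_dataset` (see [prepare_classification_data()] and
#'   friends).
#' @param spec optional [model_spec()] overriding the task default; this is
#'   how the feed-forward and recurrent classifiers share one training loop.
#' @param model optional pre-built `nk_model` (takes precedence over `spec`).
#' @param variant convenience override of the default variant.
#' @param verbose print per-epoch progress.
#' @return an object of class `nk_run`: `list(config, trace, final, model)`.
#' @export
run_training <- function(cfg, data, spec = NULL, model = NULL,
                         variant = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"), inherits(data, "nk_dataset"))
  if (cfg$task != data$task)
    stop("config task ", cfg$task, " does not match data task ", data$task)
  n <- ds_n(data)
  if (n < 2L) stop("dataset is empty or too small")
  if (is.null(spec)) spec <- default_spec_for(cfg, data, variant)
  if ((spec$variant %in% c("densenet", "dcrn")) != (cfg$task == "classify"))
    stop("model variant ", spec$variant, " does not fit task ", cfg$task)
  if (is.null(model)) model <- build_model(spec, seed = cfg$seed)
  n_val <- max(1L, round(cfg$val_fraction * n))
  val_idx <- with_build_seed(cfg$seed, sort(sample.int(n, n_val)))
  tr_idx <- setdiff(seq_len(n), val_idx)
  dtr <- ds_subset(data, tr_idx)
  dval <- ds_subset(data, val_idx)
  opt <- optim_new(model$reg$layers, method = cfg$optimizer,
                   lr = cfg$learning_rate, momentum = cfg$momentum,
                   weight_decay = cfg$weight_decay)
  trace <- NULL
  with_build_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(seq_along(tr_idx))
      losses <- c()
      for (b0 in seq(1L, length(ord), by = cfg$batch_size)) {
        bi <- ord[b0:min(b0 + cfg$batch_size - 1L, length(ord))]
        xb <- dtr$x[bi, , , , drop = FALSE]
        yb <- if (cfg$task == "classify") dtr$y[bi]
              else dtr$y[bi, , , , drop = FALSE]
        fw <- nk_model_forward(model, xb, training = TRUE)
        l <- task_loss(cfg, fw$out, yb)
        nk_zero_grads(model$reg$layers)
        nk_model_backward(model, fw$cache, l$dout)
        optim_step(opt)
        losses <- c(losses, l$loss)
      }
      vm <- evaluate_model(model, dval)
      row <- data.frame(epoch = ep, train_loss = mean(losses))
      for (nm in names(vm)) row[[paste0("val_", nm)]] <- vm[[nm]]
      trace <- rbind(trace, row)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  %s", ep, mean(losses),
                        paste(sprintf("%s=%.4f", names(vm), unlist(vm)),
                              collapse = " ")))
    }
  })
  structure(list(config = cfg, trace = trace,
                 final = as.list(trace[nrow(trace), -1L]),
                 model = model),
            class = "nk_run")
}

#' @export
print.nk_run <- function(x, ...) {
  cat(sprintf("<nk_run> task=%s epochs=%d  final: %s\n", x$config$task,
              x$config$epochs,
              paste(sprintf("%s=%.4f", names(x$final), unlist(x$final)),
                    collapse = " ")))
  invisible(x)
}

#' k-fold cross-validation
#'
#' Trains one model per fold on the remaining folds and aggregates the
#' task metric (classification accuracy, segmentation Dice, detection MSE)
#' as mean and standard deviation over folds.
#'
#' @param cfg a [train_config()].
#' @param data a `nk_dataset`.
#' @param k number of folds.
#' @param spec,variant forwarded to [run_training()].
#' @param verbose print per-fold progress.
#' @return an object of class `nk_fold_report` with per-fold values, `mean`
#'   and `sd`.
#' @export
run_crossval <- function(cfg, data, k = cfg$folds, spec = NULL,
                         variant = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  n <- ds_n(data)
  if (n < k) stop("fewer samples than folds")
  folds <- kfold_split(n, k, seed = cfg$seed)
  metric_name <- switch(cfg$task, classify = "accuracy", segment = "dice",
                        detect = "mse")
  vals <- numeric(k)
  for (f in seq_len(k)) {
    # folds share the config seed: fold-to-fold variation reflects the data,
    # not the initialization
    run <- run_training(cfg, ds_subset(data, folds[[f]]$train),
                        spec = spec, variant = variant)
    ev <- evaluate_model(run$model, ds_subset(data, folds[[f]]$test))
    vals[f] <- ev[[metric_name]]
    if (verbose) message(sprintf("fold %d: %s = %.4f", f, metric_name, vals[f]))
  }
  structure(list(metric = metric_name,
                 folds = data.frame(fold = seq_len(k), value = vals),
                 mean = mean(vals), sd = stats::sd(vals)),
            class = "nk_fold_report")
}

#' @export
print.nk_fold_report <- function(x, ...) {
  cat(sprintf("<nk_fold_report> %s over %d folds: %.4f +- %.4f\n",
              x$metric, nrow(x$folds), x$mean, x$sd))
  invisible(x)
}
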