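# Declarative model specifications and the four network variants.
#
# The unstated widths of the published architectures (initial classifier
# channels, transition compression, recurrent-kernel form, upsampling path)
# were calibrated once against the published trainable-parameter counts and
# frozen as the defaults below; the calibration is recorded in the
# architecture manifest (`write_model_spec()`) and discussed in the methods
# vignette.

NK_VARIANTS <- c("densenet", "dcrn", "r2unet", "udnet")

#' Declarative model specification
#'
#' @param variant one of `"densenet"`, `"dcrn"` (classifiers), `"r2unet"`
#'   (segmenter), `"udnet"` (density regressor).
#' @param input_shape `c(height, width, channels)`; for the encoder-decoder
#'   variants height/width may be `NA` (any multiple of 16 works).
#' @param num_outputs classes (classifiers) or output maps (encoder-decoders).
#' @param channel_schedule symmetric channel schedule for the
#'   encoder-decoder variants, e.g. `1, 32, 64, 128, 256, 128, 64, 32, 1`.
#' @param blocks,layers_per_block,growth_rate dense-network geometry for the
#'   classifier variants.
#' @param init_channels channels produced by the classifiers' initial 3x3
#'   convolution (calibrated default 92).
#' @param time_steps recurrent time steps; defaults per variant
#'   (densenet 0, dcrn 2, r2unet 2, udnet 3).
#' @param weight_mode recurrent kernel sharing across unrolled steps; see
#'   [rcl_config()].  Defaults per variant.
#' @param head `"softmax"` for classifiers, `"sigmoid"` /
#'   `"sigmoid-regression"` for the pixel-map variants.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(variant = NK_VARIANTS,
                       input_shape = NULL, num_outputs = NULL,
                       channel_schedule = NULL,
                       blocks = 4L, layers_per_block = 7L, growth_rate = 12L,
                       init_channels = 92L,
                       time_steps = NULL, weight_mode = NULL, head = NULL) {
  variant <- match.arg(variant)
  is_cls <- variant %in% c("densenet", "dcrn")
  if (is.null(time_steps))
    time_steps <- switch(variant, densenet = 0L, dcrn = 2L, r2unet = 2L, udnet = 3L)
  if (is.null(weight_mode))
    weight_mode <- if (is_cls) "shared" else "distinct"
  if (is.null(head))
    head <- switch(variant, densenet = , dcrn = "softmax",
                   r2unet = "sigmoid", udnet = "sigmoid-regression")
  if (is_cls) {
    if (is.null(input_shape)) input_shape <- c(32L, 32L, 3L)
    if (is.null(num_outputs)) num_outputs <- 4L
    if (blocks < 1 || layers_per_block < 0 || growth_rate < 1)
      stop("invalid dense-network geometry")
    sp <- min(input_shape[1L], input_shape[2L]) / 2^blocks
    if (sp < 1 || sp != round(sp))
      stop("input size must be divisible by 2^blocks")
  } else {
    if (is.null(input_shape)) input_shape <- c(NA, NA, 1L)
    if (is.null(num_outputs)) num_outputs <- 1L
    if (is.null(channel_schedule))
      channel_schedule <- c(1L, 32L, 64L, 128L, 256L, 128L, 64L, 32L, 1L)
    L <- length(channel_schedule)
    if (L < 5L || L %% 2L == 0L)
      stop("channel_schedule must have odd length >= 5")
    body <- channel_schedule[-c(1L, L)]
    if (!all(body == rev(body)))
      stop("channel_schedule must be symmetric for encoder/decoder variants")
    if (channel_schedule[1L] != input_shape[3L] && !is.na(input_shape[3L]))
      input_shape[3L] <- channel_schedule[1L]
  }
  structure(list(variant = variant, input_shape = input_shape,
                 num_outputs = as.integer(num_outputs),
                 channel_schedule = channel_schedule,
                 blocks = as.integer(blocks),
                 layers_per_block = as.integer(layers_per_block),
                 growth_rate = as.integer(growth_rate),
                 init_channels = as.integer(init_channels),
                 time_steps = as.integer(time_steps),
                 weight_mode = weight_mode, head = head),
            class = "model_spec")
}

# ---- builders ---------------------------------------------------------------

build_classifier <- function(spec, reg) {
  k0 <- spec$init_channels
  tmpl <- rcl_config(out_channels = spec$growth_rate,
                     time_steps = spec$time_steps,
                     weight_mode = spec$weight_mode,
                     recurrent_kernel = "3x3",
                     recurrent_bias = TRUE, recurrent_bn = TRUE)
  init <- ly_conv3(reg, spec$input_shape[3L], k0, bias = TRUE)
  blocks <- vector("list", spec$blocks)
  trans <- vector("list", spec$blocks)
  cin <- k0
  for (b in seq_len(spec$blocks)) {
    bcfg <- dense_block_config(spec$layers_per_block, spec$growth_rate,
                               input_channels = cin,
                               time_steps = spec$time_steps,
                               keep_recurrent_params = TRUE)
    blocks[[b]] <- new_dense_block(reg, bcfg, tmpl)
    cin <- blocks[[b]]$cout
    trans[[b]] <- new_transition(reg, cin, cin, bias = TRUE)
  }
  fc <- ly_linear(reg, cin, spec$num_outputs)
  list(init = init, blocks = blocks, trans = trans, fc = fc, feat_dim = cin)
}

classifier_fwd <- function(net, x, training = FALSE) {
  ci <- conv3_fwd(net$init, x)
  z <- ci$y
  bc <- list(); tc <- list()
  for (b in seq_along(net$blocks)) {
    o <- dense_block_fwd(net$blocks[[b]], z, training)
    bc[[b]] <- o$cache
    t <- transition_fwd(net$trans[[b]], o$y, training)
    tc[[b]] <- t$cache
    z <- t$y
  }
  g <- gap_fwd(z)
  f <- linear_fwd(net$fc, g$y)
  list(out = f$y, features = g$y,
       cache = if (training) list(init = ci$cache, blocks = bc, trans = tc,
                                  gap = g$cache, fc = f$cache) else NULL)
}

classifier_bwd <- function(net, cache, dout) {
  d <- linear_bwd(net$fc, cache$fc, dout)
  d <- gap_bwd(cache$gap, d)
  for (b in rev(seq_along(net$blocks))) {
    d <- transition_bwd(net$trans[[b]], cache$trans[[b]], d)
    d <- dense_block_bwd(net$blocks[[b]], cache$blocks[[b]], d)
  }
  conv3_bwd(net$init, cache$init, d)
  invisible(NULL)
}

build_unet <- function(spec, reg) {
  sch <- spec$channel_schedule
  L <- length(sch)
  n_enc <- (L - 3L) %/% 2L
  enc_out <- sch[2L:(1L + n_enc)]
  bott_out <- sch[2L + n_enc]
  dec_out <- sch[(3L + n_enc):(L - 1L)]
  in_ch <- sch[1L]
  ud <- spec$variant == "udnet"
  cfg0 <- rcl_config(out_channels = 1L, time_steps = spec$time_steps,
                     weight_mode = spec$weight_mode,
                     recurrent_kernel = if (ud) "1x1" else "dw3x3",
                     recurrent_bias = ud, recurrent_bn = FALSE, bias = TRUE,
                     unroll = if (ud) "iterations" else "refinements")
  mk <- function(cin, cout) {
    cfg <- cfg0
    cfg$out_channels <- as.integer(cout)
    new_rcl(reg, cin, cfg)
  }
  enc <- list(); cin <- in_ch
  for (i in seq_len(n_enc)) { enc[[i]] <- mk(cin, enc_out[i]); cin <- enc_out[i] }
  bott <- mk(cin, bott_out)
  # decoder: nearest-neighbour upsampling; the udnet variant reduces channels
  # with a 1x1 convolution before concatenation
  ups <- list(); dec <- list()
  cin <- bott_out
  for (i in seq_len(n_enc)) {
    skip_ch <- enc_out[n_enc - i + 1L]
    if (ud) {
      ups[[i]] <- ly_conv1(reg, cin, dec_out[i], bias = FALSE)
      dci <- dec_out[i] + skip_ch
    } else {
      ups[[i]] <- NULL
      dci <- cin + skip_ch
    }
    dec[[i]] <- mk(dci, dec_out[i])
    cin <- dec_out[i]
  }
  head <- ly_conv1(reg, cin, spec$num_outputs, bias = TRUE)
  list(enc = enc, bott = bott, ups = ups, dec = dec, head = head,
       n_enc = n_enc, ud = ud)
}

unet_fwd <- function(net, x, training = FALSE) {
  n_enc <- net$n_enc
  if (any(dim(x)[2:3] %% 2L^n_enc != 0L))
    stop("input spatial dimensions must be multiples of ", 2L^n_enc)
  skips <- list(); ec <- list(); pc <- list()
  z <- x
  for (i in seq_len(n_enc)) {
    o <- rcl_fwd(net$enc[[i]], z, training)
    skips[[i]] <- o$y
    ec[[i]] <- o$cache
    p <- maxpool2_fwd(o$y)
    pc[[i]] <- p$cache
    z <- p$y
  }
  ob <- rcl_fwd(net$bott, z, training)
  z <- ob$y
  uc <- list(); dc <- list(); skip_ch <- integer(n_enc)
  for (i in seq_len(n_enc)) {
    u <- upnn2_fwd(z)
    if (net$ud) {
      cu <- conv1_fwd(net$ups[[i]], u)
      uc[[i]] <- cu$cache
      u <- cu$y
    } else uc[[i]] <- NA
    sk <- skips[[n_enc - i + 1L]]
    skip_ch[i] <- dim(u)[4L]
    z <- concat_c(u, sk)
    o <- rcl_fwd(net$dec[[i]], z, training)
    dc[[i]] <- o$cache
    z <- o$y
  }
  ho <- conv1_fwd(net$head, z)
  list(out = ho$y,
       cache = if (training) list(enc = ec, pool = pc, bott = ob$cache,
                                  up = uc, dec = dc, head = ho$cache,
                                  skip_ch = skip_ch) else NULL)
}

unet_bwd <- function(net, cache, dout) {
  n_enc <- net$n_enc
  d <- conv1_bwd(net$head, cache$head, dout)
  dskips <- vector("list", n_enc)
  for (i in rev(seq_len(n_enc))) {
    d <- rcl_bwd(net$dec[[i]], cache$dec[[i]], d)
    sp <- split_c(d, cache$skip_ch[i])
    du <- sp[[1L]]
    dskips[[n_enc - i + 1L]] <- sp[[2L]]
    if (net$ud) du <- conv1_bwd(net$ups[[i]], cache$up[[i]], du)
    d <- upnn2_bwd(du)
  }
  d <- rcl_bwd(net$bott, cache$bott, d)
  for (i in rev(seq_len(n_enc))) {
    d <- maxpool2_bwd(cache$pool[[i]], d)
    d <- d + dskips[[i]]
    d <- rcl_bwd(net$enc[[i]], cache$enc[[i]], d)
  }
  invisible(NULL)
}

#' Build a network from a model specification
#'
#' Constructs the network with seeded He-normal initialization.  Two builds
#' from the same spec and seed produce identical parameters and therefore
#' identical forward outputs.
#'
#' @param spec a [model_spec()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `nk_model`.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  reg <- nk_reg_new()
  net <- with_build_seed(seed, {
    if (spec$variant %in% c("densenet", "dcrn")) build_classifier(spec, reg)
    else build_unet(spec, reg)
  })
  m <- new.env(parent = emptyenv())
  m$spec <- spec
  m$reg <- reg
  m$net <- net
  m$seed <- as.integer(seed)
  class(m) <- "nk_model"
  m
}

nk_model_forward <- function(model, x, training = FALSE) {
  if (model$spec$variant %in% c("densenet", "dcrn"))
    classifier_fwd(model$net, x, training)
  else unet_fwd(model$net, x, training)
}

nk_model_backward <- function(model, cache, dout) {
  if (model$spec$variant %in% c("densenet", "dcrn"))
    classifier_bwd(model$net, cache, dout)
  else unet_bwd(model$net, cache, dout)
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars, including batch-normalization scale and
#' shift (running statistics are buffers, not parameters).  Frozen layers
#' contribute zero.
#'
#' @param model an `nk_model`.
#' @return integer count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "nk_model"))
  nk_n_params(model$reg$layers)
}

#' Freeze or unfreeze all parameters of a model
#'
#' @param model an `nk_model`.
#' @param frozen logical.
#' @export
freeze_parameters <- function(model, frozen = TRUE) {
  for (L in model$reg$layers) L$frozen <- frozen
  invisible(model)
}

#' Run a model on new samples
#'
#' Classifiers return an `n x num_outputs` matrix of softmax probabilities
#' (rows sum to one); encoder-decoder variants return sigmoid-activated
#' per-pixel maps of the same spatial size as the input.
#'
#' @param object an `nk_model`.
#' @param x 4-D array of samples `(n, height, width, channels)`.
#' @param type `"response"` for probabilities/maps, `"features"` for the
#'   globally average-pooled pre-head representation (classifiers only).
#' @param batch_size samples per internal forward chunk.
#' @param ... unused.
#' @export
predict.nk_model <- function(object, x, type = c("response", "features"),
                             batch_size = 16L, ...) {
  type <- match.arg(type)
  nk_stopifnot_map(x)
  n <- dim(x)[1L]
  is_cls <- object$spec$variant %in% c("densenet", "dcrn")
  if (type == "features" && !is_cls)
    stop("model has no pre-head pooling block; features are defined for classifiers")
  out <- NULL
  for (i0 in seq(1L, n, by = batch_size)) {
    idx <- i0:min(i0 + batch_size - 1L, n)
    fw <- nk_model_forward(object, x[idx, , , , drop = FALSE], training = FALSE)
    piece <- if (type == "features") fw$features
             else if (is_cls) softmax_rows(fw$out)
             else sigmoid(fw$out)
    out <- if (is.null(out)) piece else {
      if (is.matrix(piece)) rbind(out, piece) else {
        d <- dim(out); d[1L] <- d[1L] + dim(piece)[1L]
        tmp <- array(0, d)
        tmp[seq_len(dim(out)[1L]), , , ] <- out
        tmp[dim(out)[1L] + seq_len(dim(piece)[1L]), , , ] <- piece
        tmp
      }
    }
  }
  out
}

#' @export
print.nk_model <- function(x, ...) {
  cat(sprintf("<nk_model> variant=%s  trainable parameters: %s (%.3f M)\n",
              x$spec$variant, format(count_parameters(x), big.mark = ","),
              count_parameters(x) / 1e6))
  invisible(x)
}

# ---- architecture manifest --------------------------------------------------

#' Read / write the architecture manifest (YAML)
#'
#' The manifest records the calibrated defaults per variant: geometry,
#' channel schedule, time steps, weight mode and head.
#'
#' @param spec a [model_spec()].
#' @param path file path.
#' @return `read_model_spec()` returns a [model_spec()].
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "model_spec"))
  yaml::write_yaml(list(
    variant = spec$variant,
    input_shape = as.integer(spec$input_shape),
    num_outputs = spec$num_outputs,
    blocks = spec$blocks, layers = spec$layers_per_block,
    growth_rate = spec$growth_rate, init_channels = spec$init_channels,
    schedule = as.integer(spec$channel_schedule),
    t = spec$time_steps, weight_mode = spec$weight_mode, head = spec$head),
    path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  y <- yaml::read_yaml(path)
  model_spec(variant = y$variant,
             input_shape = if (!is.null(y$input_shape)) unlist(y$input_shape),
             num_outputs = y$num_outputs,
             channel_schedule = if (!is.null(y$schedule)) unlist(y$schedule),
             blocks = if (!is.null(y$blocks)) y$blocks else 4L,
             layers_per_block = if (!is.null(y$layers)) y$layers else 7L,
             growth_rate = if (!is.null(y$growth_rate)) y$growth_rate else 12L,
             init_channels = if (!is.null(y$init_channels)) y$init_channels else 92L,
             time_steps = y$t, weight_mode = y$weight_mode, head = y$head)
}
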