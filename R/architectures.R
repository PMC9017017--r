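# Network architectures: recurrent convolutional layers, recurrent residual
# units, densely connected (recurrent) blocks, transitions, and the four
# model variants built from declarative specs.
#
# A recurrent convolutional layer (RCL) computes, for input x,
#   a    = conv_f(relu(BN(x)))                       (feed-forward term)
#   h_s  = a + conv_r[s](relu(BN_r[s](h_{s-1}))),  h_0 = a,
# unrolled for a fixed number of refinement steps.  `weight_mode = "shared"`
# reuses one recurrent kernel (and one recurrent BN) at every step, so the
# parameter count is independent of the number of steps; `"distinct"` gives
# each unrolled step its own recurrent kernel.

#' Configuration for a recurrent convolutional layer
#'
#' @param out_channels number of output channels.
#' @param time_steps number of recurrent time steps `t` (non-negative).
#'   With `t = 0` the layer is a plain BN-ReLU-conv.
#' @param weight_mode `"shared"` reuses a single recurrent kernel at every
#'   unrolled step; `"distinct"` allocates one kernel per step.
#' @param kernel spatial extent of the feed-forward kernel (odd; fixed 3 here).
#' @param recurrent_kernel form of the recurrent kernel: full `"3x3"`,
#'   pointwise `"1x1"`, or per-channel `"dw3x3"` (depthwise 3x3).
#' @param recurrent_bias,recurrent_bn whether the recurrent convolutions carry
#'   a bias / are preceded by their own batch normalization.
#' @param bias whether the feed-forward convolution carries a bias.
#' @param unroll `"refinements"` runs `t` recurrent steps after the
#'   feed-forward pass; `"iterations"` reads `t` as the total number of
#'   iterations, i.e. `t - 1` recurrent steps.
#' @param in_channels optional expected input channel count; forward passes
#'   reject inputs that do not match.
#' @return an object of class `rcl_config`.
#' @export
rcl_config <- function(out_channels, time_steps = 2L,
                       weight_mode = c("shared", "distinct"),
                       kernel = 3L,
                       recurrent_kernel = c("3x3", "1x1", "dw3x3"),
                       recurrent_bias = TRUE, recurrent_bn = TRUE,
                       bias = TRUE,
                       unroll = c("refinements", "iterations"),
                       in_channels = NULL) {
  weight_mode <- match.arg(weight_mode)
  recurrent_kernel <- match.arg(recurrent_kernel)
  unroll <- match.arg(unroll)
  if (time_steps < 0) stop("time_steps must be non-negative")
  if (kernel %% 2L == 0L) stop("kernel must be odd-sized")
  if (out_channels < 1) stop("out_channels must be positive")
  structure(list(out_channels = as.integer(out_channels),
                 time_steps = as.integer(time_steps),
                 weight_mode = weight_mode, kernel = as.integer(kernel),
                 recurrent_kernel = recurrent_kernel,
                 recurrent_bias = recurrent_bias, recurrent_bn = recurrent_bn,
                 bias = bias, unroll = unroll,
                 in_channels = in_channels),
            class = "rcl_config")
}

#' Configuration for a densely connected (recurrent) block
#'
#' Layer `l` of the block receives the concatenation of the block input and
#' all previous layer outputs (`k * (l - 1) + k0` channels) and emits
#' `growth_rate` channels.
#'
#' @param num_layers number of layers `L` in the block.
#' @param growth_rate channels appended by each layer (`k`).
#' @param input_channels channels entering the block (`k0`).
#' @param time_steps recurrent steps per layer; `0` gives plain feed-forward
#'   convolutions (the dense-network baseline).
#' @param keep_recurrent_params instantiate the recurrent kernels even when
#'   `time_steps = 0`, so the feed-forward baseline is parameter-for-parameter
#'   identical to its recurrent counterpart.
#' @return an object of class `dense_block_config`.
#' @export
dense_block_config <- function(num_layers = 7L, growth_rate = 12L,
                               input_channels, time_steps = 2L,
                               keep_recurrent_params = FALSE) {
  if (num_layers < 0) stop("num_layers must be >= 0")
  if (growth_rate < 1 || input_channels < 1)
    stop("growth_rate and input_channels must be >= 1")
  structure(list(num_layers = as.integer(num_layers),
                 growth_rate = as.integer(growth_rate),
                 input_channels = as.integer(input_channels),
                 time_steps = as.integer(time_steps),
                 keep_recurrent_params = keep_recurrent_params),
            class = "dense_block_config")
}

# ---- internal constructors --------------------------------------------------

new_rec_unit <- function(reg, cfg) {
  conv <- switch(cfg$recurrent_kernel,
    "3x3"   = ly_conv3(reg, cfg$out_channels, cfg$out_channels, bias = cfg$recurrent_bias),
    "1x1"   = ly_conv1(reg, cfg$out_channels, cfg$out_channels, bias = cfg$recurrent_bias),
    "dw3x3" = ly_dw3(reg, cfg$out_channels, bias = cfg$recurrent_bias))
  bn <- if (cfg$recurrent_bn) ly_bn(reg, cfg$out_channels) else NULL
  list(conv = conv, bn = bn)
}

rcl_steps <- function(cfg) {
  if (cfg$unroll == "refinements") cfg$time_steps else max(cfg$time_steps - 1L, 0L)
}

new_rcl <- function(reg, cin, cfg, force_recurrent = FALSE) {
  S <- rcl_steps(cfg)
  n_units <- if (cfg$weight_mode == "shared") min(1L, max(S, if (force_recurrent) 1L else 0L))
             else S
  if (force_recurrent && n_units == 0L) n_units <- 1L
  rc <- list(bn_f = ly_bn(reg, cin),
             conv_f = ly_conv3(reg, cin, cfg$out_channels, bias = cfg$bias),
             rec = lapply(seq_len(n_units), function(i) new_rec_unit(reg, cfg)),
             S = S, shared = cfg$weight_mode == "shared",
             cin = cin, cout = cfg$out_channels)
  class(rc) <- "nk_rcl"
  rc
}

conv_any_fwd <- function(L, x) {
  switch(L$kind, conv3 = conv3_fwd(L, x), conv1 = conv1_fwd(L, x),
         dw3 = dw3_fwd(L, x))
}

conv_any_bwd <- function(L, cache, dy) {
  switch(L$kind, conv3 = conv3_bwd(L, cache, dy), conv1 = conv1_bwd(L, cache, dy),
         dw3 = dw3_bwd(L, cache, dy))
}

rcl_fwd <- function(rc, x, training = FALSE) {
  if (dim(x)[4L] != rc$cin)
    stop("input has ", dim(x)[4L], " channels but layer expects ", rc$cin)
  bnf <- bn_fwd(rc$bn_f, x, training)
  r1 <- relu_fwd(bnf$y)
  cf <- conv3_fwd(rc$conv_f, r1)
  a <- cf$y
  h <- a
  steps <- vector("list", rc$S)
  if (rc$S > 0L) for (s in seq_len(rc$S)) {
    u <- rc$rec[[if (rc$shared) 1L else s]]
    if (!is.null(u$bn)) {
      bo <- bn_fwd(u$bn, h, training)
      hb <- bo$y
    } else {
      bo <- NULL
      hb <- h
    }
    hr <- relu_fwd(hb)
    cv <- conv_any_fwd(u$conv, hr)
    h <- a + cv$y
    if (training)
      steps[[s]] <- list(bn = if (is.null(bo)) NULL else bo$cache,
                         relu_y = hr, conv = cv$cache)
  }
  cache <- if (training) list(bn_f = bnf$cache, r1 = r1, conv_f = cf$cache,
                              steps = steps) else NULL
  list(y = h, cache = cache)
}

rcl_bwd <- function(rc, cache, dh) {
  da <- array(0, dim(dh))
  cur <- dh
  if (rc$S > 0L) for (s in rev(seq_len(rc$S))) {
    u <- rc$rec[[if (rc$shared) 1L else s]]
    st <- cache$steps[[s]]
    da <- da + cur
    dhr <- conv_any_bwd(u$conv, st$conv, cur)
    dhb <- relu_bwd(st$relu_y, dhr)
    cur <- if (is.null(u$bn)) dhb else bn_bwd(u$bn, st$bn, dhb)
  }
  da <- da + cur
  dr1 <- conv3_bwd(rc$conv_f, cache$conv_f, da)
  dbn <- relu_bwd(cache$r1, dr1)
  bn_bwd(rc$bn_f, cache$bn_f, dbn)
}

new_rru <- function(reg, cfg, n_layers = 2L) {
  rr <- list(rcls = lapply(seq_len(n_layers), function(i)
    new_rcl(reg, cfg$out_channels, cfg)),
    cout = cfg$out_channels)
  class(rr) <- "nk_rru"
  rr
}

rru_fwd <- function(rr, x, training = FALSE) {
  if (dim(x)[4L] != rr$cout)
    stop("shape mismatch between skip and branch: input has ", dim(x)[4L],
         " channels, unit expects ", rr$cout)
  h <- x
  caches <- vector("list", length(rr$rcls))
  for (i in seq_along(rr$rcls)) {
    o <- rcl_fwd(rr$rcls[[i]], h, training)
    h <- o$y
    caches[[i]] <- o$cache
  }
  list(y = x + h, cache = caches)
}

rru_bwd <- function(rr, cache, dy) {
  dh <- dy
  for (i in rev(seq_along(rr$rcls))) dh <- rcl_bwd(rr$rcls[[i]], cache[[i]], dh)
  dy + dh
}

new_dense_block <- function(reg, bcfg, rcl_template) {
  cfgs <- list()
  cin <- bcfg$input_channels
  layers <- vector("list", bcfg$num_layers)
  for (l in seq_len(bcfg$num_layers)) {
    cfg <- rcl_template
    cfg$out_channels <- bcfg$growth_rate
    cfg$time_steps <- bcfg$time_steps
    layers[[l]] <- new_rcl(reg, cin, cfg,
                           force_recurrent = isTRUE(bcfg$keep_recurrent_params))
    cin <- cin + bcfg$growth_rate
  }
  bl <- list(layers = layers, k0 = bcfg$input_channels,
             k = bcfg$growth_rate, cout = cin)
  class(bl) <- "nk_dense_block"
  bl
}

dense_block_fwd <- function(bl, x, training = FALSE) {
  z <- x
  caches <- vector("list", length(bl$layers))
  for (l in seq_along(bl$layers)) {
    o <- rcl_fwd(bl$layers[[l]], z, training)
    caches[[l]] <- o$cache
    z <- concat_c(z, o$y)
  }
  list(y = z, cache = caches)
}

dense_block_bwd <- function(bl, cache, dz) {
  for (l in rev(seq_along(bl$layers))) {
    cin_l <- bl$k0 + (l - 1L) * bl$k
    sp <- split_c(dz, cin_l)
    dz <- sp[[1L]] + rcl_bwd(bl$layers[[l]], cache[[l]], sp[[2L]])
  }
  dz
}

new_transition <- function(reg, cin, cout, bias = TRUE) {
  tr <- list(bn = ly_bn(reg, cin), conv = ly_conv1(reg, cin, cout, bias = bias))
  class(tr) <- "nk_transition"
  tr
}

transition_fwd <- function(tr, x, training = FALSE) {
  bo <- bn_fwd(tr$bn, x, training)
  r <- relu_fwd(bo$y)
  co <- conv1_fwd(tr$conv, r)
  po <- avgpool2_fwd(co$y)
  list(y = po$y, cache = if (training)
    list(bn = bo$cache, r = r, conv = co$cache, pool = po$cache) else NULL)
}

transition_bwd <- function(tr, cache, dy) {
  d <- avgpool2_bwd(cache$pool, dy)
  d <- conv1_bwd(tr$conv, cache$conv, d)
  d <- relu_bwd(cache$r, d)
  bn_bwd(tr$bn, cache$bn, d)
}

# ---- functional operations --------------------------------------------------

with_build_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Apply a recurrent convolutional layer to a feature map
#'
#' Runs BN-ReLU-conv with `time_steps` additive recurrent refinements (see
#' [rcl_config()]).  Weights are drawn once from a seeded He-normal
#' initialization, so the output is a deterministic function of
#' `(x, cfg, seed)`.  Spatial size is preserved (same padding).
#'
#' @param x 4-D feature map `(batch, height, width, channels)`.
#' @param cfg an [rcl_config()].
#' @param seed integer seed for weight initialization.
#' @return feature map with `cfg$out_channels` channels.
#' @export
recurrent_conv_layer <- function(x, cfg, seed = 1L) {
  nk_stopifnot_map(x)
  stopifnot(inherits(cfg, "rcl_config"))
  if (!is.null(cfg$in_channels) && dim(x)[4L] != cfg$in_channels)
    stop("input has ", dim(x)[4L], " channels but cfg expects ", cfg$in_channels)
  rc <- with_build_seed(seed, new_rcl(nk_reg_new(), dim(x)[4L], cfg))
  rcl_fwd(rc, x, training = FALSE)$y
}

#' Apply a recurrent residual unit
#'
#' A stack of two recurrent convolutional layers wrapped in an identity skip
#' connection: `y = x + F(x)`.  Inputs whose channel count differs from
#' `cfg$out_channels` are first passed through a seeded 1x1 projection, per
#' the unit's contract that the skip and branch shapes agree.
#'
#' @inheritParams recurrent_conv_layer
#' @param n_layers number of stacked recurrent conv layers in the branch.
#' @return feature map with `cfg$out_channels` channels, same spatial size.
#' @export
recurrent_residual_unit <- function(x, cfg, seed = 1L, n_layers = 2L) {
  nk_stopifnot_map(x)
  stopifnot(inherits(cfg, "rcl_config"))
  with_build_seed(seed, {
    reg <- nk_reg_new()
    proj <- if (dim(x)[4L] != cfg$out_channels)
      ly_conv1(reg, dim(x)[4L], cfg$out_channels, bias = FALSE) else NULL
    rr <- new_rru(reg, cfg, n_layers = n_layers)
    if (!is.null(proj)) x <- conv1_fwd(proj, x)$y
    rru_fwd(rr, x, training = FALSE)$y
  })
}

#' Apply a densely connected (recurrent) block
#'
#' Each layer receives the concatenation of the block input and all previous
#' layer outputs and appends `growth_rate` channels, so the output has
#' `k0 + L * k` channels.
#'
#' @inheritParams recurrent_conv_layer
#' @param cfg a [dense_block_config()].
#' @export
dense_recurrent_block <- function(x, cfg, seed = 1L) {
  nk_stopifnot_map(x)
  stopifnot(inherits(cfg, "dense_block_config"))
  if (dim(x)[4L] != cfg$input_channels)
    stop("input has ", dim(x)[4L], " channels but cfg expects ", cfg$input_channels)
  tmpl <- rcl_config(out_channels = cfg$growth_rate, time_steps = cfg$time_steps,
                     weight_mode = "shared", recurrent_kernel = "3x3")
  bl <- with_build_seed(seed, new_dense_block(nk_reg_new(), cfg, tmpl))
  dense_block_fwd(bl, x, training = FALSE)$y
}

#' Apply a transition block (1x1 conv + 2x2 average pooling)
#'
#' Halves the spatial dimensions and maps to `out_channels` channels.
#' Odd spatial dimensions are rejected.
#'
#' @inheritParams recurrent_conv_layer
#' @param out_channels channels after the 1x1 convolution.
#' @export
transition_block <- function(x, out_channels, seed = 1L) {
  nk_stopifnot_map(x)
  tr <- with_build_seed(seed, new_transition(nk_reg_new(), dim(x)[4L], out_channels))
  transition_fwd(tr, x, training = FALSE)$y
}
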