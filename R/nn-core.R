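# Minimal CPU engine for the networks in this package.
#
# Feature maps are dense numeric arrays with dim = c(batch, height, width,
# channels).  Convolutions are evaluated as sums of shifted-slice matrix
# products so that every heavy operation is a single BLAS GEMM; backward
# passes are written per layer (no generic autograd).  Parameter-holding
# layers are environments so gradients accumulate in place; composites keep
# their per-call caches in ordinary lists, which makes weight sharing across
# unrolled recurrent steps safe.

nk_stopifnot_map <- function(x) {
  if (!is.array(x) || length(dim(x)) != 4L)
    stop("feature map must be a 4-D array (batch, height, width, channels)")
  if (!all(is.finite(x))) stop("feature map contains non-finite values")
  invisible(x)
}

# ---- parameter registry -----------------------------------------------------

nk_reg_new <- function() {
  e <- new.env(parent = emptyenv())
  e$layers <- list()
  e
}

nk_reg_add <- function(reg, layer) {
  reg$layers[[length(reg$layers) + 1L]] <- layer
  layer
}

nk_layer_new <- function(reg, params) {
  L <- new.env(parent = emptyenv())
  L$p <- params
  L$g <- lapply(params, function(a) a * 0)
  L$frozen <- FALSE
  if (!is.null(reg)) nk_reg_add(reg, L)
  L
}

nk_zero_grads <- function(layers) {
  for (L in layers) for (nm in names(L$g)) L$g[[nm]][] <- 0
  invisible(NULL)
}

nk_n_params <- function(layers) {
  s <- 0L
  for (L in layers) if (!isTRUE(L$frozen)) s <- s + sum(vapply(L$p, length, 0L))
  s
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

# ---- shape helpers ----------------------------------------------------------

as_cmat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1L] * d[2L] * d[3L], d[4L])
  x
}

from_cmat <- function(m, n, h, w, c) {
  dim(m) <- c(n, h, w, c)
  m
}

# ---- 3x3 convolution (same padding) ----------------------------------------

ly_conv3 <- function(reg, cin, cout, bias = TRUE) {
  p <- list(w = he_init(c(3, 3, cin, cout), fan_in = 9 * cin))
  if (bias) p$b <- numeric(cout)
  L <- nk_layer_new(reg, p)
  L$kind <- "conv3"; L$cin <- cin; L$cout <- cout
  L
}

conv3_fwd <- function(L, x) {
  d <- dim(x)
  if (d[4L] != L$cin)
    stop("input has ", d[4L], " channels but layer expects ", L$cin)
  y <- cpp_conv3_fwd(x, L$p$w, L$p$b, d[1L], d[2L], d[3L], L$cin, L$cout)
  list(y = y, cache = x)
}

conv3_bwd <- function(L, cache, dy) {
  d <- dim(dy)
  out <- cpp_conv3_bwd(cache, L$p$w, dy, d[1L], d[2L], d[3L], L$cin, L$cout,
                       !is.null(L$p$b))
  L$g$w <- L$g$w + out$dw
  if (!is.null(L$p$b)) L$g$b <- L$g$b + out$db
  out$dx
}

# ---- 1x1 convolution --------------------------------------------------------

ly_conv1 <- function(reg, cin, cout, bias = TRUE) {
  p <- list(w = he_init(c(cin, cout), fan_in = cin))
  if (bias) p$b <- numeric(cout)
  L <- nk_layer_new(reg, p)
  L$kind <- "conv1"; L$cin <- cin; L$cout <- cout
  L
}

conv1_fwd <- function(L, x) {
  d <- dim(x)
  y <- as_cmat(x) %*% L$p$w
  if (!is.null(L$p$b)) y <- y + rep(L$p$b, each = nrow(y))
  list(y = from_cmat(y, d[1L], d[2L], d[3L], L$cout), cache = x)
}

conv1_bwd <- function(L, cache, dy) {
  d <- dim(cache)
  dym <- as_cmat(dy)
  L$g$w <- L$g$w + crossprod(as_cmat(cache), dym)
  if (!is.null(L$p$b)) L$g$b <- L$g$b + colSums(dym)
  from_cmat(dym %*% t(L$p$w), d[1L], d[2L], d[3L], d[4L])
}

# ---- depthwise 3x3 convolution ----------------------------------------------

ly_dw3 <- function(reg, ch, bias = FALSE) {
  p <- list(w = he_init(c(3, 3, ch), fan_in = 9))
  if (bias) p$b <- numeric(ch)
  L <- nk_layer_new(reg, p)
  L$kind <- "dw3"; L$cin <- ch; L$cout <- ch
  L
}

dw3_fwd <- function(L, x) {
  d <- dim(x)
  y <- cpp_dw3_fwd(x, L$p$w, L$p$b, d[1L], d[2L], d[3L], d[4L])
  list(y = y, cache = x)
}

dw3_bwd <- function(L, cache, dy) {
  d <- dim(dy)
  out <- cpp_dw3_bwd(cache, L$p$w, dy, d[1L], d[2L], d[3L], d[4L],
                     !is.null(L$p$b))
  L$g$w <- L$g$w + out$dw
  if (!is.null(L$p$b)) L$g$b <- L$g$b + out$db
  out$dx
}

# ---- batch normalization ----------------------------------------------------

ly_bn <- function(reg, ch, momentum = 0.1, eps = 1e-5) {
  L <- nk_layer_new(reg, list(gamma = rep(1, ch), beta = numeric(ch)))
  L$kind <- "bn"; L$cin <- ch; L$cout <- ch
  L$rm <- numeric(ch); L$rv <- rep(1, ch)
  L$momentum <- momentum; L$eps <- eps
  L
}

bn_fwd <- function(L, x, training) {
  d <- dim(x); m <- d[1L] * d[2L] * d[3L]; ch <- d[4L]
  if (training) {
    mu <- .colMeans(x, m, ch)
    v <- .colMeans(x * x, m, ch) - mu^2
    v[v < 0] <- 0
    invstd <- 1 / sqrt(v + L$eps)
    xhat <- cpp_channel_affine(x, invstd, -mu * invstd, m, ch)
    L$rm <- (1 - L$momentum) * L$rm + L$momentum * mu
    L$rv <- (1 - L$momentum) * L$rv + L$momentum * v
  } else {
    invstd <- 1 / sqrt(L$rv + L$eps)
    xhat <- cpp_channel_affine(x, invstd, -L$rm * invstd, m, ch)
  }
  y <- cpp_channel_affine(xhat, L$p$gamma, L$p$beta, m, ch)
  list(y = y, cache = list(xhat = xhat, invstd = invstd, dims = d))
}

bn_bwd <- function(L, cache, dy) {
  d <- cache$dims; m <- d[1L] * d[2L] * d[3L]; ch <- d[4L]
  xhat <- cache$xhat
  L$g$gamma <- L$g$gamma + .colSums(dy * xhat, m, ch)
  L$g$beta <- L$g$beta + .colSums(dy, m, ch)
  dxhat <- cpp_channel_affine(dy, L$p$gamma, numeric(ch), m, ch)
  s1 <- .colSums(dxhat, m, ch)
  s2 <- .colSums(dxhat * xhat, m, ch)
  t1 <- cpp_channel_affine(xhat, -s2 / m, -s1 / m, m, ch)
  cpp_channel_affine(dxhat + t1, cache$invstd, numeric(ch), m, ch)
}

# ---- dense (fully connected) ------------------------------------------------

ly_linear <- function(reg, din, dout) {
  L <- nk_layer_new(reg, list(w = he_init(c(din, dout), fan_in = din),
                              b = numeric(dout)))
  L$kind <- "linear"
  L
}

linear_fwd <- function(L, x) {
  list(y = x %*% L$p$w + rep(L$p$b, each = nrow(x)), cache = x)
}

linear_bwd <- function(L, cache, dy) {
  L$g$w <- L$g$w + crossprod(cache, dy)
  L$g$b <- L$g$b + colSums(dy)
  dy %*% t(L$p$w)
}

# ---- stateless ops ----------------------------------------------------------

relu_fwd <- function(x) cpp_relu_fwd(x)

relu_bwd <- function(y, dy) cpp_relu_bwd(y, dy)

maxpool2_fwd <- function(x) {
  d <- dim(x)
  if (d[2L] %% 2L != 0L || d[3L] %% 2L != 0L)
    stop("spatial dimensions must be even for 2x2 pooling")
  io <- seq(1L, d[2L], 2L); ie <- io + 1L
  jo <- seq(1L, d[3L], 2L); je <- jo + 1L
  a <- x[, io, jo, , drop = FALSE]; b <- x[, ie, jo, , drop = FALSE]
  cc <- x[, io, je, , drop = FALSE]; dd <- x[, ie, je, , drop = FALSE]
  y <- pmax(a, b, cc, dd)
  list(y = y, cache = list(m1 = a == y, m2 = b == y, m3 = cc == y, m4 = dd == y,
                           dims = d))
}

maxpool2_bwd <- function(cache, dy) {
  d <- cache$dims
  io <- seq(1L, d[2L], 2L); ie <- io + 1L
  jo <- seq(1L, d[3L], 2L); je <- jo + 1L
  dx <- array(0, d)
  # ties route the gradient to the first slice that attains the max
  m1 <- cache$m1
  m2 <- cache$m2 & !m1
  m3 <- cache$m3 & !m1 & !m2
  m4 <- cache$m4 & !m1 & !m2 & !m3
  dx[, io, jo, ] <- dy * m1
  dx[, ie, jo, ] <- dy * m2
  dx[, io, je, ] <- dy * m3
  dx[, ie, je, ] <- dy * m4
  dx
}

avgpool2_fwd <- function(x) {
  d <- dim(x)
  if (d[2L] %% 2L != 0L || d[3L] %% 2L != 0L)
    stop("spatial dimensions must be even for 2x2 pooling")
  if (d[2L] < 2L || d[3L] < 2L) stop("pooled output would be empty")
  io <- seq(1L, d[2L], 2L); ie <- io + 1L
  jo <- seq(1L, d[3L], 2L); je <- jo + 1L
  y <- (x[, io, jo, , drop = FALSE] + x[, ie, jo, , drop = FALSE] +
        x[, io, je, , drop = FALSE] + x[, ie, je, , drop = FALSE]) / 4
  list(y = y, cache = d)
}

avgpool2_bwd <- function(cache, dy) {
  d <- cache
  io <- seq(1L, d[2L], 2L); ie <- io + 1L
  jo <- seq(1L, d[3L], 2L); je <- jo + 1L
  dx <- array(0, d)
  q <- dy / 4
  dx[, io, jo, ] <- q; dx[, ie, jo, ] <- q
  dx[, io, je, ] <- q; dx[, ie, je, ] <- q
  dx
}

upnn2_fwd <- function(x) {
  d <- dim(x)
  y <- array(0, c(d[1L], 2L * d[2L], 2L * d[3L], d[4L]))
  io <- seq(1L, 2L * d[2L], 2L); ie <- io + 1L
  jo <- seq(1L, 2L * d[3L], 2L); je <- jo + 1L
  y[, io, jo, ] <- x; y[, ie, jo, ] <- x
  y[, io, je, ] <- x; y[, ie, je, ] <- x
  y
}

upnn2_bwd <- function(dy) {
  d <- dim(dy)
  io <- seq(1L, d[2L], 2L); ie <- io + 1L
  jo <- seq(1L, d[3L], 2L); je <- jo + 1L
  dy[, io, jo, , drop = FALSE] + dy[, ie, jo, , drop = FALSE] +
    dy[, io, je, , drop = FALSE] + dy[, ie, je, , drop = FALSE]
}

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1L], da[2L], da[3L], da[4L] + db[4L]))
  y[, , , seq_len(da[4L])] <- a
  y[, , , da[4L] + seq_len(db[4L])] <- b
  y
}

split_c <- function(dy, c1) {
  d <- dim(dy)
  list(dy[, , , seq_len(c1), drop = FALSE],
       dy[, , , (c1 + 1L):d[4L], drop = FALSE])
}

gap_fwd <- function(x) {
  d <- dim(x)
  x3 <- x
  dim(x3) <- c(d[1L], d[2L] * d[3L], d[4L])
  y <- colMeans(aperm(x3, c(2L, 1L, 3L)))
  dim(y) <- c(d[1L], d[4L])
  list(y = y, cache = d)
}

gap_bwd <- function(cache, dy) {
  d <- cache; hw <- d[2L] * d[3L]
  arr <- array(dy / hw, c(d[1L], d[4L], hw))
  x <- aperm(arr, c(1L, 3L, 2L))
  dim(x) <- d
  x
}

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}
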