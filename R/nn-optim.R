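# Losses and optimizers for the training harness.

# Cross-entropy on softmax probabilities. `labels` are 1-based class indices.
loss_softmax_ce <- function(logits, labels) {
  n <- nrow(logits)
  p <- softmax_rows(logits)
  idx <- cbind(seq_len(n), labels)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, grad = dlogits / n)
}

# Soft Dice loss on probabilities in [0, 1], computed jointly over the batch.
# Returns the gradient with respect to the probabilities.
loss_soft_dice <- function(p, y, smooth = 1) {
  num <- 2 * sum(p * y) + smooth
  den <- sum(p) + sum(y) + smooth
  loss <- 1 - num / den
  grad <- -(2 * y * den - num) / den^2
  list(loss = loss, grad = grad)
}

loss_mse <- function(p, y) {
  n <- length(p)
  list(loss = mean((p - y)^2), grad = 2 * (p - y) / n)
}

# ---- optimizers -------------------------------------------------------------

optim_new <- function(layers, method = c("sgd", "adam"), lr = 1e-3,
                      momentum = 0.9, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  method <- match.arg(method)
  st <- new.env(parent = emptyenv())
  st$layers <- layers
  st$method <- method; st$lr <- lr; st$momentum <- momentum
  st$weight_decay <- weight_decay
  st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps; st$t <- 0L
  st$slots <- lapply(layers, function(L)
    lapply(L$p, function(a) list(m = a * 0, v = a * 0)))
  st
}

optim_step <- function(st) {
  st$t <- st$t + 1L
  for (i in seq_along(st$layers)) {
    L <- st$layers[[i]]
    if (isTRUE(L$frozen)) next
    for (nm in names(L$p)) {
      g <- L$g[[nm]]
      if (st$weight_decay > 0) g <- g + st$weight_decay * L$p[[nm]]
      if (st$method == "sgd") {
        v <- st$momentum * st$slots[[i]][[nm]]$m + g
        st$slots[[i]][[nm]]$m <- v
        L$p[[nm]] <- L$p[[nm]] - st$lr * v
      } else {
        m <- st$beta1 * st$slots[[i]][[nm]]$m + (1 - st$beta1) * g
        v <- st$beta2 * st$slots[[i]][[nm]]$v + (1 - st$beta2) * g * g
        st$slots[[i]][[nm]]$m <- m
        st$slots[[i]][[nm]]$v <- v
        mh <- m / (1 - st$beta1^st$t)
        vh <- v / (1 - st$beta2^st$t)
        L$p[[nm]] <- L$p[[nm]] - st$lr * mh / (sqrt(vh) + st$eps)
      }
    }
  }
  invisible(NULL)
}
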