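# Independent oracles: scalar quadruple-loop convolutions and an exhaustive
# assignment enumerator.  These deliberately share no code with the package
# internals they check.

oracle_conv3 <- function(x, w, b = NULL) {
  d <- dim(x); h <- d[2]; wd <- d[3]; cin <- d[4]; cout <- dim(w)[4]
  y <- array(0, c(d[1], h, wd, cout))
  for (n in seq_len(d[1])) for (co in seq_len(cout)) for (r in seq_len(h))
    for (cc in seq_len(wd)) {
      s <- if (is.null(b)) 0 else b[co]
      for (ci in seq_len(cin)) for (di in -1:1) for (dj in -1:1) {
        rr <- r + di; c2 <- cc + dj
        if (rr >= 1 && rr <= h && c2 >= 1 && c2 <= wd)
          s <- s + x[n, rr, c2, ci] * w[di + 2, dj + 2, ci, co]
      }
      y[n, r, cc, co] <- s
    }
  y
}

oracle_conv1 <- function(x, w, b = NULL) {
  d <- dim(x); cin <- d[4]; cout <- ncol(w)
  y <- array(0, c(d[1], d[2], d[3], cout))
  for (n in seq_len(d[1])) for (co in seq_len(cout)) for (r in seq_len(d[2]))
    for (cc in seq_len(d[3])) {
      s <- if (is.null(b)) 0 else b[co]
      for (ci in seq_len(cin)) s <- s + x[n, r, cc, ci] * w[ci, co]
      y[n, r, cc, co] <- s
    }
  y
}

oracle_dw3 <- function(x, w, b = NULL) {
  d <- dim(x); h <- d[2]; wd <- d[3]; ch <- d[4]
  y <- array(0, d)
  for (n in seq_len(d[1])) for (c0 in seq_len(ch)) for (r in seq_len(h))
    for (cc in seq_len(wd)) {
      s <- if (is.null(b)) 0 else b[c0]
      for (di in -1:1) for (dj in -1:1) {
        rr <- r + di; c2 <- cc + dj
        if (rr >= 1 && rr <= h && c2 >= 1 && c2 <= wd)
          s <- s + x[n, rr, c2, c0] * w[di + 2, dj + 2, c0]
      }
      y[n, r, cc, c0] <- s
    }
  y
}

oracle_bn_eval <- function(x, L) {
  d <- dim(x)
  y <- array(0, d)
  for (c0 in seq_len(d[4]))
    y[, , , c0] <- (x[, , , c0] - L$rm[c0]) / sqrt(L$rv[c0] + L$eps) *
      L$p$gamma[c0] + L$p$beta[c0]
  y
}

oracle_relu <- function(x) pmax(x, 0)

oracle_conv_any <- function(L, x) {
  switch(L$kind,
         conv3 = oracle_conv3(x, L$p$w, L$p$b),
         conv1 = oracle_conv1(x, L$p$w, L$p$b),
         dw3 = oracle_dw3(x, L$p$w, L$p$b))
}

# mirrors the recurrent conv layer contract in evaluation mode:
# a = conv_f(relu(BN(x))); h_s = a + conv_r[s](relu(BN_r[s](h_{s-1})))
oracle_rcl <- function(rc, x) {
  a <- oracle_conv3(oracle_relu(oracle_bn_eval(x, rc$bn_f)),
                    rc$conv_f$p$w, rc$conv_f$p$b)
  h <- a
  if (rc$S > 0) for (s in seq_len(rc$S)) {
    u <- rc$rec[[if (rc$shared) 1L else s]]
    hb <- if (is.null(u$bn)) h else oracle_bn_eval(h, u$bn)
    h <- a + oracle_conv_any(u$conv, oracle_relu(hb))
  }
  h
}

oracle_rru <- function(rr, x) {
  h <- x
  for (rc in rr$rcls) h <- oracle_rcl(rc, h)
  x + h
}

# exhaustive one-to-one matcher: maximize matches with distance <= radius,
# then minimize the total matched distance
bf_match <- function(pred, gt, radius) {
  n <- nrow(pred); m <- nrow(gt)
  if (n == 0 || m == 0) return(list(TP = 0L, dist = 0))
  d <- sqrt(outer(pred$row, gt$row, "-")^2 + outer(pred$col, gt$col, "-")^2)
  best <- list(TP = 0L, dist = Inf)
  recurse <- function(i, used, tp, dist) {
    if (i > n) {
      if (tp > best$TP || (tp == best$TP && dist < best$dist))
        best <<- list(TP = tp, dist = dist)
      return(invisible())
    }
    recurse(i + 1L, used, tp, dist)        # leave pred i unmatched
    for (j in seq_len(m)) if (!used[j] && d[i, j] <= radius) {
      used[j] <- TRUE
      recurse(i + 1L, used, tp + 1L, dist + d[i, j])
      used[j] <- FALSE
    }
  }
  recurse(1L, rep(FALSE, m), 0L, 0)
  best
}

rand_map <- function(n, h, w, c, seed = 1) {
  set.seed(seed)
  array(stats::rnorm(n * h * w * c), c(n, h, w, c))
}

# build an RCL through the package internals with randomized BN statistics
make_rcl <- function(cin, cfg, seed = 1, randomize_bn = TRUE) {
  rc <- nucleikit:::with_build_seed(seed,
    nucleikit:::new_rcl(nucleikit:::nk_reg_new(), cin, cfg))
  if (randomize_bn) {
    set.seed(seed + 99)
    jiggle <- function(L) {
      L$p$gamma <- runif(length(L$p$gamma), 0.5, 1.5)
      L$p$beta <- rnorm(length(L$p$beta), 0, 0.3)
      L$rm <- rnorm(length(L$rm), 0, 0.2)
      L$rv <- runif(length(L$rv), 0.5, 2)
    }
    jiggle(rc$bn_f)
    for (u in rc$rec) if (!is.null(u$bn)) jiggle(u$bn)
  }
  rc
}
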