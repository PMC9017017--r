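# Recurrent conv layers, residual units, dense blocks, transitions and the
# model builders.

test_that("recurrent conv layer matches the scalar-loop oracle for t = 0..3", {
  for (t in 0:3) for (mode in c("shared", "distinct")) {
    cfg <- rcl_config(out_channels = 4L, time_steps = t, weight_mode = mode)
    rc <- make_rcl(3L, cfg, seed = 10 + t)
    x <- rand_map(1, 8, 8, 3, seed = t + 1)
    got <- nucleikit:::rcl_fwd(rc, x, training = FALSE)$y
    want <- oracle_rcl(rc, x)
    expect_lt(max(abs(got - want)), 1e-5)
  }
})

test_that("oracle equivalence holds for the pointwise and depthwise recurrent kernels", {
  for (rk in c("1x1", "dw3x3")) for (unroll in c("refinements", "iterations")) {
    cfg <- rcl_config(out_channels = 5L, time_steps = 3L,
                      weight_mode = "distinct", recurrent_kernel = rk,
                      recurrent_bn = FALSE, recurrent_bias = (rk == "1x1"),
                      unroll = unroll)
    rc <- make_rcl(2L, cfg, seed = 31)
    x <- rand_map(2, 6, 7, 2, seed = 5)
    got <- nucleikit:::rcl_fwd(rc, x, training = FALSE)$y
    expect_lt(max(abs(got - oracle_rcl(rc, x))), 1e-5)
  }
})

test_that("t = 0 reduces to a plain BN-ReLU-conv with the forward weights only", {
  cfg0 <- rcl_config(out_channels = 4L, time_steps = 0L)
  rc <- make_rcl(3L, cfg0, seed = 7)
  x <- rand_map(1, 6, 6, 3, seed = 2)
  got <- nucleikit:::rcl_fwd(rc, x, training = FALSE)$y
  plain <- oracle_conv3(oracle_relu(oracle_bn_eval(x, rc$bn_f)),
                        rc$conv_f$p$w, rc$conv_f$p$b)
  expect_equal(got, plain, tolerance = 1e-12)
})

test_that("zero recurrent weights make the output independent of t", {
  outs <- lapply(1:3, function(t) {
    cfg <- rcl_config(out_channels = 4L, time_steps = t, weight_mode = "shared")
    rc <- make_rcl(3L, cfg, seed = 5, randomize_bn = FALSE)
    for (u in rc$rec) {
      u$conv$p$w[] <- 0
      if (!is.null(u$conv$p$b)) u$conv$p$b[] <- 0
    }
    nucleikit:::rcl_fwd(rc, rand_map(1, 5, 5, 3, seed = 9), training = FALSE)$y
  })
  expect_equal(outs[[1]], outs[[2]], tolerance = 1e-12)
  expect_equal(outs[[2]], outs[[3]], tolerance = 1e-12)
})

test_that("recurrent conv layer rejects invalid configurations and inputs", {
  expect_error(rcl_config(out_channels = 4L, time_steps = -1L), "non-negative")
  expect_error(rcl_config(out_channels = 4L, kernel = 4L), "odd")
  cfg <- rcl_config(out_channels = 4L, in_channels = 3L)
  expect_error(recurrent_conv_layer(rand_map(1, 4, 4, 2), cfg), "channels")
})

test_that("recurrent conv layer preserves spatial size and sets channels", {
  cfg <- rcl_config(out_channels = 6L, time_steps = 2L)
  y <- recurrent_conv_layer(rand_map(2, 7, 9, 3), cfg, seed = 3)
  expect_identical(dim(y), c(2L, 7L, 9L, 6L))
})

test_that("recurrent residual unit is the identity when the branch is zeroed", {
  cfg <- rcl_config(out_channels = 3L, time_steps = 2L)
  rr <- nucleikit:::with_build_seed(4,
    nucleikit:::new_rru(nucleikit:::nk_reg_new(), cfg))
  for (rc in rr$rcls) {
    rc$conv_f$p$w[] <- 0; rc$conv_f$p$b[] <- 0
    for (u in rc$rec) { u$conv$p$w[] <- 0; u$conv$p$b[] <- 0 }
  }
  x <- rand_map(1, 5, 5, 3, seed = 11)
  expect_identical(nucleikit:::rru_fwd(rr, x)$y, x)
})

test_that("recurrent residual unit output equals input plus the oracle branch", {
  cfg <- rcl_config(out_channels = 2L, time_steps = 2L)
  rr <- nucleikit:::with_build_seed(12,
    nucleikit:::new_rru(nucleikit:::nk_reg_new(), cfg))
  x <- rand_map(1, 4, 4, 2, seed = 13)
  got <- nucleikit:::rru_fwd(rr, x)$y
  expect_lt(max(abs(got - oracle_rru(rr, x))), 1e-5)
})

test_that("recurrent residual unit preserves shape and projects mismatched inputs", {
  cfg <- rcl_config(out_channels = 4L, time_steps = 1L)
  for (hw in list(c(4L, 4L), c(6L, 10L))) {
    y <- recurrent_residual_unit(rand_map(1, hw[1], hw[2], 4), cfg, seed = 2)
    expect_identical(dim(y), c(1L, hw, 4L))
  }
  y <- recurrent_residual_unit(rand_map(1, 4, 4, 7), cfg, seed = 2)
  expect_identical(dim(y)[4], 4L)
  expect_error(nucleikit:::rru_fwd(
    nucleikit:::new_rru(nucleikit:::nk_reg_new(), cfg),
    rand_map(1, 4, 4, 3)), "mismatch")
})

test_that("dense block channel bookkeeping follows k0 + L * k", {
  x <- rand_map(1, 4, 4, 24, seed = 3)
  cfg <- dense_block_config(num_layers = 7L, growth_rate = 12L,
                            input_channels = 24L)
  expect_identical(dim(dense_recurrent_block(x, cfg))[4], 108L)
  # empty block is the identity
  cfg0 <- dense_block_config(num_layers = 0L, growth_rate = 12L,
                             input_channels = 24L)
  expect_identical(dense_recurrent_block(x, cfg0), x)
  # internal layer l sees k * (l - 1) + k0 input channels
  bl <- nucleikit:::with_build_seed(1, nucleikit:::new_dense_block(
    nucleikit:::nk_reg_new(),
    dense_block_config(7L, 12L, input_channels = 24L),
    rcl_config(out_channels = 12L)))
  expect_identical(bl$layers[[3]]$cin, 12L * 2L + 24L)  # l = 3 -> 48
  cins <- vapply(bl$layers, function(l) l$cin, 0L)
  expect_identical(cins, 24L + 12L * (0:6))
})

test_that("feed-forward and recurrent dense blocks differ only in unrolling", {
  x <- rand_map(1, 4, 4, 6, seed = 8)
  cfg_ff <- dense_block_config(2L, 4L, input_channels = 6L, time_steps = 0L,
                               keep_recurrent_params = TRUE)
  cfg_rc <- dense_block_config(2L, 4L, input_channels = 6L, time_steps = 2L)
  y_ff <- dense_recurrent_block(x, cfg_ff, seed = 5)
  y_rc <- dense_recurrent_block(x, cfg_rc, seed = 5)
  expect_identical(dim(y_ff), dim(y_rc))
  expect_gt(max(abs(y_ff - y_rc)), 0)
})

test_that("transition block halves spatial size and sets channels", {
  x <- rand_map(1, 32, 32, 96, seed = 4)
  y <- transition_block(x, 96L, seed = 1)
  expect_identical(dim(y), c(1L, 16L, 16L, 96L))
  expect_error(transition_block(rand_map(1, 7, 8, 4), 4L), "even")
})

test_that("transition with identity 1x1 kernel averages each 2x2 cell", {
  tr <- nucleikit:::with_build_seed(1, nucleikit:::new_transition(
    nucleikit:::nk_reg_new(), 1L, 1L))
  tr$conv$p$w[] <- 1; tr$conv$p$b[] <- 0
  # constant positive plane passes through BN (identity stats) and ReLU
  xc <- array(5, c(1, 4, 4, 1))
  yc <- nucleikit:::transition_fwd(tr, xc)$y
  expect_equal(as.vector(yc), rep(5, 4), tolerance = 1e-4)
  # 8x8 plane of 0..63 row-major: each output is the mean of its 2x2 cell
  vals <- matrix(0:63, 8, 8, byrow = TRUE)
  x <- array(0, c(1, 8, 8, 1)); x[1, , , 1] <- vals
  y <- nucleikit:::transition_fwd(tr, x)$y
  want <- (vals[seq(1, 8, 2), seq(1, 8, 2)] + vals[seq(2, 8, 2), seq(1, 8, 2)] +
           vals[seq(1, 8, 2), seq(2, 8, 2)] + vals[seq(2, 8, 2), seq(2, 8, 2)]) / 4
  expect_equal(y[1, , , 1], want, tolerance = 1e-3)
})

test_that("classifier forward yields softmax rows summing to one", {
  sp <- model_spec("dcrn", input_shape = c(16, 16, 3), blocks = 2L,
                   layers_per_block = 2L, growth_rate = 4L, init_channels = 8L)
  m <- build_model(sp, seed = 1)
  p <- predict(m, rand_map(5, 16, 16, 3, seed = 6))
  expect_identical(dim(p), c(5L, 4L))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-9)
  expect_true(all(p >= 0))
})

test_that("parameter counting is exact and respects freezing", {
  reg <- nucleikit:::nk_reg_new()
  nucleikit:::ly_conv3(reg, 1L, 8L, bias = TRUE)
  expect_identical(nucleikit:::nk_n_params(reg$layers), 80L)  # 3*3*1*8 + 8
  m <- build_model(model_spec("densenet"), seed = 1)
  n0 <- count_parameters(m)
  expect_gt(n0, 0)
  freeze_parameters(m)
  expect_identical(count_parameters(m), 0L)
  freeze_parameters(m, FALSE)
  expect_identical(count_parameters(m), n0)
})

test_that("builds are deterministic given spec and seed", {
  sp <- model_spec("r2unet", channel_schedule = c(1, 8, 16, 8, 1))
  m1 <- build_model(sp, seed = 42)
  m2 <- build_model(sp, seed = 42)
  expect_identical(count_parameters(m1), count_parameters(m2))
  x <- rand_map(1, 16, 16, 1, seed = 3)
  expect_identical(predict(m1, x), predict(m2, x))
  m3 <- build_model(sp, seed = 43)
  expect_gt(max(abs(predict(m1, x) - predict(m3, x))), 0)
})

test_that("encoder-decoder variants preserve spatial dims for multiples of 16", {
  for (v in c("r2unet", "udnet")) {
    sp <- model_spec(v, channel_schedule = c(1, 4, 8, 16, 8, 4, 1))
    m <- build_model(sp, seed = 1)
    for (s in c(16L, 32L, 48L)) {
      y <- predict(m, rand_map(1, s, s, 1, seed = s))
      expect_identical(dim(y), c(1L, s, s, 1L))
    }
    expect_error(predict(m, rand_map(1, 10, 10, 1)), "multiples")
  }
})

test_that("parameter count increases strictly with growth rate and schedule width", {
  cnt_g <- vapply(c(8L, 12L, 16L), function(k)
    count_parameters(build_model(model_spec("dcrn", growth_rate = k), seed = 1)),
    0L)
  expect_true(all(diff(cnt_g) > 0))
  cnt_w <- vapply(list(c(1, 16, 32, 16, 1), c(1, 32, 64, 32, 1),
                       c(1, 48, 96, 48, 1)), function(sch)
    count_parameters(build_model(model_spec("r2unet", channel_schedule = sch),
                                 seed = 1)), 0L)
  expect_true(all(diff(cnt_w) > 0))
})

test_that("invalid model specs are rejected", {
  expect_error(model_spec("vgg"), "arg")
  expect_error(model_spec("r2unet", channel_schedule = c(1, 32, 64, 16, 1)),
               "symmetric")
  expect_error(model_spec("r2unet", channel_schedule = c(1, 32, 1, 2)), "odd")
})

test_that("the architecture manifest round-trips through YAML", {
  sp <- model_spec("udnet")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_spec(sp, path)
  sp2 <- read_model_spec(path)
  expect_identical(sp2$variant, "udnet")
  expect_identical(sp2$time_steps, 3L)
  expect_identical(sp2$channel_schedule, sp$channel_schedule)
  m1 <- build_model(sp, seed = 1); m2 <- build_model(sp2, seed = 1)
  expect_identical(count_parameters(m1), count_parameters(m2))
})
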