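# Dice, MSE, peak extraction, point matching, precision/recall/F1, AUC and
# fold splitting.

test_that("Dice coefficient follows the overlap formula and conventions", {
  a <- matrix(0L, 10, 10); a[2:5, 2:5] <- 1L
  expect_equal(dice_coefficient(a, a), 1)
  b <- matrix(0L, 10, 10); b[7:9, 7:9] <- 1L
  expect_equal(dice_coefficient(a, b), 0)
  # |GT| = 100, |SR| = 50, overlap 50 -> 2*50/150
  gt <- matrix(0L, 20, 20); gt[1:10, 1:10] <- 1L
  sr <- matrix(0L, 20, 20); sr[1:5, 1:10] <- 1L
  expect_equal(dice_coefficient(gt, sr), 2 * 50 / 150)
  expect_equal(round(dice_coefficient(gt, sr), 4), 0.6667)
  expect_equal(dice_coefficient(matrix(0L, 3, 3), matrix(0L, 3, 3)), 1)
  expect_error(dice_coefficient(a, matrix(0L, 5, 5)), "shape")
  expect_error(dice_coefficient(a * 2L, a), "binary")
})

test_that("Dice is symmetric and equals one only for identical non-empty masks", {
  set.seed(3)
  for (i in 1:10) {
    a <- matrix(rbinom(100, 1, 0.4), 10, 10)
    b <- matrix(rbinom(100, 1, 0.4), 10, 10)
    expect_equal(dice_coefficient(a, b), dice_coefficient(b, a))
    if (!identical(a, b) && sum(a) + sum(b) > 0)
      expect_lt(dice_coefficient(a, b), 1)
  }
})

test_that("mean squared error averages over all pixels", {
  y <- matrix(runif(12), 3, 4)
  expect_equal(mean_squared_error(y, y), 0)
  expect_equal(mean_squared_error(matrix(1, 2, 2), matrix(0, 2, 2)), 1)
  expect_equal(mean_squared_error(matrix(c(0, 1), 1, 2), matrix(1, 1, 2)), 0.5)
  expect_error(mean_squared_error(y, t(y)), "shape")
})

test_that("peak detection recovers isolated Gaussian bumps exactly", {
  s <- make_density_target(point_set(48, 48), c(96, 96), sigma = 2)
  p <- detect_peaks(s, 0.5)
  expect_identical(nrow(p), 1L)
  expect_identical(c(p$row, p$col), c(48L, 48L))
  s2 <- make_density_target(point_set(c(20, 60), c(20, 20)), c(96, 96), 2)
  expect_identical(nrow(detect_peaks(s2, 0.5)), 2L)
  expect_identical(nrow(detect_peaks(s * 0.4, 0.5)), 0L)
})

test_that("nearby components are merged by min_separation", {
  s <- matrix(0, 30, 30)
  s[10, 10] <- 1; s[10, 13] <- 1  # two one-pixel components 3 px apart
  expect_identical(nrow(detect_peaks(s, 0.5, min_separation = 5)), 1L)
  expect_identical(nrow(detect_peaks(s, 0.5, min_separation = 0)), 2L)
})

test_that("matching is exact on the stated examples", {
  pts <- point_set(c(5, 10, 40), c(5, 10, 40))
  m <- match_detections(pts, pts, radius = 6)
  expect_identical(unlist(m), c(TP = 3L, FP = 0L, FN = 0L))
  m2 <- match_detections(point_set(), pts, radius = 6)
  expect_identical(unlist(m2), c(TP = 0L, FP = 0L, FN = 3L))
  # one prediction within radius of two gt points: one-to-one forces FN = 1
  m3 <- match_detections(point_set(10, 10), point_set(c(10, 10), c(6, 14)),
                         radius = 6)
  expect_identical(unlist(m3), c(TP = 1L, FP = 0L, FN = 1L))
  expect_error(match_detections(pts, pts, radius = -1), "radius")
})

test_that("matching conserves counts and agrees with exhaustive enumeration", {
  set.seed(11)
  for (trial in 1:25) {
    n <- sample(0:6, 1); m <- sample(0:6, 1)
    pred <- point_set(sample(0:30, n), sample(0:30, n))
    gt <- point_set(sample(0:30, m), sample(0:30, m))
    got <- match_detections(pred, gt, radius = 8)
    expect_identical(got$TP + got$FP, n)
    expect_identical(got$TP + got$FN, m)
    expect_identical(got$TP, bf_match(pred, gt, 8)$TP)
  }
})

test_that("optimal matching beats greedy on a crafted chain", {
  # greedy takes the single closest pair and strands the second prediction
  pred <- point_set(c(0, 0), c(4, 10))
  gt <- point_set(c(0, 0), c(0, 5))
  opt <- match_detections(pred, gt, radius = 6, method = "optimal")
  grd <- match_detections(pred, gt, radius = 6, method = "greedy")
  expect_identical(opt$TP, 2L)
  expect_identical(grd$TP, 1L)
})

test_that("precision/recall/F1 follow the count formulas and conventions", {
  v <- precision_recall_f1(list(TP = 8L, FP = 2L, FN = 4L))
  expect_equal(unname(v), c(0.8, 8 / 12, 2 * 0.8 * (8 / 12) / (0.8 + 8 / 12)),
               tolerance = 1e-12)
  expect_equal(round(unname(v), 4), c(0.8, 0.6667, 0.7273))
  expect_equal(unname(precision_recall_f1(list(TP = 5L, FP = 0L, FN = 0L))),
               c(1, 1, 1))
  expect_equal(unname(precision_recall_f1(list(TP = 0L, FP = 3L, FN = 2L))),
               c(0, 0, 0))
  expect_equal(unname(precision_recall_f1(list(TP = 0L, FP = 0L, FN = 0L))),
               c(1, 1, 1))
})

test_that("macro AUC matches hand counts and the pROC cross-check", {
  # binary toy set with one inversion: 3 of 4 concordant pairs
  sc <- cbind(c(0.9, 0.4, 0.3, 0.6), 1 - c(0.9, 0.4, 0.3, 0.6))
  lab <- c(1, 1, 2, 2)
  expect_equal(roc_auc_macro(sc, lab), 0.75)
  # perfect separation and constant scores
  sc2 <- cbind(c(0.9, 0.8, 0.1), c(0.1, 0.2, 0.9))
  expect_equal(roc_auc_macro(sc2, c(1, 1, 2)), 1)
  sc3 <- matrix(0.25, 8, 4)
  expect_equal(roc_auc_macro(sc3, rep(1:4, 2)), 0.5)
  # against pROC on random 4-class scores
  set.seed(5)
  s <- matrix(runif(200), 50, 4); s <- s / rowSums(s)
  lab4 <- sample(1:4, 50, TRUE)
  ours <- roc_auc_macro(s, lab4)
  ref <- mean(vapply(1:4, function(k)
    as.numeric(pROC::auc(pROC::roc((lab4 == k) * 1, s[, k], quiet = TRUE,
                                   direction = "<"))), 0))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("AUC of reversed scores is one minus the AUC", {
  set.seed(9)
  s <- runif(30); lab <- rbinom(30, 1, 0.5) == 1
  a <- nucleikit:::auc_binary(s, lab)
  b <- nucleikit:::auc_binary(-s, lab)
  expect_equal(a, 1 - b, tolerance = 1e-12)
})

test_that("absent classes are skipped with a warning", {
  sc <- cbind(c(0.9, 0.2), c(0.1, 0.8), c(0, 0), c(0, 0))
  w <- testthat::capture_warnings(a <- roc_auc_macro(sc, c(1, 2)))
  expect_length(w, 2)
  expect_match(w, "absent", all = TRUE)
  expect_equal(a, 1)
})

test_that("bottleneck features are the channel means of the final block", {
  sp <- model_spec("dcrn", input_shape = c(16, 16, 3), blocks = 2L,
                   layers_per_block = 2L, growth_rate = 4L, init_channels = 8L)
  m <- build_model(sp, seed = 2)
  x <- rand_map(3, 16, 16, 3, seed = 4)
  f <- extract_bottleneck_features(m, x)
  expect_identical(dim(f), c(3L, m$net$feat_dim))
  expect_identical(nrow(f), 3L)
  # encoder-decoder models have no pre-head pooling block
  mu <- build_model(model_spec("r2unet", channel_schedule = c(1, 4, 8, 4, 1)),
                    seed = 1)
  expect_error(extract_bottleneck_features(mu, rand_map(1, 16, 16, 1)),
               "pre-head")
})

test_that("k-fold splits are balanced, disjoint and deterministic", {
  f <- kfold_split(10, 5, seed = 3)
  tests <- lapply(f, `[[`, "test")
  expect_identical(sort(unlist(tests)), 1:10)
  expect_true(all(vapply(tests, length, 0L) == 2L))
  expect_identical(kfold_split(10, 5, seed = 3), f)
  expect_false(identical(kfold_split(10, 5, seed = 4), f))
  sizes <- sort(vapply(kfold_split(16329, 5, seed = 1),
                       function(x) length(x$test), 0L))
  expect_identical(sizes, c(3265L, 3266L, 3266L, 3266L, 3266L))
  expect_error(kfold_split(10, 1), "at least 2")
  expect_error(kfold_split(3, 5), "at least k")
})
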