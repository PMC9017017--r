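# Metrics: Dice coefficient, mean squared error, peak extraction from
# density surfaces, one-to-one cell matching, precision/recall/F1,
# one-vs-rest macro ROC-AUC, bottleneck features, and k-fold splits.

check_binary <- function(m, what) {
  v <- as.vector(m)
  if (!all(v %in% c(0, 1)))
    stop(what, " must be binary (values in {0, 1})")
  invisible(m)
}

#' Dice coefficient between two binary masks
#'
#' `DC = 2 |GT intersect SR| / (|GT| + |SR|)`.  Two empty masks have
#' coefficient 1 by convention.
#'
#' @param gt,sr binary masks (matrices or arrays of identical shape).
#' @return a number in `[0, 1]`.
#' @export
dice_coefficient <- function(gt, sr) {
  if (!identical(dim(gt), dim(sr))) stop("mask shapes differ")
  check_binary(gt, "gt"); check_binary(sr, "sr")
  a <- sum(gt); b <- sum(sr)
  if (a + b == 0) return(1)
  2 * sum(gt * sr) / (a + b)
}

#' Mean squared error between two arrays
#'
#' `(1/n) * sum((Y - Yhat)^2)` with `n` the number of elements.
#'
#' @param y,yhat arrays of identical shape.
#' @export
mean_squared_error <- function(y, yhat) {
  if (!identical(dim(y), dim(yhat)) || length(y) != length(yhat))
    stop("shapes differ")
  mean((y - yhat)^2)
}

#' Extract nucleus detections from a density surface
#'
#' Binarizes the surface at `threshold`, labels connected components and
#' reports one point per component at its intensity-weighted centroid
#' (rounded to the nearest pixel).  Components whose centroids are closer
#' than `min_separation` are merged (single linkage, mass-weighted centroid).
#'
#' @param density numeric matrix (predicted or ground-truth density surface).
#' @param threshold detection threshold on the surface values.
#' @param min_separation merge distance in pixels.
#' @return a [point_set()] (0-based coordinates).
#' @export
detect_peaks <- function(density, threshold = 0.5, min_separation = 5) {
  stopifnot(is.matrix(density), all(is.finite(density)))
  bw <- density > threshold
  if (!any(bw)) return(point_set())
  lab <- EBImage::bwlabel(matrix(as.numeric(bw), nrow(density)))
  idx <- which(lab > 0)
  l <- lab[idx]
  wgt <- density[idx]
  rows0 <- (idx - 1L) %% nrow(density)
  cols0 <- (idx - 1L) %/% nrow(density)
  mass <- tapply(wgt, l, sum)
  cr <- tapply(wgt * rows0, l, sum) / mass
  cc <- tapply(wgt * cols0, l, sum) / mass
  pts <- cbind(r = as.numeric(cr), c = as.numeric(cc), m = as.numeric(mass))
  # merge components closer than min_separation
  if (min_separation > 0 && nrow(pts) > 1L) {
    repeat {
      dm <- as.matrix(stats::dist(pts[, 1:2, drop = FALSE]))
      diag(dm) <- Inf
      if (min(dm) >= min_separation || nrow(pts) == 1L) break
      ij <- which(dm == min(dm), arr.ind = TRUE)[1L, ]
      i <- min(ij); j <- max(ij)
      mi <- pts[i, 3L]; mj <- pts[j, 3L]
      pts[i, ] <- c((pts[i, 1L] * mi + pts[j, 1L] * mj) / (mi + mj),
                    (pts[i, 2L] * mi + pts[j, 2L] * mj) / (mi + mj),
                    mi + mj)
      pts <- pts[-j, , drop = FALSE]
    }
  }
  point_set(row = round(pts[, 1L]), col = round(pts[, 2L]))
}

# minimal-cost square assignment (Hungarian algorithm with potentials);
# returns the column assigned to each row
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L)          # p[j+1] = row matched to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[-1L])
      cur <- cost[i0, free] - u[i0 + 1L] - v[free + 1L]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd] + 1L] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      us <- which(used)
      u[p[us]  + 1L] <- u[p[us] + 1L] + delta
      v[us] <- v[us] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) assign[p[j + 1L]] <- j
  assign
}

#' Match detected points to ground-truth points
#'
#' One-to-one assignment maximizing the number of matches whose pairwise
#' Euclidean distance is at most `radius`; among maximal matchings the total
#' distance is minimized (optimal bipartite assignment).  Matched pairs are
#' true positives, unmatched predictions false positives, unmatched
#' ground-truth points false negatives.
#'
#' @param pred,gt [point_set()]s in the same image frame.
#' @param radius maximum match distance in pixels.
#' @param method `"optimal"` (default) or `"greedy"` (nearest-first, faster,
#'   order-independent only up to distance ties).
#' @return an object of class `detection_counts`: list with `TP`, `FP`, `FN`.
#' @export
match_detections <- function(pred, gt, radius = 6, method = c("optimal", "greedy")) {
  method <- match.arg(method)
  if (radius < 0) stop("radius must be non-negative")
  check_points(pred); check_points(gt)
  n <- nrow(pred); m <- nrow(gt)
  if (n == 0L || m == 0L)
    return(structure(list(TP = 0L, FP = n, FN = m), class = "detection_counts"))
  d <- sqrt(outer(pred$row, gt$row, "-")^2 + outer(pred$col, gt$col, "-")^2)
  if (method == "greedy") {
    feas <- which(d <= radius, arr.ind = TRUE)
    ord <- order(d[feas])
    up <- rep(TRUE, n); ug <- rep(TRUE, m); tp <- 0L
    for (k in ord) {
      i <- feas[k, 1L]; j <- feas[k, 2L]
      if (up[i] && ug[j]) { up[i] <- FALSE; ug[j] <- FALSE; tp <- tp + 1L }
    }
  } else {
    s <- n + m
    big <- 1e9
    un <- radius + 1          # cost of leaving a point unmatched
    cost <- matrix(0, s, s)
    cost[seq_len(n), seq_len(m)] <- ifelse(d <= radius, d, big)
    cost[seq_len(n), m + seq_len(n)] <- un
    cost[n + seq_len(m), seq_len(m)] <- un
    a <- solve_assignment(cost)
    tp <- sum(a[seq_len(n)] <= m & cost[cbind(seq_len(n), a[seq_len(n)])] < big)
  }
  structure(list(TP = as.integer(tp), FP = as.integer(n - tp),
                 FN = as.integer(m - tp)), class = "detection_counts")
}

#' Precision, recall and F1 from detection counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2 * precision * recall / (precision + recall)`.  If there are no
#' predictions and no ground truth at all the three are reported as 1;
#' otherwise any 0/0 ratio is 0.
#'
#' @param counts a `detection_counts` (or list with `TP`, `FP`, `FN`).
#' @return named numeric vector `(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(counts) {
  tp <- unname(counts$TP); fp <- unname(counts$FP); fn <- unname(counts$FN)
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative")
  if (tp + fp + fn == 0L)
    return(c(precision = 1, recall = 1, f1 = 1))
  pr <- if (tp + fp > 0) tp / (tp + fp) else 0
  rc <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
  c(precision = pr, recall = rc, f1 = f1)
}

# rank-based (Mann-Whitney) AUC; equals the trapezoid area under the ROC
# curve with tie handling via mid-ranks
auc_binary <- function(scores, positive) {
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

#' Macro-averaged one-vs-rest ROC-AUC
#'
#' One-vs-rest AUC per class by the rank construction, averaged over the
#' classes present in `labels`.  Classes absent from `labels` are skipped
#' with a warning.
#'
#' @param scores `n x K` matrix of class probabilities (rows sum to 1);
#'   column names, if present, identify the classes.
#' @param labels class membership for each row (values in `1..K` or the
#'   column names).
#' @return macro-averaged AUC.
#' @export
roc_auc_macro <- function(scores, labels) {
  scores <- as.matrix(scores)
  K <- ncol(scores)
  classes <- if (!is.null(colnames(scores))) colnames(scores) else seq_len(K)
  labels <- as.character(labels)
  aucs <- numeric(0)
  for (k in seq_len(K)) {
    pos <- labels == as.character(classes[k])
    if (!any(pos)) {
      warning("class ", classes[k], " absent from labels; skipped")
      next
    }
    a <- auc_binary(scores[, k], pos)
    if (!is.na(a)) aucs <- c(aucs, a)
  }
  if (length(aucs) == 0L) stop("no class with both positives and negatives")
  mean(aucs)
}

#' Bottleneck feature matrix of a classifier
#'
#' Activations of the final pre-head block, globally average-pooled to one
#' value per channel.
#'
#' @param model a classifier `nk_model`.
#' @param samples 4-D array of input samples.
#' @return `n x F` matrix, `F` the final block's channel count.
#' @export
extract_bottleneck_features <- function(model, samples) {
  predict(model, samples, type = "features")
}

#' Deterministic k-fold split
#'
#' Partitions `1..n` into `k` folds whose sizes differ by at most one.
#'
#' @param n number of samples.
#' @param k number of folds.
#' @param seed RNG seed; the same seed reproduces the same folds.
#' @return list of `k` folds, each `list(train =, test =)` of 1-based indices.
#' @export
kfold_split <- function(n, k = 5L, seed = 1L) {
  if (k <= 1L) stop("k must be at least 2")
  if (n < k) stop("need at least k samples")
  perm <- with_build_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(k), function(i) {
    test <- sort(perm[starts[i]:ends[i]])
    list(train = setdiff(seq_len(n), test), test = test)
  })
}
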