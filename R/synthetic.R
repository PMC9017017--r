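# Seeded generator of microscopy-like scenes: elliptical nuclei of four
# phenotype classes (differing in size, intensity, eccentricity and
# speckle texture) on a noisy bright background, with matched binary masks
# and center-point lists.  Scenes emulate H&E-style tiles: nuclei are
# darker, blue-purple tinted blobs on a pale background.

NK_CLASSES <- c("epithelial", "fibroblast", "inflammatory", "miscellaneous")

default_class_params <- function() {
  data.frame(
    label = NK_CLASSES,
    radius = c(9, 6, 4.5, 7),        # mean semi-major axis, px
    radius_sd = c(1.2, 0.9, 0.6, 1.5),
    intensity = c(110, 150, 60, 180),  # mean nuclear gray level, 0-255
    eccentricity = c(0.30, 0.75, 0.10, 0.50),
    speckle = c(12, 8, 5, 20),       # within-nucleus texture sd
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic scene generator
#'
#' Defaults emulate the study tiles: 500x500 pixels containing between 5 and
#' 500 nuclei of four classes.  The full scene is a deterministic function
#' of `(seed, scene index)`.
#'
#' @param image_size side length in pixels.
#' @param n_nuclei `c(min, max)` nuclei per scene (sampled uniformly).
#' @param classes per-class parameter table; see `nucleikit:::default_class_params`.
#' @param background `c(mean, sd)` gray level of the background.
#' @param overlap allowed overlap fraction between nuclei (0 = disjoint).
#' @param seed base RNG seed.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(image_size = 500L, n_nuclei = c(5L, 500L),
                         classes = default_class_params(),
                         background = c(mean = 215, sd = 10),
                         overlap = 0, seed = 1L) {
  stopifnot(image_size > 0, all(n_nuclei >= 0), n_nuclei[1] <= n_nuclei[2],
            overlap >= 0, overlap < 1, nrow(classes) >= 1)
  structure(list(image_size = as.integer(image_size),
                 n_nuclei = as.integer(n_nuclei), classes = classes,
                 background = background, overlap = overlap,
                 seed = as.integer(seed)),
            class = "synth_config")
}

scene_seed <- function(cfg, scene_index) {
  (cfg$seed + 10007L * as.integer(scene_index)) %% .Machine$integer.max
}

# draw one ellipse into gray/mask matrices; returns updated list
render_nucleus <- function(gray, mask, r0, c0, a, b, theta, intensity, speckle) {
  n <- nrow(gray)
  rad <- ceiling(max(a, b))
  rr <- max(0L, floor(r0 - rad)):min(n - 1L, ceiling(r0 + rad))
  cc <- max(0L, floor(c0 - rad)):min(ncol(gray) - 1L, ceiling(c0 + rad))
  dr <- outer(rr - r0, rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - c0)
  u <- (dr * cos(theta) + dc * sin(theta)) / a
  v <- (-dr * sin(theta) + dc * cos(theta)) / b
  inside <- u^2 + v^2 <= 1
  if (any(inside)) {
    blk <- gray[rr + 1L, cc + 1L, drop = FALSE]
    tex <- intensity + stats::rnorm(sum(inside), 0, speckle)
    blk[inside] <- tex
    gray[rr + 1L, cc + 1L] <- blk
    mblk <- mask[rr + 1L, cc + 1L, drop = FALSE]
    mblk[inside] <- 1L
    mask[rr + 1L, cc + 1L] <- mblk
  }
  list(gray = gray, mask = mask)
}

#' Generate one synthetic scene
#'
#' Renders elliptical nuclei with class-dependent size, intensity and
#' texture on a noisy background.  The binary mask is the union of the
#' ellipses and the point list holds the (rounded) ellipse centers with
#' class labels.
#'
#' @param cfg a [synth_config()].
#' @param scene_index index of the scene within a set; `(seed, scene_index)`
#'   fixes the scene bit-for-bit.
#' @return `list(image, mask, points)` of class `synthetic_scene`: RGB image
#'   `(size, size, 3)` in 0-255, binary mask, [point_set()] with labels.
#' @export
generate_scene <- function(cfg, scene_index = 1L) {
  stopifnot(inherits(cfg, "synth_config"))
  with_build_seed(scene_seed(cfg, scene_index), {
    sz <- cfg$image_size
    n <- if (cfg$n_nuclei[1] == cfg$n_nuclei[2]) cfg$n_nuclei[1]
         else sample(cfg$n_nuclei[1]:cfg$n_nuclei[2], 1L)
    gray <- matrix(cfg$background["mean"] +
                     stats::rnorm(sz * sz, 0, cfg$background["sd"]), sz, sz)
    mask <- matrix(0L, sz, sz)
    placed <- NULL  # rows: r, c, reff
    pts_r <- integer(0); pts_c <- integer(0); pts_l <- character(0)
    tries_left <- 500L * max(n, 1L)
    for (i in seq_len(n)) {
      ok <- FALSE
      while (!ok) {
        if (tries_left <= 0L)
          stop("infeasible packing: could not place ", n, " nuclei in ",
               sz, "x", sz, " pixels")
        tries_left <- tries_left - 1L
        ci <- sample.int(nrow(cfg$classes), 1L)
        cl <- cfg$classes[ci, ]
        a <- max(2, stats::rnorm(1, cl$radius, cl$radius_sd))
        b <- a * (1 - cl$eccentricity * 0.8)
        r0 <- stats::runif(1, a, sz - 1 - a)
        c0 <- stats::runif(1, a, sz - 1 - a)
        # conservative separation on the semi-major axes keeps disjoint
        # nuclei disjoint whatever their orientations
        sep_ok <- is.null(placed) ||
          all(sqrt((placed[, 1] - r0)^2 + (placed[, 2] - c0)^2) >
                (placed[, 3] + a) * (1 - cfg$overlap) + 2)
        dup <- any(pts_r == round(r0) & pts_c == round(c0))
        if (sep_ok && !dup) {
          theta <- stats::runif(1, 0, pi)
          out <- render_nucleus(gray, mask, r0, c0, a, b, theta,
                                cl$intensity, cl$speckle)
          gray <- out$gray; mask <- out$mask
          placed <- rbind(placed, c(r0, c0, a))
          pts_r <- c(pts_r, round(r0)); pts_c <- c(pts_c, round(c0))
          pts_l <- c(pts_l, cl$label)
          ok <- TRUE
        }
      }
    }
    gray <- pmin(pmax(gray, 0), 255)
    img <- array(0, c(sz, sz, 3))
    img[, , 1] <- gray * 1.00
    img[, , 2] <- gray * 0.88
    img[, , 3] <- pmin(gray * 1.06, 255)
    structure(list(image = img, mask = mask,
                   points = point_set(pts_r, pts_c, pts_l)),
              class = "synthetic_scene")
  })
}

#' Generate a balanced labelled patch set for classification
#'
#' One nucleus of the generating class centered in each `size x size` patch.
#'
#' @param cfg a [synth_config()].
#' @param n_per_class patches per class.
#' @param size patch side length.
#' @return `list(x, labels, meta)`: `x` is `(n, size, size, 3)` in 0-255,
#'   `labels` a factor, `meta` a data.frame with the sampled radius and
#'   intensity per patch.
#' @export
generate_classification_set <- function(cfg, n_per_class = 50L, size = 32L) {
  stopifnot(inherits(cfg, "synth_config"), nrow(cfg$classes) >= 1)
  nc <- nrow(cfg$classes)
  n <- nc * n_per_class
  x <- array(0, c(n, size, size, 3))
  labels <- character(n)
  meta <- data.frame(label = character(n), radius = numeric(n),
                     intensity = numeric(n), stringsAsFactors = FALSE)
  idx <- 0L
  for (ci in seq_len(nc)) for (j in seq_len(n_per_class)) {
    idx <- idx + 1L
    x_i <- with_build_seed(scene_seed(cfg, 100000L + idx), {
      cl <- cfg$classes[ci, ]
      gray <- matrix(cfg$background["mean"] +
                       stats::rnorm(size * size, 0, cfg$background["sd"]),
                     size, size)
      mask <- matrix(0L, size, size)
      a <- max(2, stats::rnorm(1, cl$radius, cl$radius_sd))
      b <- a * (1 - cl$eccentricity * 0.8)
      theta <- stats::runif(1, 0, pi)
      ctr <- (size - 1) / 2
      out <- render_nucleus(gray, mask, ctr, ctr, a, b, theta,
                            cl$intensity, cl$speckle)
      gray <- pmin(pmax(out$gray, 0), 255)
      list(gray = gray, radius = a, intensity = cl$intensity)
    })
    x[idx, , , 1] <- x_i$gray
    x[idx, , , 2] <- x_i$gray * 0.88
    x[idx, , , 3] <- pmin(x_i$gray * 1.06, 255)
    labels[idx] <- cfg$classes$label[ci]
    meta[idx, ] <- list(cfg$classes$label[ci], x_i$radius, x_i$intensity)
  }
  list(x = x, labels = factor(labels, levels = cfg$classes$label), meta = meta)
}

#' Generate a detection set: images with center-point lists
#'
#' @param cfg a [synth_config()].
#' @param n_images number of scenes.
#' @return `list(images, points)`: lists of RGB arrays and [point_set()]s.
#' @export
generate_detection_set <- function(cfg, n_images = 4L) {
  scenes <- lapply(seq_len(n_images), function(i) generate_scene(cfg, i))
  list(images = lapply(scenes, `[[`, "image"),
       points = lapply(scenes, `[[`, "points"))
}
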