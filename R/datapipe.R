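# Dataset mechanics: patch extraction and tiling, grayscale conversion,
# point-annotation dilation and Gaussian density-surface targets.
#
# Conventions: pixel coordinates are 0-based (row, col); patch windows are
# half-open [r - size/2, r + size/2).  Images are numeric arrays in 0-255,
# either (rows, cols) or (rows, cols, 3).

#' Construct a set of nucleus center points
#'
#' @param row,col 0-based integer pixel coordinates.
#' @param label optional class labels (character or factor).
#' @return a `data.frame` with columns `row`, `col` and optionally `label`.
#' @export
point_set <- function(row = integer(), col = integer(), label = NULL) {
  row <- as.integer(row); col <- as.integer(col)
  if (length(row) != length(col)) stop("row and col must have equal length")
  if (anyDuplicated(paste(row, col)))
    stop("duplicate (row, col) coordinates are not allowed")
  df <- data.frame(row = row, col = col)
  if (!is.null(label)) df$label <- as.character(label)
  df
}

check_points <- function(points, shape = NULL) {
  if (!is.data.frame(points) || !all(c("row", "col") %in% names(points)))
    stop("points must be a data.frame with columns row and col")
  if (!is.null(shape) && nrow(points) > 0 &&
      (any(points$row < 0) || any(points$col < 0) ||
       any(points$row >= shape[1L]) || any(points$col >= shape[2L])))
    stop("points must lie within the image bounds")
  invisible(points)
}

# mirror an out-of-range 0-based index back into [0, n-1] without repeating
# the edge pixel
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(0L, length(i)))
  p <- 2L * (n - 1L)
  i <- ((i %% p) + p) %% p
  ifelse(i >= n, p - i, i)
}

#' Convert an image to grayscale
#'
#' Uses the luminosity weights 0.299, 0.587, 0.114; single-channel input is
#' returned unchanged.  Intensity range is preserved.
#'
#' @param img `(rows, cols)` or `(rows, cols, channels)` array with
#'   channels 1 or 3.
#' @return a `(rows, cols)` matrix.
#' @export
to_grayscale <- function(img) {
  if (length(dim(img)) == 2L) return(img)
  if (length(dim(img)) != 3L) stop("image must be 2-D or 3-D")
  ch <- dim(img)[3L]
  if (ch == 1L) return(img[, , 1L])
  if (ch != 3L) stop("channel count must be 1 or 3, got ", ch)
  0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
}

#' Extract class-labelled patches centered on annotated points
#'
#' One `size x size` patch per annotated point, window rows
#' `[r - size/2, r + size/2)` and likewise for columns; regions falling
#' outside the image are mirror-reflected, so every patch has the full size
#' regardless of the point position.
#'
#' @param img image array, `(rows, cols)` or `(rows, cols, 3)`.
#' @param points a [point_set()] with a `label` column.
#' @param size even patch size in pixels.
#' @return list of `list(patch =, label =)`; empty list for an empty point set.
#' @export
extract_class_patches <- function(img, points, size = 32L) {
  if (size %% 2L != 0L) stop("patch size must be even")
  check_points(points, dim(img))
  if (nrow(points) == 0L) return(list())
  if (!"label" %in% names(points)) stop("points must carry class labels")
  h <- dim(img)[1L]; w <- dim(img)[2L]
  half <- size %/% 2L
  lapply(seq_len(nrow(points)), function(i) {
    r <- points$row[i]; cc <- points$col[i]
    ri <- reflect_index((r - half):(r + half - 1L), h) + 1L
    ci <- reflect_index((cc - half):(cc + half - 1L), w) + 1L
    patch <- if (length(dim(img)) == 3L) img[ri, ci, , drop = FALSE]
             else img[ri, ci, drop = FALSE]
    list(patch = patch, label = points$label[i])
  })
}

#' Tile an image into non-overlapping square patches
#'
#' The largest top-left-anchored region whose sides are multiples of
#' `patch_size` is tiled; the remainder is dropped (a 500x500 image tiled at
#' 96 yields the 480x480 crop).
#'
#' @param img image array.
#' @param patch_size side length of the square patches.
#' @return an object of class `patch_grid` with elements `patches` (list),
#'   `origins` (0-based `(row, col)` matrix), `patch_size`, `cropped_shape`.
#' @export
tile_patches <- function(img, patch_size = 96L) {
  d <- dim(img)
  if (d[1L] < patch_size || d[2L] < patch_size)
    stop("image is smaller than one patch")
  nr <- d[1L] %/% patch_size; nc <- d[2L] %/% patch_size
  origins <- as.matrix(expand.grid(row = (seq_len(nr) - 1L) * patch_size,
                                   col = (seq_len(nc) - 1L) * patch_size))
  patches <- lapply(seq_len(nrow(origins)), function(i) {
    r0 <- origins[i, 1L]; c0 <- origins[i, 2L]
    if (length(d) == 3L) img[(r0 + 1L):(r0 + patch_size),
                             (c0 + 1L):(c0 + patch_size), , drop = FALSE]
    else img[(r0 + 1L):(r0 + patch_size), (c0 + 1L):(c0 + patch_size),
             drop = FALSE]
  })
  structure(list(patches = patches, origins = origins,
                 patch_size = as.integer(patch_size),
                 cropped_shape = c(nr, nc) * patch_size),
            class = "patch_grid")
}

#' Merge a patch grid back into a full image
#'
#' Exact inverse of [tile_patches()] on the cropped region; the grid must
#' tile a complete rectangle.
#'
#' @param grid a `patch_grid`.
#' @return the reassembled image array.
#' @export
merge_patches <- function(grid) {
  stopifnot(inherits(grid, "patch_grid"))
  ps <- grid$patch_size
  or <- grid$origins
  if (any(or %% ps != 0L)) stop("origins must be multiples of patch_size")
  hs <- grid$cropped_shape
  want <- expand.grid(row = seq(0L, hs[1L] - ps, by = ps),
                      col = seq(0L, hs[2L] - ps, by = ps))
  key <- paste(or[, 1L], or[, 2L])
  if (!setequal(key, paste(want$row, want$col)) || anyDuplicated(key))
    stop("patch grid does not tile the full rectangle (missing tile?)")
  nd <- dim(grid$patches[[1L]])
  out <- if (length(nd) == 3L) array(0, c(hs, nd[3L])) else array(0, hs)
  for (i in seq_along(grid$patches)) {
    r0 <- or[i, 1L]; c0 <- or[i, 2L]
    if (length(nd) == 3L)
      out[(r0 + 1L):(r0 + ps), (c0 + 1L):(c0 + ps), ] <- grid$patches[[i]]
    else out[(r0 + 1L):(r0 + ps), (c0 + 1L):(c0 + ps)] <- grid$patches[[i]]
  }
  out
}

#' Dilate point annotations into a binary mask
#'
#' Sets the square `kernel_size x kernel_size` neighbourhood of every point
#' to 1, clipped at the image borders.
#'
#' @param points a [point_set()].
#' @param shape `c(rows, cols)` of the output mask.
#' @param kernel_size odd kernel side length.
#' @return integer matrix over \{0, 1\}.
#' @export
dilate_points <- function(points, shape, kernel_size = 5L) {
  if (kernel_size %% 2L == 0L) stop("kernel_size must be odd")
  check_points(points, shape)
  m <- matrix(0L, shape[1L], shape[2L])
  half <- kernel_size %/% 2L
  for (i in seq_len(nrow(points))) {
    r <- points$row[i]; cc <- points$col[i]
    rr <- max(0L, r - half):min(shape[1L] - 1L, r + half)
    ccs <- max(0L, cc - half):min(shape[2L] - 1L, cc + half)
    m[rr + 1L, ccs + 1L] <- 1L
  }
  m
}

#' Build a Gaussian density surface from point annotations
#'
#' Each point contributes an isotropic Gaussian bump with peak amplitude 1
#' centered at the point and truncated at 3 sigma.  Bumps are combined
#' pixelwise by maximum (default; values stay in [0, 1] so a 0.5 threshold
#' is meaningful for the regression head) or by summation.
#'
#' @param points a [point_set()].
#' @param shape `c(rows, cols)` of the surface.
#' @param sigma Gaussian width in pixels.
#' @param combine_mode `"max"` or `"sum"`.
#' @return numeric matrix with attributes `sigma` and `combine_mode`.
#' @export
make_density_target <- function(points, shape, sigma = 2.0,
                                combine_mode = c("max", "sum")) {
  combine_mode <- match.arg(combine_mode)
  if (sigma <= 0) stop("sigma must be positive")
  check_points(points, shape)
  s <- matrix(0, shape[1L], shape[2L])
  rad <- ceiling(3 * sigma)
  for (i in seq_len(nrow(points))) {
    r <- points$row[i]; cc <- points$col[i]
    rr <- max(0L, r - rad):min(shape[1L] - 1L, r + rad)
    ccs <- max(0L, cc - rad):min(shape[2L] - 1L, cc + rad)
    d2 <- outer((rr - r)^2, (ccs - cc)^2, "+")
    g <- exp(-d2 / (2 * sigma^2))
    g[d2 > (3 * sigma)^2] <- 0
    blk <- s[rr + 1L, ccs + 1L, drop = FALSE]
    s[rr + 1L, ccs + 1L] <- if (combine_mode == "max") pmax(blk, g) else blk + g
  }
  attr(s, "sigma") <- sigma
  attr(s, "combine_mode") <- combine_mode
  s
}
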