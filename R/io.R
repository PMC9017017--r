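# File formats: PNG/TIFF images, single-channel {0,255} PNG masks,
# 32-bit float TIFF density surfaces, and `row,col,label` CSV point lists.

#' Read / write images
#'
#' Images are held in memory as 0-255 numeric arrays `(rows, cols[, 3])`.
#' PNG and TIFF are supported (by file extension).
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param img image array in 0-255.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
              png = png::readPNG(path),
              tif = , tiff = tiff::readTIFF(path),
              stop("unsupported image format: ", ext))
  if (length(dim(x)) == 3L && dim(x)[3L] == 4L) x <- x[, , 1:3]  # drop alpha
  x * 255
}

#' @rdname read_image
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  x <- pmin(pmax(img / 255, 0), 1)
  switch(ext,
         png = png::writePNG(x, path),
         tif = , tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
         stop("unsupported image format: ", ext))
  invisible(path)
}

#' Read / write binary masks as single-channel PNG over \{0, 255\}
#'
#' @param mask binary matrix.
#' @param path file path.
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  (m > 0.5) * 1L
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  png::writePNG((mask > 0) * 1, path)
  invisible(path)
}

#' Read / write density surfaces as 32-bit float TIFF
#'
#' @param surface numeric matrix.
#' @param path file path.
#' @export
read_density <- function(path) {
  tiff::readTIFF(path, as.is = FALSE)
}

#' @rdname read_density
#' @export
write_density <- function(surface, path) {
  tiff::writeTIFF(surface, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read / write point annotations as CSV with header `row,col[,label]`
#'
#' @param points a [point_set()].
#' @param path file path.
#' @export
read_points <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  point_set(df$row, df$col, label = df$label)
}

#' @rdname read_points
#' @export
write_points <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
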