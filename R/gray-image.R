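#' Grayscale image container
#'
#' A `gray_image` is the common currency of the package: a numeric matrix of
#' pixel intensities on the nominal 0--255 scale.  Noise fields are carried
#' *unclipped* (values may fall outside 0--255); clipping to the displayable
#' range happens once, after SSNR blending.
#'
#' @param pixels numeric matrix of intensities (rows = image height).
#' @param meta optional named list of provenance metadata.
#' @return An object of class `gray_image` (a numeric matrix with attributes).
#' @export
gray_image <- function(pixels, meta = list()) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a non-empty numeric matrix", call. = FALSE)
  if (any(!is.finite(pixels)))
    stop("`pixels` must contain only finite values", call. = FALSE)
  structure(pixels, class = c("gray_image", class(pixels)), meta = meta)
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, range [%.2f, %.2f]>\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

as_gray_image <- function(x, meta = list()) {
  if (inherits(x, "gray_image")) x else gray_image(x, meta)
}

#' Clip intensities into the displayable 0--255 range
#'
#' @param img a `gray_image` or numeric matrix.
#' @return A `gray_image` with all values in \[0, 255\].
#' @export
clip_image <- function(img) {
  m <- unclass(img)
  m[m < 0] <- 0
  m[m > 255] <- 255
  gray_image(m, meta = attr(img, "meta") %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write 8-bit grayscale PNG
#'
#' Thin wrappers around [png::readPNG()] / [png::writePNG()] converting
#' between the package's 0--255 convention and PNG's 0--1.  Images are
#' clipped on write.
#'
#' @param path file path.
#' @param img a `gray_image`.
#' @return `read_gray_png()` returns a `gray_image`; `write_gray_png()`
#'   returns `path` invisibly.
#' @export
read_gray_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]  # first channel of gray-encoded RGB
  gray_image(a * 255)
}

#' @rdname read_gray_png
#' @export
write_gray_png <- function(img, path) {
  png::writePNG(unclass(clip_image(img)) / 255, target = path)
  invisible(path)
}
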