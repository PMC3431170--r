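#' Read a grayscale image
#'
#' Reads an 8-bit PNG (or TIFF, if the tiff package is installed) into a
#' numeric matrix of gray levels 0-255. Color images are converted by
#' channel averaging.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return Numeric matrix, gray levels 0-255.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the tiff package", call. = FALSE)
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(arr)) == 3L) arr <- apply(arr[, , 1:min(3, dim(arr)[3])], c(1, 2), mean)
  round(arr * 255)
}

#' Write a grayscale image or binary mask as PNG
#'
#' Masks are written as 0/255.
#'
#' @param x Numeric image matrix (0-255) or logical mask.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(x, path) {
  if (is.logical(x)) x <- x * 255
  png::writePNG(pmin(pmax(x, 0), 255) / 255, path)
  invisible(path)
}

#' Write a snake contour as CSV
#'
#' Two columns `x`, `y` (1-based pixel-center coordinates, column/row);
#' the polygon closes implicitly from the last row to the first.
#'
#' @param contour A `snake_contour`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contour_csv <- function(contour, path) {
  stopifnot(inherits(contour, "snake_contour"))
  utils::write.csv(as.data.frame(unclass(contour)), path, row.names = FALSE)
  invisible(path)
}
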