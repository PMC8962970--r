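#' Read / write grayscale images
#'
#' In memory, images are numeric matrices in gray levels (nominally
#' 0-255).  On disk, PNG files are 8-bit (the image is quantized with
#' [quantize8()] on write) and TIFF files are 32-bit float, both stored on
#' the usual normalized [0, 1] scale; reading rescales back to gray
#' levels.  The format is chosen from the file extension.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param image numeric matrix (gray levels).
#' @return `read_gray_image`: a numeric matrix in gray levels;
#'   `write_gray_image`: the path, invisibly.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(x)) == 3) x <- x[, , 1]   # first channel of gray-written RGB
  x * 255
}

#' @rdname read_gray_image
#' @export
write_gray_image <- function(image, path) {
  check_gray_image(image)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(quantize8(image) / 255, path),
    tif = ,
    tiff = tiff::writeTIFF(pmin(pmax(image / 255, 0), 1), path,
                           bits.per.sample = 32),
    stop("unsupported image format: .", ext, call. = FALSE))
  invisible(path)
}

#' Write an RGB array image as PNG
#'
#' @param rgb H x W x 3 array in gray levels (0-255), or a
#'   `psi_array_image`.
#' @param path PNG path.
#' @return the path, invisibly.
#' @export
write_rgb_image <- function(rgb, path) {
  if (inherits(rgb, "psi_array_image")) rgb <- rgb$rgb
  png::writePNG(pmin(pmax(rgb / 255, 0), 1), path)
  invisible(path)
}

#' Read an RGB PNG as a gray-level array
#'
#' @param path PNG path.
#' @return H x W x 3 array in gray levels (0-255).
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- png::readPNG(path)
  if (length(dim(x)) == 2) x <- array(rep(x, 3), c(dim(x), 3))
  x[, , 1:3, drop = FALSE] * 255
}
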