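# Reading and writing images and result tables.

#' Read a grayscale or RGB image
#'
#' PNG and TIFF are supported (by file extension). RGB images are returned
#' as h x w x 3 arrays for [select_channel()]; grayscale as matrices.
#' Intensities are rescaled to 0..255.
#'
#' @param path file path (.png, .tif, .tiff).
#' @return numeric matrix or h x w x 3 array, intensities 0..255.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 2L) img <- img[, , 1]                 # gray + alpha
    else if (dim(img)[3] == 4L) img <- img[, , 1:3]          # drop alpha
  }
  img * 255
}

#' Write a matrix as an 8-bit grayscale PNG
#'
#' @param image numeric matrix; intensities 0..255 (logical masks are
#'   written as 0/255).
#' @param path output path.
#' @export
write_gray_png <- function(image, path) {
  if (is.logical(image)) image <- image * 255
  png::writePNG(clamp(image / 255, 0, 1), path)
  invisible(path)
}

#' Write orientation-field planes as 32-bit float TIFFs
#'
#' Writes theta (NA as -1), coherency and energy next to each other using
#' the given path stem.
#'
#' @param field an \code{orientation_field}.
#' @param stem path prefix; files become \code{<stem>_theta.tif} etc.
#' @return the written paths, invisibly.
#' @export
write_orientation_tiff <- function(field, stem) {
  th <- field$theta; th[is.na(th)] <- -1
  paths <- paste0(stem, c("_theta.tif", "_coherency.tif", "_energy.tif"))
  tiff::writeTIFF(th / 180, paths[1], bits.per.sample = 32L)
  tiff::writeTIFF(clamp(field$coherency, 0, 1), paths[2], bits.per.sample = 32L)
  en <- field$energy; mx <- max(en)
  tiff::writeTIFF(if (mx > 0) en / mx else en, paths[3], bits.per.sample = 32L)
  invisible(paths)
}

#' Write an RGB array as PNG
#'
#' @param rgb h x w x 3 array in [0, 1] (as from [render_hsb()]).
#' @param path output path.
#' @export
write_rgb_png <- function(rgb, path) {
  png::writePNG(clamp(rgb, 0, 1), path)
  invisible(path)
}
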