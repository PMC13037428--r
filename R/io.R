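# Image and sinogram I/O: float TIFF for working images, 8-bit PNG for
# previews, RDS for sinograms/frame stacks, YAML for configurations.

#' Write an image as single-channel 32-bit float TIFF
#'
#' @param img numeric matrix; values outside `[0, 1]` are allowed and
#'   preserved (float sample format).
#' @param path output path.
#' @export
write_image_tiff <- function(img, path) {
  check_image(img)
  tiff::writeTIFF(img, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

#' Read a single-channel TIFF image
#' @param path file path.
#' @export
read_image_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m
}

#' Write an 8-bit PNG preview of an image (min-max stretched)
#' @param img numeric matrix.
#' @param path output path.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(normalize01(img), path)
  invisible(path)
}

#' Save / load a sinogram (samples + geometry)
#' @param sino a `sinogram` object.
#' @param path RDS path.
#' @export
save_sinogram <- function(sino, path) {
  if (!inherits(sino, "sinogram")) stopf("not a sinogram object")
  saveRDS(list(samples = sino$samples, geometry = unclass(sino$geometry)), path)
  invisible(path)
}

#' @rdname save_sinogram
#' @export
load_sinogram <- function(path) {
  x <- readRDS(path)
  structure(list(samples = x$samples,
                 geometry = structure(x$geometry, class = "array_geometry")),
            class = "sinogram")
}
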