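#' Read and write wafer images and masks
#'
#' Images travel as uncompressed TIFF (the archival format of flatbed
#' mixing-test scans) or PNG, masks as 0/255 PNG.  In memory an image is an
#' `h x w x 3` array of 8-bit values (0..255); files store the usual
#' `[0, 1]` scale.
#'
#' @param path file path; format chosen by extension (`.tif`/`.tiff` or
#'   `.png`).
#' @param image an `h x w x 3` array of values in 0..255.
#' @param mask a logical matrix.
#' @return `read_wafer_image()` returns the 8-bit array;
#'   `read_mask_png()` a logical matrix; the writers return `path`
#'   invisibly.
#' @export
read_wafer_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = ,
                tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3 && dim(img)[3] > 3) img <- img[, , 1:3]
  if (length(dim(img)) != 3 || dim(img)[3] != 3)
    stop("expected a 3-channel RGB image: ", path)
  round(img * 255)
}

#' @rdname read_wafer_image
#' @export
write_wafer_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  arr <- image / 255
  switch(ext,
         tif = ,
         tiff = tiff::writeTIFF(arr, path, compression = "none"),
         png = png::writePNG(arr, path),
         stop("unsupported image format: .", ext))
  invisible(path)
}

#' @rdname read_wafer_image
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname read_wafer_image
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m > 0.5
}
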