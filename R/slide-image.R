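# SlideImage / RegionMask containers and plain-image I/O.
#
# Pixels are stored as a base-R array with dim c(H, W, 3), values in
# [0, 1], 0-based pixel (row, col) indices mapping to physical
# coordinates as index * mpp (microns), origin at the top-left corner.

#' Construct a slide image
#'
#' A \code{slide_image} bundles an RGB pixel grid with its physical
#' scale (microns per pixel) and slide identity.
#'
#' @param pixels numeric array, dim \code{c(H, W, 3)}, values in \[0, 1\].
#' @param mpp microns per pixel (> 0).
#' @param slide_id identifier of the slide (individual id or similar).
#' @param kidney_side \code{"left"}, \code{"right"} or \code{NA}.
#' @param stain_level optional staining-intensity label, one of
#'   \code{"very_low"}, \code{"low"}, \code{"high"}, \code{"very_high"}.
#' @return an object of class \code{slide_image}.
#' @export
slide_image <- function(pixels, mpp, slide_id = NA_character_,
                        kidney_side = NA_character_, stain_level = NULL) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stopf("pixels must be an H x W x 3 array")
  if (dim(pixels)[1] < 64L || dim(pixels)[2] < 64L)
    stopf("slide images must be at least 64 x 64 pixels")
  if (!is.numeric(mpp) || length(mpp) != 1L || !is.finite(mpp) || mpp <= 0)
    stopf("mpp must be a single positive number")
  if (!is.na(kidney_side) && !kidney_side %in% c("left", "right"))
    stopf("kidney_side must be 'left', 'right' or NA")
  structure(
    list(pixels = pixels, mpp = mpp, slide_id = slide_id,
         kidney_side = kidney_side, stain_level = stain_level),
    class = "slide_image"
  )
}

#' @export
print.slide_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<slide_image> %d x %d px at %.3g um/px (%.2f x %.2f mm), id=%s side=%s\n",
              d[1], d[2], x$mpp, d[2] * x$mpp / 1e3, d[1] * x$mpp / 1e3,
              x$slide_id, x$kidney_side))
  invisible(x)
}

#' @export
dim.slide_image <- function(x) dim(x$pixels)

#' Construct a region mask
#'
#' Per-pixel tissue-region labels aligned with a slide image:
#' 0 background, 1 cortex, 2 medulla.
#'
#' @param labels integer matrix (H x W) with values in \{0, 1, 2\}.
#' @param mpp microns per pixel of the parent image.
#' @return an object of class \code{region_mask} with a
#'   \code{cortex_area_mm2} field.
#' @export
region_mask <- function(labels, mpp) {
  if (!is.matrix(labels)) stopf("labels must be a matrix")
  bad <- setdiff(unique(as.integer(labels)), c(0L, 1L, 2L))
  if (length(bad)) stopf("region labels must be 0, 1 or 2 (got %s)",
                         paste(bad, collapse = ", "))
  structure(
    list(labels = matrix(as.integer(labels), nrow(labels), ncol(labels)),
         mpp = mpp,
         cortex_area_mm2 = sum(labels == 1L) * mpp^2 / UM2_PER_MM2,
         medulla_area_mm2 = sum(labels == 2L) * mpp^2 / UM2_PER_MM2),
    class = "region_mask"
  )
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> %d x %d px, cortex %.3f mm2, medulla %.3f mm2\n",
              nrow(x$labels), ncol(x$labels), x$cortex_area_mm2,
              x$medulla_area_mm2))
  invisible(x)
}

#' Read a slide image from PNG or TIFF
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @param mpp microns per pixel of the stored image (images carry no
#'   scale metadata; it must be supplied).
#' @inheritParams slide_image
#' @return a \code{slide_image}.
#' @export
read_slide_image <- function(path, mpp, slide_id = basename(path),
                             kidney_side = NA_character_) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stopf("unsupported image format '%s' (use png or tiff)", ext)
  )
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]  # drop alpha
  slide_image(px, mpp = mpp, slide_id = slide_id, kidney_side = kidney_side)
}

#' Write a slide image to PNG or TIFF
#'
#' @param image a \code{slide_image}.
#' @param path destination ending in .png, .tif or .tiff.
#' @return \code{path}, invisibly.
#' @export
write_slide_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  px <- pmin(pmax(image$pixels, 0), 1)
  switch(ext,
    png  = png::writePNG(px, path),
    tif  = ,
    tiff = tiff::writeTIFF(px, path, bits.per.sample = 8L),
    stopf("unsupported image format '%s' (use png or tiff)", ext)
  )
  invisible(path)
}

#' Write / read a region mask as an indexed PNG
#'
#' The mask is stored as an 8-bit grayscale PNG with pixel values 0
#' (background), 1 (cortex) and 2 (medulla).
#'
#' @param mask a \code{region_mask}.
#' @param path destination .png path.
#' @return \code{path} invisibly (write); a \code{region_mask} (read).
#' @export
write_region_mask <- function(mask, path) {
  png::writePNG(mask$labels / 255, path)
  invisible(path)
}

#' @rdname write_region_mask
#' @param mpp microns per pixel, required when reading.
#' @export
read_region_mask <- function(path, mpp) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  region_mask(matrix(as.integer(round(m * 255)), nrow(m), ncol(m)), mpp = mpp)
}
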