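#' Construct a PlateImage
#'
#' @param pixels numeric array `[height, width, 3]` of per-channel counts in
#'   red, green, blue order, on the native sensor scale.
#' @param bit_depth integer, 8 (default) or 16.
#' @return A [PlateImage-class].
#' @examples
#' img <- PlateImage(array(0, c(20, 30, 3)))
#' imageWidth(img)
#' @export
PlateImage <- function(pixels, bit_depth = 8L) {
  if (length(dim(pixels)) == 2L) {
    clStop("cadmilume_input_error",
           "a plate image needs 3 channels; got a single-channel matrix")
  }
  new("PlateImage", pixels = pixels, bitDepth = as.integer(bit_depth))
}

#' @rdname PlateImage
#' @param x,object a `PlateImage`.
#' @export
setGeneric("imageWidth", function(x) standardGeneric("imageWidth"))
#' @rdname PlateImage
#' @export
setGeneric("imageHeight", function(x) standardGeneric("imageHeight"))
#' @rdname PlateImage
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))
#' @rdname PlateImage
#' @export
setGeneric("pixelArray", function(x) standardGeneric("pixelArray"))
#' @rdname PlateImage
#' @export
setGeneric("fullScale", function(x) standardGeneric("fullScale"))

#' @rdname PlateImage
#' @export
setMethod("imageWidth", "PlateImage", function(x) dim(x@pixels)[2])
#' @rdname PlateImage
#' @export
setMethod("imageHeight", "PlateImage", function(x) dim(x@pixels)[1])
#' @rdname PlateImage
#' @export
setMethod("bitDepth", "PlateImage", function(x) x@bitDepth)
#' @rdname PlateImage
#' @export
setMethod("pixelArray", "PlateImage", function(x) x@pixels)
#' @rdname PlateImage
#' @export
setMethod("fullScale", "PlateImage", function(x) 2^x@bitDepth - 1)

#' @rdname PlateImage
#' @export
setMethod("show", "PlateImage", function(object) {
  cat(sprintf("PlateImage: %d x %d px, 3 channels, %d-bit (max count %d)\n",
              imageWidth(object), imageHeight(object), object@bitDepth,
              as.integer(max(object@pixels))))
})

#' Read a plate photograph from PNG, JPEG or TIFF
#'
#' PNG and JPEG are decoded to 8-bit counts (16-bit PNG is detected from the
#' decoded grey resolution and kept at native depth); TIFF is read at its
#' native bit depth.
#'
#' @param path file path; format inferred from the extension.
#' @return A [PlateImage-class].
#' @export
readPlateImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  # decoders scale to [0,1]; 16-bit files show resolution finer than 1/255
  guess_depth <- function(v)
    if (any(abs(v * 255 - round(v * 255)) > 1e-6)) 16L else 8L
  if (ext == "png") {
    v <- png::readPNG(path)
    depth <- guess_depth(v)
  } else if (ext %in% c("jpg", "jpeg")) {
    v <- jpeg::readJPEG(path)
    depth <- 8L
  } else if (ext %in% c("tif", "tiff")) {
    v <- tiff::readTIFF(path)
    depth <- guess_depth(v)
  } else {
    clStop("cadmilume_input_error",
           sprintf("unsupported image format '.%s' (use PNG, JPEG or TIFF)", ext))
  }
  if (length(dim(v)) == 2L) v <- array(rep(v, 3L), c(dim(v), 3L))
  if (dim(v)[3] > 3L) v <- v[, , 1:3, drop = FALSE]  # drop alpha
  PlateImage(round(v * (2^depth - 1)), depth)
}

#' Write a plate image to PNG
#'
#' Output is 8-bit PNG; 16-bit images are rescaled to 8-bit on write.
#'
#' @param image a [PlateImage-class].
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
writePlateImage <- function(image, path) {
  png::writePNG(image@pixels / fullScale(image), path)
  invisible(path)
}
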