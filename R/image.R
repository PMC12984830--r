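#' Describe the geometry of an en-face scan
#'
#' An image spec ties the pixel grid to physical units: a square field of
#' `extent_mm` millimetres sampled on `width_px` x `height_px` pixels.  The
#' default corresponds to the common high-density macular protocol, a
#' 3 mm x 3 mm field on a 512 x 512 grid (5.859 um per pixel).
#'
#' @param width_px,height_px Grid size in pixels; must be equal and positive.
#' @param extent_mm Physical side length of the (square) field, in mm.
#' @param bit_depth Intensity bit depth, 8 or 16.
#'
#' @return An object of class `octa_spec` with fields `width_px`, `height_px`,
#'   `extent_mm`, `bit_depth`, and the derived `pixel_size_mm`.
#' @export
#' @examples
#' sp <- image_spec()
#' sp$pixel_size_mm * 1000  # micrometres per pixel, 5.859375 for 512 px / 3 mm
image_spec <- function(width_px = 512L, height_px = width_px,
                       extent_mm = 3, bit_depth = 8L) {
  width_px <- as.integer(width_px)
  height_px <- as.integer(height_px)
  if (width_px <= 0L || width_px != height_px) {
    abort("`width_px` and `height_px` must be equal and positive.")
  }
  if (!is.numeric(extent_mm) || extent_mm <= 0) abort("`extent_mm` must be > 0.")
  if (!bit_depth %in% c(8L, 16L)) abort("`bit_depth` must be 8 or 16.")
  structure(
    list(
      width_px = width_px, height_px = height_px,
      extent_mm = as.numeric(extent_mm), bit_depth = as.integer(bit_depth),
      pixel_size_mm = as.numeric(extent_mm) / width_px
    ),
    class = "octa_spec"
  )
}

#' @export
print.octa_spec <- function(x, ...) {
  cat(sprintf(
    "<octa_spec> %d x %d px over %.3g x %.3g mm (%.4g um/px, %d-bit)\n",
    x$width_px, x$height_px, x$extent_mm, x$extent_mm,
    x$pixel_size_mm * 1000, x$bit_depth
  ))
  invisible(x)
}

max_intensity <- function(spec) 2^spec$bit_depth - 1

#' Construct an en-face angiogram image
#'
#' Wraps a numeric intensity matrix together with its physical spec and
#' acquisition metadata (device, plexus, participant and eye identifiers).
#' Rows index the vertical (y) direction from the top of the field, columns
#' the horizontal (x) direction; pixel centres sit at `(i - 0.5) * pixel_size`.
#'
#' @param pixels Numeric matrix of nonnegative intensities, dimensions
#'   matching `spec`.
#' @param spec An [image_spec()].
#' @param plexus Capillary plexus label, `"SCP"` or `"DCP"`.
#' @param device Free-form device label.
#' @param participant,eye Identifiers used to pair scans across devices.
#' @return An object of class `octa_image`.
#' @export
en_face_image <- function(pixels, spec = image_spec(), plexus = "SCP",
                          device = "device", participant = NA_character_,
                          eye = NA_character_) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) abort("`pixels` must be a numeric matrix.")
  if (nrow(pixels) != spec$height_px || ncol(pixels) != spec$width_px) {
    abort(sprintf(
      "image is %d x %d but spec requires %d x %d",
      nrow(pixels), ncol(pixels), spec$height_px, spec$width_px
    ))
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > max_intensity(spec)) {
    abort("pixel values must lie within the bit-depth range and contain no NA.")
  }
  if (!plexus %in% c("SCP", "DCP")) abort('`plexus` must be "SCP" or "DCP".')
  structure(
    list(
      pixels = pixels, spec = spec, plexus = plexus, device = device,
      participant = as.character(participant), eye = as.character(eye)
    ),
    class = "octa_image"
  )
}

#' @export
print.octa_image <- function(x, ...) {
  cat(sprintf(
    "<octa_image> %s/%s %s %s: %d x %d px, intensities [%.3g, %.3g]\n",
    x$participant, x$eye, x$device, x$plexus,
    nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' Read an en-face image from PNG or TIFF
#'
#' Single-channel 8- or 16-bit images are accepted; multi-channel files are
#' coerced to their first channel with a warning.  Intensities are returned on
#' the native integer scale of the spec's bit depth.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @inheritParams en_face_image
#' @return An `octa_image`.
#' @export
read_enface <- function(path, spec = image_spec(), plexus = "SCP",
                        device = "device", participant = NA_character_,
                        eye = NA_character_) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        abort("reading TIFF requires the 'tiff' package.")
      }
      tiff::readTIFF(path)
    },
    abort(sprintf("unsupported image format: .%s (use PNG or TIFF)", ext))
  )
  if (length(dim(arr)) == 3L) {
    warn(sprintf("multi-channel image %s: using first channel only", basename(path)))
    arr <- arr[, , 1L]
  }
  if (nrow(arr) != spec$height_px || ncol(arr) != spec$width_px) {
    abort(sprintf(
      "%s is %d x %d but spec requires %d x %d",
      basename(path), nrow(arr), ncol(arr), spec$height_px, spec$width_px
    ))
  }
  # readPNG/readTIFF scale to [0,1]; restore the integer intensity scale
  px <- round(arr * max_intensity(spec))
  en_face_image(px, spec, plexus, device, participant, eye)
}

#' Write an image or binary mask as 8-bit grayscale PNG
#'
#' Masks are written as 0/255; images are rescaled from their bit-depth range.
#'
#' @param x An `octa_image`, or a numeric/logical matrix.
#' @param path Output path ending in `.png`.
#' @param spec Spec used for intensity scaling when `x` is a bare matrix of
#'   intensities (ignored for logical masks).
#' @return `path`, invisibly.
#' @export
write_enface_png <- function(x, path, spec = image_spec()) {
  if (inherits(x, "octa_image")) {
    m <- x$pixels / max_intensity(x$spec)
  } else if (is.logical(x) || all(x %in% c(0, 1))) {
    m <- matrix(as.numeric(x), nrow(x), ncol(x))
  } else {
    m <- x / max_intensity(spec)
  }
  png::writePNG(pmin(pmax(m, 0), 1), path)
  invisible(path)
}
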