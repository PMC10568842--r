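#' Construct an enface OCTA image
#'
#' The elementary data object of the package: one 2-D grayscale enface
#' angiography scan with intensities in `[0, 1]` plus acquisition metadata.
#' Pixels are stored as a numeric matrix indexed `[row, col]` with the origin
#' at the top-left.
#'
#' @param pixels Numeric matrix, finite; values are clipped to `[0, 1]`.
#'   Both dimensions must be at least 64 (one network patch).
#' @param eye_id Character scalar identifying the eye.
#' @param frame_index Integer >= 0; position within a repeated acquisition.
#' @param role One of `"single"`, `"averaged"`, `"pseudoaveraged"`, `"truth"`.
#' @param pixel_size_um Transverse pixel pitch in micrometres.
#' @param motion_rows Integer vector of 1-based row indices corrupted by
#'   motion-line artifact (simulator annotation; may be empty).
#' @param shadow_bbox `NULL` or integer vector `c(r0, r1, c0, c1)` delimiting
#'   a low-signal shadow patch.
#' @param true_transform `NULL` or a [transform2d()] that was applied when the
#'   frame was rendered (simulator annotation used by registration tests).
#'
#' @return An object of class `enface_image`.
#' @export
enface_image <- function(pixels, eye_id = "eye", frame_index = 0L,
                         role = c("single", "averaged", "pseudoaveraged", "truth"),
                         pixel_size_um = 6000 / nrow(pixels),
                         motion_rows = integer(0), shadow_bbox = NULL,
                         true_transform = NULL) {
  role <- match.arg(role)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(pixels)))
    stop("'pixels' must be finite", call. = FALSE)
  if (nrow(pixels) < 64L || ncol(pixels) < 64L)
    stop("enface images must be at least 64 x 64 pixels", call. = FALSE)
  if (!is.null(shadow_bbox)) {
    shadow_bbox <- as.integer(shadow_bbox)
    stopifnot(length(shadow_bbox) == 4L)
  }
  structure(list(
    pixels = clip01(pixels),
    eye_id = as.character(eye_id),
    frame_index = as.integer(frame_index),
    role = role,
    pixel_size_um = as.numeric(pixel_size_um),
    motion_rows = sort(unique(as.integer(motion_rows))),
    shadow_bbox = shadow_bbox,
    true_transform = true_transform
  ), class = "enface_image")
}

#' @export
print.enface_image <- function(x, ...) {
  cat(sprintf("<enface_image> %s frame %d [%s], %d x %d px (%.1f um/px)\n",
              x$eye_id, x$frame_index, x$role,
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um))
  cat(sprintf("  intensity range [%.3f, %.3f]; %d motion row(s)%s\n",
              min(x$pixels), max(x$pixels), length(x$motion_rows),
              if (is.null(x$shadow_bbox)) "" else "; shadow patch"))
  invisible(x)
}

#' @export
dim.enface_image <- function(x) dim(x$pixels)

as_pixels <- function(x) {
  if (inherits(x, "enface_image")) x$pixels
  else if (is.matrix(x)) x
  else stop("expected an enface_image or a numeric matrix", call. = FALSE)
}

#' Read/write enface images as 16-bit grayscale TIFF
#'
#' Images are serialized as single-channel 16-bit TIFF so that training
#' targets do not pick up 8-bit quantization steps. Binary masks use 8-bit
#' PNG (see [write_mask_png()]).
#'
#' @param image An [enface_image()] (or plain matrix for `write_enface_tiff`).
#' @param path File path.
#' @return `read_enface_tiff` returns a numeric matrix in `[0, 1]`.
#' @export
write_enface_tiff <- function(image, path) {
  px <- as_pixels(image)
  tiff::writeTIFF(px, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_enface_tiff
#' @export
read_enface_tiff <- function(path) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  px
}

#' @rdname write_enface_tiff
#' @param mask Logical matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' @rdname write_enface_tiff
#' @export
read_mask_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  px > 0.5
}
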