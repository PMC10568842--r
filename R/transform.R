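#' Rigid 2-D transforms
#'
#' A rigid (rotation + translation) transform of the enface plane. The
#' rotation is about the image centre; `dx` shifts columns (x, to the right)
#' and `dy` shifts rows (y, downward), both in pixels. The forward action on
#' an image point `p` (in (x, y) = (col, row) coordinates) is
#' `p' = R(theta) (p - c) + c + (dx, dy)` with `c` the image centre, i.e. a
#' frame rendered "under" transform `t` shows the reference scene moved by
#' `t`.
#'
#' @param dx,dy Translation in pixels (columns / rows).
#' @param theta Rotation in radians, counter-clockwise in (x, y).
#' @return An object of class `transform2d`.
#' @export
transform2d <- function(dx = 0, dy = 0, theta = 0) {
  stopifnot_scalar(dx, "dx"); stopifnot_scalar(dy, "dy")
  stopifnot_scalar(theta, "theta")
  structure(list(dx = as.numeric(dx), dy = as.numeric(dy),
                 theta = as.numeric(theta)),
            class = "transform2d")
}

#' @export
print.transform2d <- function(x, ...) {
  cat(sprintf("<transform2d> dx=%.3f px, dy=%.3f px, theta=%.4f deg\n",
              x$dx, x$dy, x$theta * 180 / pi))
  invisible(x)
}

#' @rdname transform2d
#' @param t1,t2 Transforms; `compose_transform(t1, t2)` is "apply `t1`,
#'   then `t2`" (about the same image centre).
#' @export
compose_transform <- function(t1, t2) {
  ct <- cos(t2$theta); st <- sin(t2$theta)
  transform2d(dx = ct * t1$dx - st * t1$dy + t2$dx,
              dy = st * t1$dx + ct * t1$dy + t2$dy,
              theta = t1$theta + t2$theta)
}

#' @rdname transform2d
#' @param t A `transform2d`.
#' @export
invert_transform <- function(t) {
  ct <- cos(-t$theta); st <- sin(-t$theta)
  transform2d(dx = -(ct * t$dx - st * t$dy),
              dy = -(st * t$dx + ct * t$dy),
              theta = -t$theta)
}

# Warp a plain pixel matrix by a rigid transform (bilinear interpolation,
# compiled kernel). Returns list(pixels, valid): `valid` is FALSE wherever
# the source location falls outside the original frame; those pixels are
# filled with `fill`.
warp_pixels <- function(px, t, fill = 0) {
  r <- cpp_warp_bilinear(px, t$dx, t$dy, t$theta, fill)
  r$valid <- r$valid > 0L
  r
}

#' Apply a rigid transform to an enface image
#'
#' Bilinear resampling; returns the warped image with a logical validity
#' mask (attribute `"valid"`) that is `FALSE` where the source location fell
#' outside the original frame. Motion-row annotations are carried along by
#' shifting them with the transform's row translation.
#'
#' @param image An [enface_image()] or numeric matrix.
#' @param transform A [transform2d()].
#' @param fill Fill value for invalid pixels.
#' @return An `enface_image` with attribute `"valid"` (logical matrix).
#' @export
apply_transform <- function(image, transform, fill = 0) {
  px <- as_pixels(image)
  wr <- warp_pixels(px, transform, fill = fill)
  if (inherits(image, "enface_image")) {
    rows <- round(image$motion_rows + transform$dy)
    rows <- rows[rows >= 1 & rows <= nrow(px)]
    out <- enface_image(wr$pixels, eye_id = image$eye_id,
                        frame_index = image$frame_index, role = image$role,
                        pixel_size_um = image$pixel_size_um,
                        motion_rows = rows, shadow_bbox = image$shadow_bbox,
                        true_transform = image$true_transform)
  } else {
    out <- enface_image(wr$pixels)
  }
  attr(out, "valid") <- wr$valid
  out
}
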