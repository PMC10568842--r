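#' Pseudoaverage a whole enface scan
#'
#' Tiled inference: the scan is covered by network-sized tiles on a stride
#' lattice (edge tiles snapped inside the frame, so no synthetic padding
#' enters the prediction), each tile is denoised by the U-Net, and
#' overlapping predictions are blended with a normalized cosine-squared
#' (Hann-squared) window, which removes tile-seam discontinuities. Where a
#' pixel is covered by a single tile the normalization makes the blend equal
#' that tile's prediction exactly.
#'
#' @param image An [enface_image()] or matrix, at least `tile` pixels a side.
#' @param model A fitted [fit_pseudoaverager()] model (or any `octa_unet`).
#' @param tile Tile side in pixels; must be divisible by
#'   `2^(levels-1)` of the model spec.
#' @param stride Lattice stride; `tile / 2` gives seam-free blending.
#' @param match_contrast If `TRUE`, the output is passed through
#'   [match_brightness_contrast()] against the input scan.
#' @return An [enface_image()] with role `"pseudoaveraged"`; simulator
#'   annotations (motion rows, shadow box) are carried over from the input
#'   so that artifact metrics can be evaluated on the output.
#' @export
pseudoaverage <- function(image, model, tile = 64L, stride = tile %/% 2L,
                          match_contrast = FALSE) {
  stopifnot(inherits(model, "octa_unet"))
  px <- as_pixels(image)
  check_divisible(tile, tile, model$spec)
  grid <- patch_grid(dim(px), patch_size = tile, stride = stride)
  n <- nrow(grid$positions)
  tiles <- array(0, c(tile, tile, n))
  for (i in seq_len(n)) {
    r <- grid$positions[i, 1]; c <- grid$positions[i, 2]
    tiles[, , i] <- px[r:(r + tile - 1L), c:(c + tile - 1L)]
  }
  preds <- cpp_unet_forward(model$layers, model$spec$channels, tiles,
                            identical(model$spec$residual_head, "logit") == FALSE)

  ## cosine-squared blending window (half-pixel offsets keep it positive)
  wv <- sin(pi * ((seq_len(tile) - 0.5) / tile))^2
  win <- outer(wv, wv)
  acc <- matrix(0, nrow(px), ncol(px)); wsum <- matrix(0, nrow(px), ncol(px))
  for (i in seq_len(n)) {
    r <- grid$positions[i, 1]; c <- grid$positions[i, 2]
    rows <- r:(r + tile - 1L); cols <- c:(c + tile - 1L)
    acc[rows, cols] <- acc[rows, cols] + preds[, , i] * win
    wsum[rows, cols] <- wsum[rows, cols] + win
  }
  out_px <- clip01(acc / wsum)

  if (inherits(image, "enface_image")) {
    out <- enface_image(out_px, eye_id = image$eye_id,
                        frame_index = image$frame_index,
                        role = "pseudoaveraged",
                        pixel_size_um = image$pixel_size_um,
                        motion_rows = image$motion_rows,
                        shadow_bbox = image$shadow_bbox)
  } else out <- enface_image(out_px, role = "pseudoaveraged")
  if (match_contrast) out <- match_brightness_contrast(out, image)
  out
}

#' @rdname pseudoaverage
#' @param object,newdata Standard `predict` interface: `newdata` is the scan.
#' @param ... Passed on to `pseudoaverage()`.
#' @export
predict.pseudoaverager <- function(object, newdata, ...) {
  pseudoaverage(newdata, object, ...)
}

#' Match output brightness/contrast to a reference scan
#'
#' Applies the affine intensity map `a*x + b` with `a` and `b` chosen so the
#' output's mean and standard deviation equal the reference's, then clips to
#' `[0, 1]`. A zero-variance output is mean-shifted only. Matching the
#' first two moments is the two-parameter "brightness/contrast" notion of
#' display adjustment; it is idempotent up to clipping effects.
#'
#' @param output,reference Same-shape [enface_image()]s or matrices.
#' @return Same class as `output`, intensity-matched and clipped.
#' @export
match_brightness_contrast <- function(output, reference) {
  op <- as_pixels(output); rp <- as_pixels(reference)
  if (!all(dim(op) == dim(rp)))
    stop("output and reference must have the same shape", call. = FALSE)
  s_o <- stats::sd(op); s_r <- stats::sd(rp)
  if (s_o < 1e-12) {
    mapped <- op - mean(op) + mean(rp)
  } else {
    a <- s_r / s_o
    mapped <- a * (op - mean(op)) + mean(rp)
  }
  mapped <- clip01(mapped)
  if (inherits(output, "enface_image")) {
    out <- output
    out$pixels <- mapped
    out
  } else mapped
}
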