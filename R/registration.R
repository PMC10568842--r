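#' Frame quality score
#'
#' Scalar image-quality proxy used to pick the reference frame for averaging
#' and to order peer-to-peer training pairs: mean gradient magnitude divided
#' by an estimate of the background-region standard deviation (the standard
#' deviation of the pixels at or below the image median). Higher is better;
#' a constant image scores 0. The score is invariant to adding a constant
#' offset to all pixels.
#'
#' This is an objective stand-in for the subjective "best quality" frame
#' selection a human grader would perform.
#'
#' @param image An [enface_image()] or numeric matrix.
#' @return Non-negative scalar.
#' @export
quality_score <- function(image) {
  px <- as_pixels(image)
  h <- nrow(px); w <- ncol(px)
  gx <- (px[, c(2:w, w)] - px[, c(1, 1:(w - 1))]) / 2
  gy <- (px[c(2:h, h), ] - px[c(1, 1:(h - 1)), ]) / 2
  grad <- mean(sqrt(gx^2 + gy^2))
  bg <- px[px <= stats::median(px)]
  s <- stats::sd(bg)
  if (!is.finite(s) || s < 1e-12 || grad < 1e-15) return(0)
  grad / s
}

# 2-D Hann window
hann2 <- function(h, w) {
  wr <- 0.5 * (1 - cos(2 * pi * (0:(h - 1)) / (h - 1)))
  wc <- 0.5 * (1 - cos(2 * pi * (0:(w - 1)) / (w - 1)))
  outer(wr, wc)
}

# Normalized cross-power spectrum of two equally sized (windowed) images.
cross_power <- function(a, b) {
  fa <- stats::fft(a); fb <- stats::fft(b)
  r <- fa * Conj(fb)
  r / (Mod(r) + 1e-12)
}

# Integer-precision phase-correlation peak. Returns the translation d such
# that `b` is approximately `a` shifted by d (dx = cols, dy = rows), plus the
# peak height of the normalized correlation surface.
phase_corr_peak <- function(a, b) {
  h <- nrow(a); w <- ncol(a)
  r <- Re(stats::fft(cross_power(a, b), inverse = TRUE)) / (h * w)
  i <- which.max(r)
  pr <- (i - 1) %% h; pc <- (i - 1) %/% h
  dy <- if (pr > h / 2) pr - h else pr
  dx <- if (pc > w / 2) pc - w else pc
  list(dx = -dx, dy = -dy, peak = r[i])
}

# Matrix-multiply DFT upsampling of the correlation surface in a small
# neighbourhood of (dy0, dx0); refines the translation to 1/usf pixel.
phase_corr_subpixel <- function(a, b, dx0, dy0, usf = 50, halfwidth = 1) {
  h <- nrow(a); w <- ncol(a)
  cp <- cross_power(a, b)
  fr <- c(0:(floor(h / 2)), -(ceiling(h / 2) - 1):-1) / h
  fc <- c(0:(floor(w / 2)), -(ceiling(w / 2) - 1):-1) / w
  ys <- -dy0 + seq(-halfwidth, halfwidth, by = 1 / usf)
  xs <- -dx0 + seq(-halfwidth, halfwidth, by = 1 / usf)
  wy <- exp(2i * pi * outer(ys, fr))        # |ys| x h
  wx <- exp(2i * pi * outer(fc, xs))        # w x |xs|
  r <- Re(wy %*% cp %*% wx) / (h * w)
  i <- which.max(r)
  iy <- (i - 1) %% length(ys) + 1; ix <- (i - 1) %/% length(ys) + 1
  list(dx = -xs[ix], dy = -ys[iy], peak = r[i])
}

#' Estimate the rigid transform between two enface frames
#'
#' Phase correlation (Hann-windowed, phase-only cross power) recovers the
#' translation; rotation is recovered by maximizing the phase-correlation
#' peak height over candidate rotations (coarse grid plus parabolic
#' refinement), and the final translation is refined to sub-pixel precision
#' with a matrix-multiply upsampled DFT.
#'
#' The returned transform follows the convention of [transform2d()]: if
#' `moving` shows the `reference` scene moved by `t`, the estimate is `t`;
#' apply [invert_transform()] before [apply_transform()] to align `moving`
#' onto `reference`.
#'
#' @param reference,moving Same-shape [enface_image()]s or matrices.
#' @param max_rot_deg Half-width of the rotation search range, degrees.
#' @param min_peak Phase-correlation peak below which the estimate is
#'   flagged as failed (attribute `"failed"` set to `TRUE`); callers are
#'   expected to fall back to the identity transform.
#' @return A [transform2d()] with attributes `"peak"` and `"failed"`.
#' @export
estimate_transform <- function(reference, moving, max_rot_deg = 3,
                               min_peak = 0.03) {
  a <- as_pixels(reference); b <- as_pixels(moving)
  if (!all(dim(a) == dim(b)))
    stop("reference and moving frames must have the same shape", call. = FALSE)
  win <- hann2(nrow(a), ncol(a))
  aw <- (a - mean(a)) * win
  if (stats::sd(aw) < 1e-12 || stats::sd(b) < 1e-12) {
    t0 <- transform2d(0, 0, 0)
    attr(t0, "failed") <- TRUE; attr(t0, "peak") <- 0
    return(t0)
  }

  score <- function(theta_deg) {
    bu <- warp_pixels(b, transform2d(0, 0, -theta_deg * pi / 180))$pixels
    phase_corr_peak(aw, (bu - mean(bu)) * win)
  }
  ## stage 1: coarse rotation grid on the phase-correlation peak height
  grid <- seq(-max_rot_deg, max_rot_deg, by = 0.5)
  peaks <- vapply(grid, function(th) score(th)$peak, numeric(1))
  ib <- which.max(peaks)
  th0 <- grid[ib]
  if (peaks[ib] < min_peak) {
    t0 <- transform2d(0, 0, 0)
    attr(t0, "failed") <- TRUE; attr(t0, "peak") <- peaks[ib]
    return(t0)
  }

  ## stage 2: sub-pixel translation at the coarse rotation
  theta0 <- th0 * pi / 180
  bu <- warp_pixels(b, transform2d(0, 0, -theta0))$pixels
  buw <- (bu - mean(bu)) * win
  ip <- phase_corr_peak(aw, buw)
  sp <- phase_corr_subpixel(aw, buw, ip$dx, ip$dy)
  ct <- cos(theta0); st <- sin(theta0)
  par0 <- c(ct * sp$dx - st * sp$dy, st * sp$dx + ct * sp$dy, th0)

  ## stage 3: direct refinement of the normalized cross-correlation between
  ## the reference and the aligned moving frame (Nelder-Mead)
  neg_ncc <- function(par) {
    tt <- transform2d(par[1], par[2], par[3] * pi / 180)
    al <- warp_pixels(b, invert_transform(tt))
    v <- al$valid
    if (sum(v) < 0.25 * length(v)) return(1)
    r <- stats::cor(a[v], al$pixels[v])
    if (!is.finite(r)) 1 else -r
  }
  opt <- stats::optim(par0, neg_ncc, method = "Nelder-Mead",
                      control = list(reltol = 1e-8, maxit = 250))
  est <- transform2d(opt$par[1], opt$par[2], opt$par[3] * pi / 180)
  attr(est, "peak") <- sp$peak
  attr(est, "ncc") <- -opt$value
  attr(est, "failed") <- sp$peak < min_peak
  est
}

#' Register and average a frame stack
#'
#' The reference frame is the one with the highest [quality_score()] (ties
#' broken toward the lowest frame index). Every other frame is registered to
#' it with [estimate_transform()], aligned by the inverse transform, and the
#' stack is reduced to a per-pixel mean over the frames whose validity mask
#' is true at that pixel (the reference is valid everywhere, so the divisor
#' is always >= 1). Frames whose registration fails fall back to the
#' identity transform; if every non-reference registration fails the
#' reference frame itself is returned with attribute
#' `"registration_failed" = TRUE` and a warning.
#'
#' @param stack A [render_frame_stack()] result (or list of frames).
#' @return An [enface_image()] with role `"averaged"`; attribute
#'   `"transform_log"` holds the per-frame estimated transforms and peak
#'   values, `reference_index` the chosen reference (1-based).
#' @export
average_frames <- function(stack) {
  frames <- if (inherits(stack, "frame_stack")) stack$frames else stack
  if (length(frames) < 2L)
    stop("averaging needs at least 2 frames", call. = FALSE)
  shapes <- vapply(frames, function(f) dim(as_pixels(f)), integer(2))
  if (any(shapes != shapes[, 1]))
    stop("all frames in a stack must have the same shape", call. = FALSE)

  q <- vapply(frames, quality_score, numeric(1))
  ref_i <- which.max(q)          # which.max takes the first (lowest index) tie
  ref <- frames[[ref_i]]
  rpx <- as_pixels(ref)
  acc <- rpx
  cnt <- matrix(1, nrow(rpx), ncol(rpx))
  rows <- if (inherits(ref, "enface_image")) ref$motion_rows else integer(0)

  log <- vector("list", length(frames))
  n_failed <- 0L
  for (i in seq_along(frames)) {
    if (i == ref_i) next
    est <- estimate_transform(ref, frames[[i]])
    log[[i]] <- list(frame = i, dx = est$dx, dy = est$dy, theta = est$theta,
                     peak = attr(est, "peak"), failed = attr(est, "failed"))
    if (isTRUE(attr(est, "failed"))) {
      n_failed <- n_failed + 1L
      est <- transform2d(0, 0, 0)
    }
    al <- apply_transform(frames[[i]], invert_transform(est))
    v <- attr(al, "valid")
    acc <- acc + al$pixels * v
    cnt <- cnt + v
    rows <- c(rows, al$motion_rows)
  }
  if (n_failed == length(frames) - 1L && n_failed > 0L) {
    warning("all registrations failed; returning the reference frame")
    out <- enface_image(rpx, eye_id = if (inherits(ref, "enface_image")) ref$eye_id else "eye",
                        frame_index = 0L, role = "averaged",
                        motion_rows = rows)
    attr(out, "registration_failed") <- TRUE
    attr(out, "reference_index") <- ref_i
    return(out)
  }
  out <- enface_image(acc / cnt,
                      eye_id = if (inherits(ref, "enface_image")) ref$eye_id else "eye",
                      frame_index = 0L, role = "averaged",
                      pixel_size_um = if (inherits(ref, "enface_image")) ref$pixel_size_um else 6000 / nrow(rpx),
                      motion_rows = sort(unique(rows)))
  attr(out, "transform_log") <- log[!vapply(log, is.null, logical(1))]
  attr(out, "reference_index") <- ref_i
  attr(out, "quality_scores") <- q
  out
}
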