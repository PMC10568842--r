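#' Noise model parameters for synthetic enface rendering
#'
#' The rendering model is multiplicative speckle plus an additive
#' decorrelation background floor:
#' `pixels = clip(perfusion * (1 + speckle) + background, 0, 1)`, with
#' `speckle ~ N(0, speckle_sigma)` and
#' `background ~ N(background_level, background_sigma)`, followed by
#' motion-line corruption and (optionally) a multiplicative low-signal
#' shadow patch.
#'
#' @param speckle_sigma Multiplicative speckle scale, >= 0.
#' @param background_level Mean of the additive decorrelation floor, in `[0, 1)`.
#' @param background_sigma Std. dev. of the background floor, >= 0.
#' @param motion_line_rate Expected number of corrupted rows per frame
#'   (Poisson), >= 0.
#' @param shadow_prob Probability that a frame carries a low-signal shadow
#'   patch, in `[0, 1]`.
#' @param shadow_attenuation Multiplicative attenuation inside the shadow
#'   patch, in `(0, 1)`.
#' @param seed Integer seed; identical parameters and seed give a
#'   bit-identical rendering.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(speckle_sigma = 0.30, background_level = 0.12,
                         background_sigma = 0.04, motion_line_rate = 2,
                         shadow_prob = 0.3, shadow_attenuation = 0.5,
                         seed = 0L) {
  stopifnot_scalar(speckle_sigma, "speckle_sigma", lo = 0)
  stopifnot_scalar(background_level, "background_level", lo = 0, hi = 1 - 1e-9)
  stopifnot_scalar(background_sigma, "background_sigma", lo = 0)
  stopifnot_scalar(motion_line_rate, "motion_line_rate", lo = 0)
  stopifnot_scalar(shadow_prob, "shadow_prob", lo = 0, hi = 1)
  stopifnot_scalar(shadow_attenuation, "shadow_attenuation",
                   lo = 1e-9, hi = 1 - 1e-9)
  structure(list(speckle_sigma = speckle_sigma,
                 background_level = background_level,
                 background_sigma = background_sigma,
                 motion_line_rate = motion_line_rate,
                 shadow_prob = shadow_prob,
                 shadow_attenuation = shadow_attenuation,
                 seed = as.integer(seed)), class = "noise_params")
}

# Zero-noise variant used in tests and documentation examples.
#' @rdname noise_params
#' @export
noise_free <- function(seed = 0L) {
  noise_params(speckle_sigma = 0, background_level = 0, background_sigma = 0,
               motion_line_rate = 0, shadow_prob = 0, shadow_attenuation = 0.5,
               seed = seed)
}

# -- internal helpers ---------------------------------------------------------

# Disk offsets (dr, dc) for a given radius, cached per call site.
disk_offsets <- function(radius) {
  r <- max(0, radius)
  ri <- ceiling(r)
  g <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  g[g$dr^2 + g$dc^2 <= r^2 + 1e-9, , drop = FALSE]
}

# Stamp max(img, value) over a disk at (row, col); bounds-checked.
stamp_disk <- function(img, row, col, offs, value) {
  h <- nrow(img); w <- ncol(img)
  rr <- round(row) + offs$dr
  cc <- round(col) + offs$dc
  ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
  if (!any(ok)) return(img)
  idx <- (cc[ok] - 1L) * h + rr[ok]
  img[idx] <- pmax(img[idx], value)
  img
}

# Evaluation background: zero-perfusion pixels at least 2 px away from any
# vessel, excluding partial-volume pixels at vessel borders (the standard
# margin when measuring background statistics next to bright structures).
background_eval_mask <- function(perfusion, vessel_mask) {
  dil <- EBImage::dilate(vessel_mask * 1, EBImage::makeBrush(5, "disc"))
  perfusion == 0 & !(dil > 0)
}

# Smooth Gaussian random field in [0,1] (rank-uniformized), FFT low-pass.
smooth_field <- function(h, w, sigma_px) {
  z <- matrix(stats::rnorm(h * w), h, w)
  fr <- c(0:(floor(h / 2)), -(ceiling(h / 2) - 1):-1) / h
  fc <- c(0:(floor(w / 2)), -(ceiling(w / 2) - 1):-1) / w
  g <- exp(-2 * pi^2 * sigma_px^2 * outer(fr^2, fc^2, `+`))
  sm <- Re(stats::fft(stats::fft(z) * g, inverse = TRUE)) / (h * w)
  u <- rank(sm, ties.method = "first") / (h * w)
  dim(u) <- c(h, w)
  u
}

# -- phantom ------------------------------------------------------------------

#' Generate a seeded synthetic retinal-vasculature phantom
#'
#' Builds a noiseless ground-truth perfusion map emulating the structure of
#' a macular enface OCTA projection: 3-5 vessel trunks grown from the image
#' border by a recursive branching random walk (branch-angle jitter, width
#' decay per generation), a smooth capillary texture, a central foveal
#' avascular zone (FAZ) with a vessel-positive contour ring, and - depending
#' on `pathology_level` - capillary-dropout regions, microaneurysm dots and
#' (for `"pdr"`) a partially attenuated FAZ contour.
#'
#' The truth record is self-consistent: `vessel_mask` is exactly
#' `perfusion >= vessel_threshold`; `background_mask` marks pure background
#' used for noise statistics - zero-perfusion pixels at least 2 px from any
#' vessel (partial-volume pixels at vessel borders are excluded).
#'
#' @param size_px Integer vector `c(H, W)` (or scalar), each >= 64.
#' @param pathology_level `"healthy"`, `"npdr"` or `"pdr"`.
#' @param seed Integer seed; the phantom is a pure function of the arguments.
#' @param vessel_threshold Global perfusion threshold defining `vessel_mask`.
#' @param mm_extent Physical scan extent in millimetres (square field).
#' @return An object of class `octa_phantom`.
#' @export
generate_phantom <- function(size_px = c(256L, 256L),
                             pathology_level = c("healthy", "npdr", "pdr"),
                             seed = 1L, vessel_threshold = 0.35,
                             mm_extent = 6) {
  pathology_level <- match.arg(pathology_level)
  size_px <- rep(as.integer(size_px), length.out = 2L)
  if (any(size_px < 64L))
    stop("phantom size must be at least 64 px in each dimension", call. = FALSE)
  h <- size_px[1L]; w <- size_px[2L]

  with_seed(seed, {
    cr <- h / 2 + stats::runif(1, -5, 5)
    cc <- w / 2 + stats::runif(1, -5, 5)
    faz_radius <- 0.085 * min(h, w) * stats::runif(1, 0.9, 1.1)

    perf <- matrix(0, h, w)

    ## vessel trunks: branching random walks from the border toward the fovea.
    ## Stamps are collected and applied in one batched max-assignment.
    n_trunk <- sample(3:5, 1L)
    queue <- vector("list", 0L)
    for (k in seq_len(n_trunk)) {
      side <- sample(1:4, 1L)
      pos <- switch(side,
                    c(1, stats::runif(1, 1, w)),
                    c(h, stats::runif(1, 1, w)),
                    c(stats::runif(1, 1, h), 1),
                    c(stats::runif(1, 1, h), w))
      dir <- c(cr, cc) - pos
      dir <- dir / sqrt(sum(dir^2))
      ang <- atan2(dir[1], dir[2]) + stats::rnorm(1, 0, 0.2)
      queue[[length(queue) + 1L]] <-
        list(pos = pos, ang = ang, width = stats::runif(1, 1.8, 2.6), gen = 0L)
    }
    st_r <- st_c <- st_w <- st_v <- numeric(0)
    while (length(queue) > 0L) {
      wk <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (step in seq_len(220L)) {
        d <- sqrt((wk$pos[1] - cr)^2 + (wk$pos[2] - cc)^2)
        if (d < faz_radius + 3) break
        if (wk$pos[1] < -5 || wk$pos[1] > h + 5 ||
            wk$pos[2] < -5 || wk$pos[2] > w + 5) break
        if (wk$width < 0.6) break
        st_r <- c(st_r, wk$pos[1]); st_c <- c(st_c, wk$pos[2])
        st_w <- c(st_w, wk$width)
        st_v <- c(st_v, min(0.9, 0.5 + 0.15 * wk$width))
        ## steer: jitter plus a weak pull toward the fovea while far away
        wk$ang <- wk$ang + stats::rnorm(1, 0, 0.12)
        if (d > 0.35 * min(h, w)) {
          to_c <- atan2(cr - wk$pos[1], cc - wk$pos[2])
          dd <- atan2(sin(to_c - wk$ang), cos(to_c - wk$ang))
          wk$ang <- wk$ang + 0.08 * dd
        }
        wk$pos <- wk$pos + 1.5 * c(sin(wk$ang), cos(wk$ang))
        wk$width <- wk$width * 0.998
        if (stats::runif(1) < 0.012 && wk$gen < 4L && wk$width * 0.72 >= 0.6) {
          queue[[length(queue) + 1L]] <- list(
            pos = wk$pos,
            ang = wk$ang + sample(c(-1, 1), 1L) * stats::runif(1, 0.35, 0.8),
            width = wk$width * 0.72, gen = wk$gen + 1L)
        }
      }
    }
    if (length(st_r) > 0) {
      wkey <- round(st_w * 2) / 2
      idx_all <- integer(0); val_all <- numeric(0)
      for (rk in unique(wkey)) {
        offs <- disk_offsets(rk)
        sel <- which(wkey == rk)
        rr <- rep(round(st_r[sel]), each = nrow(offs)) + offs$dr
        cc2 <- rep(round(st_c[sel]), each = nrow(offs)) + offs$dc
        vv <- rep(st_v[sel], each = nrow(offs))
        ok <- rr >= 1 & rr <= h & cc2 >= 1 & cc2 <= w
        idx_all <- c(idx_all, (cc2[ok] - 1L) * h + rr[ok])
        val_all <- c(val_all, vv[ok])
      }
      ## duplicate indices: assign in increasing value order so max wins
      o <- order(val_all)
      perf[idx_all[o]] <- val_all[o]
    }

    ## capillary texture: thresholded smooth random field
    u <- smooth_field(h, w, sigma_px = 2.5)
    cov <- 0.16
    cap <- matrix(0, h, w)
    sel <- u > 1 - cov
    cap[sel] <- 0.42 + 0.18 * (u[sel] - (1 - cov)) / cov
    perf <- pmax(perf, cap)

    ## FAZ: clear the interior, draw the contour ring
    dist <- sqrt(outer((seq_len(h) - cr)^2, (seq_len(w) - cc)^2, `+`))
    perf[dist < faz_radius] <- 0
    ring_mask <- dist >= faz_radius - 1 & dist <= faz_radius + 1
    perf[ring_mask] <- 0.55
    if (pathology_level == "pdr") {
      ## partially attenuated contour: one ~30 degree arc drops below threshold
      a0 <- stats::runif(1, -pi, pi)
      ang <- atan2(outer(seq_len(h) - cr, rep(1, w)),
                   outer(rep(1, h), seq_len(w) - cc))
      gap <- ring_mask & (atan2(sin(ang - a0), cos(ang - a0)) > 0) &
        (atan2(sin(ang - a0), cos(ang - a0)) < pi / 6)
      perf[gap] <- 0.18
    }

    ## capillary-dropout regions (rotated ellipses, perfusion zeroed)
    n_drop <- switch(pathology_level, healthy = 0L,
                     npdr = sample(1:3, 1L), pdr = sample(3:6, 1L))
    dropout_masks <- vector("list", n_drop)
    rowg <- matrix(seq_len(h), h, w); colg <- matrix(seq_len(w), h, w, byrow = TRUE)
    for (k in seq_len(n_drop)) {
      repeat {
        dr0 <- stats::runif(1, 0.15 * h, 0.85 * h)
        dc0 <- stats::runif(1, 0.15 * w, 0.85 * w)
        if (sqrt((dr0 - cr)^2 + (dc0 - cc)^2) > faz_radius + 12) break
      }
      a <- stats::runif(1, 8, 20); b <- stats::runif(1, 6, 14)
      phi <- stats::runif(1, 0, pi)
      xr <- (rowg - dr0) * cos(phi) + (colg - dc0) * sin(phi)
      yr <- -(rowg - dr0) * sin(phi) + (colg - dc0) * cos(phi)
      m <- (xr / a)^2 + (yr / b)^2 <= 1
      perf[m] <- 0
      dropout_masks[[k]] <- m
    }

    ## microaneurysms: small bright dots away from the FAZ
    n_ma <- switch(pathology_level, healthy = 0L,
                   npdr = sample(3:8, 1L), pdr = sample(8:15, 1L))
    ma_centers <- matrix(NA_real_, n_ma, 2L,
                         dimnames = list(NULL, c("row", "col")))
    ma_offs <- disk_offsets(1.5)
    for (k in seq_len(n_ma)) {
      repeat {
        mr <- stats::runif(1, 5, h - 5); mc <- stats::runif(1, 5, w - 5)
        if (sqrt((mr - cr)^2 + (mc - cc)^2) > faz_radius + 6) break
      }
      perf <- stamp_disk(perf, mr, mc, ma_offs, 0.8)
      ma_centers[k, ] <- c(mr, mc)
    }

    perf <- clip01(perf)
    vessel_mask <- perf >= vessel_threshold
    structure(list(
      perfusion = perf,
      vessel_mask = vessel_mask,
      background_mask = background_eval_mask(perf, vessel_mask),
      ring_mask = ring_mask,
      faz_center = c(row = cr, col = cc),
      faz_radius = faz_radius,
      microaneurysm_centers = ma_centers,
      dropout_masks = dropout_masks,
      size_px = c(h, w),
      mm_extent = mm_extent,
      pathology = pathology_level,
      vessel_threshold = vessel_threshold,
      seed = as.integer(seed)
    ), class = "octa_phantom")
  })
}

#' @export
print.octa_phantom <- function(x, ...) {
  out <- !x$ring_mask & outer((seq_len(x$size_px[1]) - x$faz_center[1])^2,
                              (seq_len(x$size_px[2]) - x$faz_center[2])^2,
                              `+`) > x$faz_radius^2
  cat(sprintf("<octa_phantom> %d x %d px (%s), seed %d\n",
              x$size_px[1], x$size_px[2], x$pathology, x$seed))
  cat(sprintf("  vessel fraction outside FAZ: %.1f%%; %d microaneurysm(s), %d dropout region(s)\n",
              100 * mean(x$vessel_mask[out]),
              sum(!is.na(x$microaneurysm_centers[, 1])),
              length(x$dropout_masks)))
  invisible(x)
}

# -- rendering ----------------------------------------------------------------

#' Render a noisy single-frame enface scan from a phantom
#'
#' Applies the package noise model (see [noise_params()]) to the phantom's
#' perfusion map: multiplicative speckle, additive Gaussian decorrelation
#' background, Poisson-count motion-line rows (each equiprobably replaced by
#' bright noise or horizontally shifted by up to 6 px), and optionally one
#' multiplicative shadow patch. An optional rigid [transform2d()] is applied
#' to the scene before noising, emulating inter-acquisition eye motion.
#'
#' @param phantom An [generate_phantom()] result.
#' @param noise A [noise_params()] object.
#' @param eye_id,frame_index Metadata for the returned [enface_image()].
#' @param transform Optional [transform2d()] applied to the clean scene.
#' @return An [enface_image()] with motion rows, shadow box and the true
#'   transform recorded in its metadata.
#' @export
render_single_frame <- function(phantom, noise = noise_params(),
                                eye_id = "eye", frame_index = 0L,
                                transform = NULL) {
  stopifnot(inherits(phantom, "octa_phantom"), inherits(noise, "noise_params"))
  base <- phantom$perfusion
  if (!is.null(transform)) base <- warp_pixels(base, transform)$pixels
  h <- nrow(base); w <- ncol(base)

  with_seed(noise$seed, {
    img <- base
    if (noise$speckle_sigma > 0)
      img <- img * (1 + matrix(stats::rnorm(h * w, 0, noise$speckle_sigma), h, w))
    if (noise$background_sigma > 0) {
      img <- img + matrix(stats::rnorm(h * w, noise$background_level,
                                       noise$background_sigma), h, w)
    } else {
      img <- img + noise$background_level
    }
    img <- clip01(img)

    motion_rows <- integer(0)
    n_rows <- stats::rpois(1, noise$motion_line_rate)
    if (n_rows > 0) {
      motion_rows <- sort(sample.int(h, min(n_rows, h)))
      for (r in motion_rows) {
        if (stats::runif(1) < 0.5) {
          ## white-line artifact: the row is replaced by bright noise
          img[r, ] <- clip01(stats::rnorm(w, 0.85, 0.08))
        } else {
          ## displaced row: horizontal shift by 1..6 px
          k <- sample.int(6, 1L) * sample(c(-1L, 1L), 1L)
          filler <- clip01(stats::rnorm(abs(k), noise$background_level,
                                        max(noise$background_sigma, 1e-6)))
          img[r, ] <- if (k > 0) c(filler, img[r, seq_len(w - k)])
                      else c(img[r, (1 - k):w], filler)
        }
      }
    }

    shadow_bbox <- NULL
    if (stats::runif(1) < noise$shadow_prob) {
      hs <- min(round(stats::runif(1, 40, 80)), h - 2L)
      ws <- min(round(stats::runif(1, 40, 80)), w - 2L)
      r0 <- sample.int(h - hs + 1L, 1L); c0 <- sample.int(w - ws + 1L, 1L)
      shadow_bbox <- c(r0, r0 + hs - 1L, c0, c0 + ws - 1L)
      img[r0:(r0 + hs - 1L), c0:(c0 + ws - 1L)] <-
        img[r0:(r0 + hs - 1L), c0:(c0 + ws - 1L)] * noise$shadow_attenuation
    }

    enface_image(img, eye_id = eye_id, frame_index = frame_index,
                 role = "single",
                 pixel_size_um = 1000 * phantom$mm_extent / h,
                 motion_rows = motion_rows, shadow_bbox = shadow_bbox,
                 true_transform = transform)
  })
}

#' Render a repeated-acquisition frame stack
#'
#' Renders `n_frames` single frames of the same phantom, each under an
#' independent rigid true transform drawn within the stated bounds and with
#' independent noise and motion lines. The true transforms are stored with
#' the stack for registration parameter-recovery tests.
#'
#' @inheritParams render_single_frame
#' @param n_frames Number of repetitions, >= 2 (default 4).
#' @param max_shift_px Bound on |dx| and |dy| of the true transforms.
#' @param max_rot_deg Bound on |rotation| of the true transforms, degrees.
#' @return An object of class `frame_stack` with elements `frames` (list of
#'   [enface_image()]), `true_transforms`, `eye_id` and `reference_index`
#'   (unset until [average_frames()] selects it).
#' @export
render_frame_stack <- function(phantom, n_frames = 4L, noise = noise_params(),
                               max_shift_px = 5, max_rot_deg = 1,
                               eye_id = "eye") {
  if (n_frames < 2L)
    stop("a frame stack needs at least 2 frames", call. = FALSE)
  trs <- with_seed(noise$seed, {
    lapply(seq_len(n_frames), function(i) {
      transform2d(dx = stats::runif(1, -max_shift_px, max_shift_px),
                  dy = stats::runif(1, -max_shift_px, max_shift_px),
                  theta = stats::runif(1, -max_rot_deg, max_rot_deg) * pi / 180)
    })
  })
  frames <- lapply(seq_len(n_frames), function(i) {
    ni <- noise; ni$seed <- child_seed(noise$seed, i)
    render_single_frame(phantom, ni, eye_id = eye_id,
                        frame_index = i - 1L, transform = trs[[i]])
  })
  structure(list(frames = frames, true_transforms = trs,
                 eye_id = eye_id, reference_index = NA_integer_),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("<frame_stack> %s: %d frames of %d x %d px\n", x$eye_id,
              length(x$frames), nrow(x$frames[[1]]$pixels),
              ncol(x$frames[[1]]$pixels)))
  invisible(x)
}
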