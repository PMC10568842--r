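#' Simulate a full synthetic study cohort in memory
#'
#' Draws one phantom per eye (pathology sampled from `pathology_mix`),
#' renders 4-frame repeated-acquisition stacks for training/validation eyes
#' and a single frame for test eyes, all deterministically from `seed`.
#'
#' @param n_eyes Total number of eyes.
#' @param splits Named integer vector `c(train=, val=, test=)` (missing
#'   entries are 0) that must sum to `n_eyes`.
#' @param size_px Scan side in pixels (square).
#' @param noise A [noise_params()] object; its `seed` is ignored in favour
#'   of per-eye seeds derived from `seed`.
#' @param pathology_mix Named probabilities for `healthy`/`npdr`/`pdr`
#'   (defaults approximate a mixed healthy/diabetic clinic population).
#' @param n_frames Frames per stack for train/val eyes.
#' @param max_shift_px,max_rot_deg Inter-frame true-motion bounds.
#' @param seed Master seed.
#' @return List of eyes; each is a list with `eye_id`, `split`,
#'   `pathology`, `phantom`, and `stack` (train/val) or `scan` (test).
#' @export
simulate_study <- function(n_eyes, splits = c(train = 4L, test = n_eyes - 4L),
                           size_px = 256L, noise = noise_params(),
                           pathology_mix = c(healthy = 0.42, npdr = 0.41,
                                             pdr = 0.17),
                           n_frames = 4L, max_shift_px = 5, max_rot_deg = 1,
                           seed = 0L) {
  full <- c(train = 0L, val = 0L, test = 0L)
  if (is.null(names(splits))) names(splits) <- names(full)[seq_along(splits)]
  full[names(splits)] <- as.integer(splits)
  if (sum(full) != n_eyes)
    stop(sprintf("splits (%s) must partition n_eyes = %d",
                 paste(full, collapse = "+"), n_eyes), call. = FALSE)
  assignment <- rep(names(full), times = full)
  pathologies <- with_seed(seed, {
    sample(names(pathology_mix), n_eyes, replace = TRUE, prob = pathology_mix)
  })
  lapply(seq_len(n_eyes), function(i) {
    eye_id <- sprintf("eye%03d", i)
    phantom <- generate_phantom(c(size_px, size_px), pathologies[i],
                                seed = child_seed(seed, i))
    ni <- noise; ni$seed <- child_seed(seed, 100000L + i)
    if (assignment[i] %in% c("train", "val")) {
      stack <- render_frame_stack(phantom, n_frames = n_frames, noise = ni,
                                  max_shift_px = max_shift_px,
                                  max_rot_deg = max_rot_deg, eye_id = eye_id)
      list(eye_id = eye_id, split = assignment[i], pathology = pathologies[i],
           phantom = phantom, stack = stack)
    } else {
      scan <- render_single_frame(phantom, ni, eye_id = eye_id)
      list(eye_id = eye_id, split = assignment[i], pathology = pathologies[i],
           phantom = phantom, scan = scan)
    }
  })
}

#' Artifact mask for a training target scan
#'
#' Marks target regions that must not drive the loss: rows carrying
#' residual motion-line artifact in the averaged target (plus a halo) and,
#' optionally, its shadow box. This plays the role of the manual masking of
#' artifact-affected patches in averaged targets; masked regions still
#' enter the network input.
#'
#' @param target An [enface_image()] (typically an [average_frames()] output).
#' @param halo Rows above/below each annotated motion row also masked.
#' @param mask_shadow Also mask the shadow bounding box, if annotated.
#' @return Logical matrix, `TRUE` where the target is a valid training target.
#' @export
target_artifact_mask <- function(target, halo = 1L, mask_shadow = TRUE) {
  px <- as_pixels(target)
  m <- matrix(TRUE, nrow(px), ncol(px))
  if (inherits(target, "enface_image")) {
    for (r in target$motion_rows) {
      rows <- max(1L, r - halo):min(nrow(px), r + halo)
      m[rows, ] <- FALSE
    }
    if (mask_shadow && !is.null(target$shadow_bbox)) {
      b <- target$shadow_bbox
      m[b[1]:b[2], b[3]:b[4]] <- FALSE
    }
  }
  m
}

#' Build the training corpus from simulated training eyes
#'
#' For each training eye the frame stack is registered and averaged; the
#' best-quality single frame (the averaging reference, already aligned) is
#' paired with the average on a patch grid, with residual target artifacts
#' masked out of the loss. When `use_p2p` is `TRUE`, the lowest-quality
#' frame of each eye is registered to the highest-quality frame and added
#' as peer-to-peer pairs (low in, high out), the safety ingredient against
#' over-denoising of low-signal regions.
#'
#' @param eyes A [simulate_study()] result (train/val eyes are used).
#' @param stride Patch-grid stride in pixels.
#' @param use_p2p Include peer-to-peer pairs.
#' @return List with `pairs` (training pairs), `averages` (named list of
#'   averaged [enface_image()]s) and `references` (named integer vector of
#'   reference frame indices).
#' @export
build_training_pairs <- function(eyes, stride = 64L, use_p2p = TRUE) {
  train_eyes <- Filter(function(e) !is.null(e$stack), eyes)
  pairs <- list(); averages <- list(); refs <- integer(0)
  for (e in train_eyes) {
    avg <- average_frames(e$stack)
    ref_i <- attr(avg, "reference_index")
    averages[[e$eye_id]] <- avg
    refs[e$eye_id] <- ref_i
    ref <- e$stack$frames[[ref_i]]
    grid <- patch_grid(dim(ref$pixels), stride = stride)
    mask <- target_artifact_mask(avg)
    pairs <- c(pairs, make_single_to_average_pairs(ref, avg, mask, grid,
                                                   source_eye = e$eye_id))
    if (use_p2p) {
      q <- vapply(e$stack$frames, quality_score, numeric(1))
      lo <- which.min(q); hi <- which.max(q)
      if (lo != hi && q[lo] < q[hi]) {
        est <- estimate_transform(e$stack$frames[[hi]], e$stack$frames[[lo]])
        if (!isTRUE(attr(est, "failed"))) {
          al <- apply_transform(e$stack$frames[[lo]], invert_transform(est))
          pmask <- attr(al, "valid") &
            target_artifact_mask(e$stack$frames[[hi]], mask_shadow = FALSE)
          pp <- tryCatch(
            make_peer_to_peer_pairs(al, e$stack$frames[[hi]], grid,
                                    artifact_mask = pmask,
                                    source_eye = e$eye_id),
            error = function(err) list())
          pairs <- c(pairs, pp)
        }
      }
    }
  }
  list(pairs = pairs, averages = averages, references = refs)
}

#' Write a synthetic dataset to disk
#'
#' Renders a [simulate_study()] cohort and writes 16-bit grayscale TIFF
#' images, truth masks (8-bit PNG) and a JSON manifest recording file
#' paths, roles, true transforms, motion rows and shadow boxes per frame.
#' Re-running with the same configuration reproduces byte-identical files.
#'
#' @param n_eyes,splits As in [simulate_study()].
#' @param config Optional list overriding [simulate_study()] arguments
#'   (`size_px`, `noise` (a list of [noise_params()] fields), `pathology_mix`,
#'   `n_frames`, `max_shift_px`, `max_rot_deg`, `seed`).
#' @param out_dir Output directory (created; must be writable).
#' @return The manifest path, invisibly.
#' @export
make_dataset <- function(n_eyes, splits, config = list(), out_dir) {
  defaults <- list(size_px = 256L, noise = list(), pathology_mix = NULL,
                   n_frames = 4L, max_shift_px = 5, max_rot_deg = 1, seed = 0L)
  bad <- setdiff(names(config), names(defaults))
  if (length(bad) > 0)
    stop("unknown config field(s): ", paste(bad, collapse = ", "), call. = FALSE)
  cfg <- utils::modifyList(defaults, config)
  noise <- do.call(noise_params, cfg$noise)
  args <- list(n_eyes = n_eyes, splits = splits, size_px = cfg$size_px,
               noise = noise, n_frames = cfg$n_frames,
               max_shift_px = cfg$max_shift_px, max_rot_deg = cfg$max_rot_deg,
               seed = cfg$seed)
  if (!is.null(cfg$pathology_mix)) args$pathology_mix <- unlist(cfg$pathology_mix)
  eyes <- do.call(simulate_study, args)

  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory ", out_dir, call. = FALSE)
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, showWarnings = FALSE)

  frame_entry <- function(fr, path) {
    tt <- fr$true_transform
    list(path = path, frame_index = fr$frame_index, role = fr$role,
         true_transform = if (is.null(tt)) NULL else
           list(dx = tt$dx, dy = tt$dy, theta = tt$theta),
         motion_rows = as.list(fr$motion_rows),
         shadow_bbox = if (is.null(fr$shadow_bbox)) NULL else
           as.list(fr$shadow_bbox))
  }
  manifest_eyes <- lapply(eyes, function(e) {
    truth_tiff <- file.path("images", paste0(e$eye_id, "_truth.tiff"))
    mask_png <- file.path("images", paste0(e$eye_id, "_vessel_mask.png"))
    write_enface_tiff(e$phantom$perfusion, file.path(out_dir, truth_tiff))
    write_mask_png(e$phantom$vessel_mask, file.path(out_dir, mask_png))
    frames <- if (!is.null(e$stack)) e$stack$frames else list(e$scan)
    fentries <- lapply(frames, function(fr) {
      path <- file.path("images", sprintf("%s_frame%d.tiff", e$eye_id,
                                          fr$frame_index))
      write_enface_tiff(fr, file.path(out_dir, path))
      frame_entry(fr, path)
    })
    list(eye_id = e$eye_id, split = e$split, pathology = e$pathology,
         faz = list(center_row = unname(e$phantom$faz_center[1]),
                    center_col = unname(e$phantom$faz_center[2]),
                    radius = e$phantom$faz_radius),
         vessel_threshold = e$phantom$vessel_threshold,
         truth = list(perfusion = truth_tiff, vessel_mask = mask_png),
         frames = fentries)
  })
  manifest <- list(n_eyes = n_eyes, size_px = cfg$size_px, seed = cfg$seed,
                   eyes = manifest_eyes)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest_path)
}

#' Load a dataset written by [make_dataset()]
#'
#' Reconstructs the in-memory cohort: frames as [enface_image()]s with
#' their annotations, and a truth record per eye (perfusion map, vessel and
#' background masks, FAZ geometry) sufficient for every evaluation metric.
#'
#' @param dir Dataset directory containing `manifest.json`.
#' @return List of eyes mirroring [simulate_study()] output.
#' @export
load_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  lapply(manifest$eyes, function(me) {
    perf <- read_enface_tiff(file.path(dir, me$truth$perfusion))
    h <- nrow(perf); w <- ncol(perf)
    cr <- me$faz$center_row; cc <- me$faz$center_col; rad <- me$faz$radius
    dist <- sqrt(outer((seq_len(h) - cr)^2, (seq_len(w) - cc)^2, `+`))
    vm <- read_mask_png(file.path(dir, me$truth$vessel_mask))
    phantom <- structure(list(
      perfusion = perf,
      vessel_mask = vm,
      background_mask = octapseudo:::background_eval_mask(perf, vm),
      ring_mask = dist >= rad - 1 & dist <= rad + 1,
      faz_center = c(row = cr, col = cc), faz_radius = rad,
      microaneurysm_centers = NULL, dropout_masks = NULL,
      size_px = c(h, w), mm_extent = 6, pathology = me$pathology,
      vessel_threshold = me$vessel_threshold, seed = NA_integer_),
      class = "octa_phantom")
    frames <- lapply(me$frames, function(fe) {
      tt <- fe$true_transform
      if (is.null(tt$dx)) tt <- NULL     # JSON null round-trips as empty list
      enface_image(read_enface_tiff(file.path(dir, fe$path)),
                   eye_id = me$eye_id, frame_index = fe$frame_index,
                   role = fe$role,
                   motion_rows = unlist(fe$motion_rows),
                   shadow_bbox = if (length(fe$shadow_bbox)) unlist(fe$shadow_bbox),
                   true_transform = if (!is.null(tt))
                     transform2d(tt$dx, tt$dy, tt$theta))
    })
    out <- list(eye_id = me$eye_id, split = me$split,
                pathology = me$pathology, phantom = phantom)
    if (me$split %in% c("train", "val") && length(frames) > 1L) {
      out$stack <- structure(list(
        frames = frames,
        true_transforms = lapply(frames, `[[`, "true_transform"),
        eye_id = me$eye_id, reference_index = NA_integer_),
        class = "frame_stack")
    } else out$scan <- frames[[1L]]
    out
  })
}
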