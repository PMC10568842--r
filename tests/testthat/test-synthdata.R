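test_that("phantom generation is deterministic and honours the pathology knob", {
  p1 <- generate_phantom(c(256, 256), "npdr", seed = 2)
  p2 <- generate_phantom(c(256, 256), "npdr", seed = 2)
  expect_identical(p1, p2)

  healthy <- generate_phantom(c(256, 256), "healthy", seed = 1)
  expect_identical(nrow(healthy$microaneurysm_centers), 0L)
  expect_length(healthy$dropout_masks, 0)

  npdr <- generate_phantom(c(128, 128), "npdr", seed = 3)
  expect_gt(nrow(npdr$microaneurysm_centers), 0)
  expect_gt(length(npdr$dropout_masks), 0)

  expect_error(generate_phantom(c(32, 256), "healthy"), "at least 64")
  expect_error(generate_phantom(c(256, 256), "plain-weird"))
})

test_that("phantom truth record is self-consistent", {
  for (seed in 1:3) {
    ph <- generate_phantom(c(256, 256), c("healthy", "npdr", "pdr")[seed],
                           seed = seed)
    expect_true(all(is.finite(ph$perfusion)))
    expect_true(all(ph$perfusion >= 0 & ph$perfusion <= 1))
    ## vessel mask is exactly a recomputed threshold of the perfusion map
    expect_identical(ph$vessel_mask, ph$perfusion >= ph$vessel_threshold)

    ## FAZ interior carries no vessels (ring pixels excluded)
    h <- ph$size_px[1]; w <- ph$size_px[2]
    d <- sqrt(outer((seq_len(h) - ph$faz_center[1])^2,
                    (seq_len(w) - ph$faz_center[2])^2, `+`))
    expect_false(any(ph$vessel_mask[d < ph$faz_radius - 1.5]))

    ## vessel coverage outside the FAZ in the plausible OCTA range
    outside <- d > ph$faz_radius + 1 & !ph$ring_mask
    frac <- mean(ph$vessel_mask[outside])
    expect_gt(frac, 0.15)
    expect_lt(frac, 0.45)
  }
})

test_that("healthy phantoms carry a complete, vessel-positive FAZ contour ring", {
  ph <- generate_phantom(c(256, 256), "healthy", seed = 4)
  expect_true(all(ph$perfusion[ph$ring_mask] >= ph$vessel_threshold))
  expect_equal(faz_contour_continuity(ph$perfusion, ph), 1.0)
})

test_that("zero-noise rendering reduces to clip(perfusion + background level)", {
  ph <- fx_phantom()
  np <- noise_params(speckle_sigma = 0, background_level = 0.1,
                     background_sigma = 0, motion_line_rate = 0,
                     shadow_prob = 0, seed = 3)
  img <- render_single_frame(ph, np)
  expect_equal(img$pixels, pmin(ph$perfusion + 0.1, 1), tolerance = 1e-12)
  expect_length(img$motion_rows, 0)
  expect_null(img$shadow_bbox)
})

test_that("background noise statistics match the stated model", {
  ## pure-background region: an npdr phantom's dropout-free zero-perfusion area
  ph <- generate_phantom(c(256, 256), "healthy", seed = 11)
  np <- noise_params(background_level = 0.1, background_sigma = 0.03,
                     motion_line_rate = 0, shadow_prob = 0, seed = 7)
  img <- render_single_frame(ph, np)
  bg <- img$pixels[ph$background_mask]
  se <- 0.03 / sqrt(length(bg))
  expect_lt(abs(mean(bg) - 0.1), 3 * se + 0.001)  # +0.001 for clip bias
  ## noise calibration: empirical sd within 5% of background_sigma
  expect_lt(abs(sd(bg) - 0.03) / 0.03, 0.05)
})

test_that("rendering determinism and the Poisson motion-line rate hold", {
  ph <- fx_phantom()
  np <- noise_params(seed = 5)
  expect_identical(render_single_frame(ph, np)$pixels,
                   render_single_frame(ph, np)$pixels)

  small <- generate_phantom(c(64, 64), "healthy", seed = 1)
  counts <- vapply(1:800, function(s) {
    length(render_single_frame(small, noise_params(motion_line_rate = 3,
                                                   shadow_prob = 0,
                                                   seed = s))$motion_rows)
  }, numeric(1))
  ## Monte-Carlo check of the stated rate (sampling error ~ 3*sqrt(3/800))
  expect_lt(abs(mean(counts) - 3), 3 * sqrt(3 / 800))
})

test_that("frame stacks record bounded true transforms and vary motion rows", {
  ph <- fx_phantom()
  st0 <- render_frame_stack(ph, 4, noise_free(seed = 2), max_shift_px = 0,
                            max_rot_deg = 0)
  for (i in 2:4) expect_equal(st0$frames[[i]]$pixels, st0$frames[[1]]$pixels)

  st <- render_frame_stack(ph, 4, noise_params(seed = 3), max_shift_px = 8,
                           max_rot_deg = 1)
  for (tt in st$true_transforms) {
    expect_lte(abs(tt$dx), 8); expect_lte(abs(tt$dy), 8)
    expect_lte(abs(tt$theta), 1 * pi / 180)
  }

  ## independent motion lines: row sets differ between frames (the premise
  ## that averaging can draw on unaffected repetitions)
  any_equal <- 0
  for (s in 1:40) {
    st <- render_frame_stack(ph, 4, noise_params(motion_line_rate = 3, seed = s))
    rows <- lapply(st$frames, `[[`, "motion_rows")
    pairs <- combn(4, 2)
    any_equal <- any_equal + any(apply(pairs, 2, function(ij)
      identical(rows[[ij[1]]], rows[[ij[2]]]) && length(rows[[ij[1]]]) > 0))
  }
  expect_lt(any_equal / 40, 0.1)
  expect_error(render_frame_stack(ph, 1), "at least 2")
})

test_that("datasets on disk partition the cohort and rebuild faithfully", {
  dir1 <- withr::local_tempdir()
  cfg <- list(size_px = 64L, seed = 42L)
  make_dataset(10, c(train = 2, val = 3, test = 5), cfg, dir1)
  man <- jsonlite::read_json(file.path(dir1, "manifest.json"))
  expect_length(man$eyes, 10)
  splits <- vapply(man$eyes, `[[`, "", "split")
  expect_identical(as.integer(table(splits)[c("train", "val", "test")]),
                   c(2L, 3L, 5L))
  expect_error(make_dataset(10, c(train = 3, test = 5), cfg, withr::local_tempdir()),
               "partition")

  ## reload: images and annotations round-trip (16-bit quantization only)
  eyes <- load_dataset(dir1)
  expect_length(eyes, 10)
  tr <- eyes[[which(splits == "train")[1]]]
  expect_length(tr$stack$frames, 4)
  expect_true(all(abs(tr$phantom$perfusion -
                        generate_phantom(c(64, 64),
                                         tr$pathology,
                                         seed = octapseudo:::child_seed(42L, which(splits == "train")[1]))$perfusion) < 1e-4))

  ## byte-identical regeneration under the same config
  dir2 <- withr::local_tempdir()
  make_dataset(10, c(train = 2, val = 3, test = 5), cfg, dir2)
  f1 <- list.files(dir1, recursive = TRUE)
  expect_identical(f1, list.files(dir2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readBin(file.path(dir1, f), "raw", 2e6),
                     readBin(file.path(dir2, f), "raw", 2e6))
  }
})

test_that("study-scale split sizes are respected", {
  full <- c(train = 5L, val = 34L, test = 105L)
  eyes <- simulate_study(144, full, size_px = 64L, seed = 1)
  got <- table(vapply(eyes, `[[`, "", "split"))
  expect_identical(as.integer(got[names(full)]), unname(as.integer(full)))
  ## test eyes are single frames without averaged targets
  test_eyes <- Filter(function(e) e$split == "test", eyes)
  expect_true(all(vapply(test_eyes, function(e) is.null(e$stack), logical(1))))
  expect_length(test_eyes, 105)
})
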