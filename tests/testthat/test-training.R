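test_that("masked L1 loss matches hand-computed values", {
  p <- matrix(runif(64 * 64), 64)
  expect_equal(masked_l1_loss(p, p), 0)
  expect_equal(masked_l1_loss(p - 0.1, p), 0.1, tolerance = 1e-12)

  ## differences confined to the masked-out half contribute nothing
  t <- p
  m <- matrix(TRUE, 64, 64); m[, 1:32] <- FALSE
  p2 <- p; p2[, 1:32] <- p2[, 1:32] + 0.4
  expect_equal(masked_l1_loss(p2, t, m), 0)

  expect_error(masked_l1_loss(p, t, matrix(FALSE, 64, 64)), "no TRUE")
  expect_error(masked_l1_loss(p, matrix(0, 32, 32)), "shapes")
})

test_that("single-to-average pair cutting applies the artifact-mask rules", {
  set.seed(1)
  single <- matrix(runif(256 * 256), 256)
  avg <- matrix(runif(256 * 256), 256)
  grid <- patch_grid(c(256L, 256L), stride = 64L)

  pairs <- make_single_to_average_pairs(single, avg, grid = grid)
  expect_length(pairs, 16L)
  expect_true(all(vapply(pairs, function(p) all(p$mask), logical(1))))
  expect_true(all(vapply(pairs, `[[`, "", "kind") == "single_to_average"))

  ## mask excluding exactly one 64x64 tile drops that pair
  m <- matrix(TRUE, 256, 256); m[65:128, 129:192] <- FALSE
  pairs2 <- make_single_to_average_pairs(single, avg, m, grid)
  expect_length(pairs2, 15L)

  ## half-masked tile is retained with exactly 2048 valid pixels
  m3 <- matrix(TRUE, 256, 256); m3[1:32, 1:64] <- FALSE
  pairs3 <- make_single_to_average_pairs(single, avg, m3, grid)
  expect_length(pairs3, 16L)
  expect_equal(sum(pairs3[[1]]$mask), 2048L)

  expect_error(make_single_to_average_pairs(single, avg[1:128, 1:128]),
               "same shape")
})

test_that("peer-to-peer pairs require a real quality gap and preserve shadows", {
  ph <- fx_phantom(256)
  clean <- render_single_frame(ph, noise_params(shadow_prob = 0,
                                                motion_line_rate = 0, seed = 1))
  expect_error(make_peer_to_peer_pairs(clean, clean), "quality_score")

  shadowed <- clean
  shadowed$pixels[81:160, 81:160] <- shadowed$pixels[81:160, 81:160] * 0.5
  shadowed$shadow_bbox <- c(81L, 160L, 81L, 160L)
  grid <- patch_grid(c(256L, 256L), stride = 64L)
  pairs <- make_peer_to_peer_pairs(shadowed, clean, grid)
  expect_gt(length(pairs), 0)
  expect_true(all(vapply(pairs, `[[`, "", "kind") == "peer_to_peer"))
  ## inside the shadow box every input patch is dimmer than its target
  for (p in pairs) expect_lte(mean(p$input), mean(p$target) + 1e-9)
})

test_that("training on an identity task converges and is reproducible", {
  pairs <- fx_identity_pairs()
  spec <- unet_spec(levels = 3, base_channels = 8)
  fit <- fit_pseudoaverager(pairs, spec,
                            train_config(epochs = 5, learning_rate = 0.02,
                                         momentum = 0.5, seed = 1))
  ## the network starts near the identity, so the identity task sits at the
  ## loss floor from the first epoch and stays there
  expect_lt(min(fit$loss_history), 0.01)
  expect_true(all(fit$loss_history < 0.05))

  ## bit-identical weights under an identical config + seed
  fit2 <- fit_pseudoaverager(pairs, spec,
                             train_config(epochs = 5, learning_rate = 0.02,
                                          momentum = 0.5, seed = 1))
  expect_identical(fit$layers, fit2$layers)
  expect_identical(fit$loss_history, fit2$loss_history)
})

test_that("augmentation sets generate the expected dihedral variants", {
  ac <- octapseudo:::augment_codes
  expect_identical(ac(character(0)), 0L)
  expect_length(ac("hflip"), 2L)
  expect_length(ac(c("hflip", "vflip")), 4L)
  expect_length(ac(c("hflip", "vflip", "rot90")), 8L)
  expect_length(ac("rot90"), 4L)   # rotations alone form the cyclic subgroup
})

test_that("training rejects malformed configurations", {
  expect_error(train_config(learning_rate = 0), "learning_rate")
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(augmentations = "elastic"), "unknown augmentations")
  expect_error(fit_pseudoaverager(list()), "no training pairs")
})
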