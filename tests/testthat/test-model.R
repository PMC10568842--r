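test_that("patch grids cover the image and honour the count formula", {
  g <- patch_grid(c(500L, 500L), 64L)                 # default stride 14
  expect_equal(g$stride, 14L)
  ## 32 lattice positions per side plus one edge-snapped column/row for
  ## complete coverage: 33^2 positions, "approximately 1000" per scan
  expect_equal(nrow(g$positions), 1089L)

  g1 <- patch_grid(c(64L, 64L), 64L, stride = 10L)
  expect_equal(g1$positions, cbind(row = 1L, col = 1L))

  g2 <- patch_grid(c(256L, 256L), 64L, stride = 64L)
  expect_equal(nrow(g2$positions), 16L)
  ## non-overlapping tiling reassembles exactly
  img <- matrix(runif(256 * 256), 256)
  ep <- extract_patches(img, 64L, 64L)
  expect_identical(octapseudo:::reassemble_patches(ep$grid, ep$patches), img)

  ## count formula and full coverage on assorted sizes
  for (case in list(c(96, 128, 32), c(200, 150, 48), c(64, 300, 17))) {
    g <- patch_grid(case[1:2], 64L, stride = case[3])
    nexp <- (ceiling((case[1] - 64) / case[3]) + 1) *
            (ceiling((case[2] - 64) / case[3]) + 1)
    expect_equal(nrow(g$positions), nexp)
    cov <- matrix(FALSE, case[1], case[2])
    for (i in seq_len(nrow(g$positions))) {
      r <- g$positions[i, 1]; c <- g$positions[i, 2]
      cov[r:(r + 63), c:(c + 63)] <- TRUE
    }
    expect_true(all(cov))
  }
  expect_error(patch_grid(c(128, 128), 64, stride = 0), "positive")
  expect_error(patch_grid(c(32, 128), 64), "smaller")
})

test_that("network parameter count matches an independent hand count", {
  spec <- unet_spec(levels = 3, base_channels = 4)
  m <- build_unet(spec)
  ## hand count, layer by layer (channels 4-8-16):
  ## encoder: (1*9+1)*4 + (4*9+1)*4, (4*9+1)*8 + (8*9+1)*8, (8*9+1)*16 + (16*9+1)*16
  enc <- (1 * 9 + 1) * 4 + (4 * 9 + 1) * 4 +
         (4 * 9 + 1) * 8 + (8 * 9 + 1) * 8 +
         (8 * 9 + 1) * 16 + (16 * 9 + 1) * 16
  ## decoder level 2: 1x1 up 16->8, 3x3 16->8, 3x3 8->8
  ## decoder level 1: 1x1 up 8->4, 3x3 8->4, 3x3 4->4
  dec <- (16 * 1 + 1) * 8 + (16 * 9 + 1) * 8 + (8 * 9 + 1) * 8 +
         (8 * 1 + 1) * 4 + (8 * 9 + 1) * 4 + (4 * 9 + 1) * 4
  head <- 4 * 1 + 1
  expect_identical(m$n_params, as.numeric(enc + dec + head))
})

test_that("forward pass keeps shape and range and enforces divisibility", {
  m <- build_unet(unet_spec(), seed = 0)
  x <- matrix(runif(64 * 64), 64)
  y <- unet_forward(m, x)
  expect_equal(dim(y), c(64L, 64L, 1L))
  expect_true(all(y >= 0 & y <= 1))   # clamp head may sit exactly on a bound
  expect_error(unet_forward(m, matrix(0.5, 100, 100)), "divisible by 16")

  ## deterministic given the seed
  m2 <- build_unet(unet_spec(), seed = 0)
  expect_identical(unet_forward(m2, x), y)
})

test_that("an untrained network is near-identity and shift-equivariant", {
  m <- build_unet(unet_spec(), seed = 3)
  x <- octapseudo:::clip01(octapseudo:::smooth_field(128, 128, 3) * 0.8 + 0.1)
  y <- unet_forward(m, x)[, , 1]
  expect_lt(max(abs(y - x)), 0.05)

  ## shift by one full downsampling factor (16 px at levels = 5)
  xs <- rbind(x[17:128, ], x[1:16, ])        # cyclic row shift keeps content
  ys <- unet_forward(m, xs)[, , 1]
  interior <- 33:96
  expect_lt(max(abs(ys[interior - 16, interior] - y[interior, interior])), 0.05)
})
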