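test_that("CNR matches its closed form and invariances", {
  set.seed(2)
  img <- matrix(0, 200, 200)
  vm <- matrix(FALSE, 200, 200); vm[1:100, ] <- TRUE
  bm <- !vm
  img[vm] <- 1
  img <- img + matrix(rnorm(200 * 200, 0, 0.1), 200)
  v <- cnr(img, vm, bm)
  expect_equal(v, 10, tolerance = 0.05 * 10)          # (1 - 0) / 0.1

  ## identically distributed vessel and background: CNR ~ 0
  img2 <- matrix(rnorm(200 * 200, 0.5, 0.1), 200)
  expect_lt(abs(cnr(img2, vm, bm)), 0.05)

  ## translation invariance
  expect_equal(cnr(img + 0.05, vm, bm), v, tolerance = 1e-9)

  expect_error(cnr(img, vm, vm), "disjoint")
  flat <- matrix(0.5, 200, 200)
  expect_true(is.na(cnr(flat, vm, bm)))
})

test_that("perfusion artifact detectors flag constructed cases only", {
  ph <- fx_phantom(256)
  truth <- ph$perfusion

  expect_false(as.logical(fn_perfusion(ph, truth)))
  expect_false(as.logical(fp_perfusion(ph, truth)))

  ## erase one >= 30 px vessel component region
  lab <- EBImage::bwlabel(ph$vessel_mask * 1)
  sizes <- tabulate(as.integer(lab))
  big <- which(sizes >= 30)[1]
  erased <- truth; erased[as.integer(lab) == big] <- 0
  ## removing a component entirely erases >= 30 px of true vessels
  expect_true(as.logical(fn_perfusion(ph, erased)))

  ## tau monotonicity: flags are non-decreasing in tau
  dimmed <- truth * 0.4
  flags <- vapply(c(0.10, 0.15, 0.20),
                  function(tau) as.logical(fn_perfusion(ph, dimmed, tau = tau)),
                  logical(1))
  expect_true(all(diff(flags) >= 0))

  ## a bright blob wholly inside true background triggers the FP detector
  bg_idx <- which(ph$background_mask, arr.ind = TRUE)
  centre <- bg_idx[which.max(
    apply(bg_idx, 1, function(rc) sum(ph$background_mask[
      pmax(1, rc[1] - 3):pmin(256, rc[1] + 3),
      pmax(1, rc[2] - 3):pmin(256, rc[2] + 3)]))), ]
  blob <- truth
  rows <- pmax(1, centre[1] - 3):pmin(256, centre[1] + 3)
  cols <- pmax(1, centre[2] - 3):pmin(256, centre[2] + 3)
  sel <- ph$background_mask[rows, cols]
  if (sum(sel) >= 20) {
    blob[rows, cols][sel] <- 0.95
    expect_true(as.logical(fp_perfusion(ph, blob)))
  }
})

test_that("motion index reflects line artifacts exactly", {
  img <- matrix(0.2, 128, 128)
  expect_equal(motion_index(img, integer(0)), 0)
  img[50, ] <- 1.0
  expect_equal(motion_index(img, 50L), 0.8, tolerance = 1e-12)
})

test_that("FAZ contour continuity counts angular bins", {
  ph <- fx_phantom(256)
  expect_equal(faz_contour_continuity(ph$perfusion, ph), 1.0)
  expect_equal(faz_contour_continuity(matrix(0, 256, 256), ph), 0.0)

  ## zero a 30-degree arc aligned with the bin lattice: exactly 3 bins fail
  px <- ph$perfusion
  idx <- which(ph$ring_mask)
  r <- (idx - 1L) %% 256 + 1L; c <- (idx - 1L) %/% 256 + 1L
  ang <- atan2(r - ph$faz_center[1], c - ph$faz_center[2])
  bin <- floor((ang + pi) / (2 * pi) * 36)
  px[idx[bin %in% 6:8]] <- 0
  expect_equal(faz_contour_continuity(px, ph), 33 / 36)
})

test_that("Wilcoxon signed-rank matches exact enumeration and textbook cases", {
  ## all-positive differences 1..5: one-sided 1/32, two-sided 1/16
  w <- wilcoxon_signed_rank(1:5, alternative = "greater")
  expect_equal(w$statistic, 15)
  expect_equal(w$p.value, 1 / 32)
  expect_equal(wilcoxon_signed_rank(1:5)$p.value, 1 / 16)

  ## zero differences are dropped; < 5 retained pairs -> NA
  expect_true(is.na(wilcoxon_signed_rank(c(0, 0, 0, 1, 2, 3))$p.value))
  expect_true(is.na(wilcoxon_signed_rank(rep(0, 6))$p.value))

  ## oracle equivalence against full sign enumeration, n <= 10, with ties
  set.seed(42)
  for (i in 1:50) {
    n <- sample(5:10, 1)
    d <- sample(c(-4:-1, 1:4), n, replace = TRUE)   # ties guaranteed
    ours <- wilcoxon_signed_rank(d)
    ref <- brute_wilcoxon(d)
    expect_equal(ours$statistic, ref$statistic)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
  }

  ## cross-check against the standard implementation when ties are absent
  set.seed(7)
  for (i in 1:10) {
    d <- sample(seq(0.1, 9.9, by = 0.1), 12)
    d <- d * sample(c(-1, 1), 12, replace = TRUE)
    ours <- wilcoxon_signed_rank(d)
    ref <- suppressWarnings(stats::wilcox.test(d, exact = TRUE))
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-9)
  }

  ## large-sample normal path stays close to the standard implementation
  set.seed(9)
  d <- rnorm(40, mean = 0.3)
  ours <- wilcoxon_signed_rank(d)
  ref <- suppressWarnings(stats::wilcox.test(d, correct = TRUE, exact = FALSE))
  expect_false(ours$exact)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-6)
})

test_that("scan ranking mirrors the grading protocol", {
  set.seed(31)
  tab <- data.frame(
    eye = rep(sprintf("e%02d", 1:8), each = 3),
    variant = rep(c("original", "averaged", "pseudoaveraged"), 8),
    cnr = c(t(cbind(rnorm(8, 2), rnorm(8, 4), rnorm(8, 6)))))
  rk <- rank_scans(tab)
  expect_true(all(rk$ranks$rank >= 1 & rk$ranks$rank <= 3))
  best <- subset(rk$ranks, variant == "pseudoaveraged")
  expect_true(mean(best$rank) > 2.5)
  expect_equal(nrow(rk$tests), 3)        # three pairwise comparisons
  expect_true(all(rk$tests$n == 8))

  ## identical paired values -> all differences zero -> NA p-value
  tab2 <- data.frame(eye = rep(c("a", "b", "c", "d", "e"), each = 2),
                     variant = rep(c("x", "y"), 5), m = rep(1:5, each = 2))
  rk2 <- rank_scans(tab2)
  expect_true(is.na(rk2$tests$p.value))
})

test_that("cohort reporting is exact for a perfect denoiser stand-in", {
  ## identity model on clean scans: no artifact flags, metric shifts ~ 0
  fit <- fx_identity_model()
  eyes <- lapply(1:3, function(i) {
    ph <- generate_phantom(c(128, 128), "healthy", seed = 20 + i)
    list(phantom = ph,
         scan = render_single_frame(ph, noise_params(seed = i,
                                                     motion_line_rate = 0,
                                                     shadow_prob = 0)))
  })
  rep <- cohort_report(eyes, fit)
  expect_equal(rep$summary$pct_fn_flagged, 0)
  expect_equal(rep$summary$pct_fp_flagged, 0)
  expect_equal(rep$summary$n_with_motion_rows, 0L)
  expect_true(is.na(rep$summary$pct_motion_reduced))
  orig <- subset(rep$per_scan, variant == "original")
  pseu <- subset(rep$per_scan, variant == "pseudoaveraged")
  expect_lt(max(abs(orig$cnr - pseu$cnr)) / max(orig$cnr), 0.1)

  ## percentages recomputed from the emitted CSV equal the report's values
  csv <- withr::local_tempfile(fileext = ".csv")
  rep2 <- cohort_report(eyes, fit, out_csv = csv)
  tab <- read.csv(csv)
  o <- subset(tab, variant == "original"); p <- subset(tab, variant == "pseudoaveraged")
  expect_equal(100 * mean(p$cnr > o$cnr), rep2$summary$pct_cnr_improved)
  expect_equal(100 * mean(p$background_sigma < o$background_sigma),
               rep2$summary$pct_background_sigma_reduced)
  expect_true(all(tab$faz_contour >= 0 & tab$faz_contour <= 1))
})
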