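# Shared fixtures: everything is generated in code, no files.

# Small cached phantom / rendering used across files (computed once per run).
fixture_env <- new.env()

fx_phantom <- function(size = 128L, level = "npdr", seed = 7L) {
  key <- sprintf("ph_%d_%s_%d", size, level, seed)
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- generate_phantom(c(size, size), level, seed = seed)
  fixture_env[[key]]
}

# Identity training pairs cut from one clean rendering.
fx_identity_pairs <- function(size = 128L, stride = 32L) {
  ph <- fx_phantom(size, "healthy", seed = 5L)
  img <- render_single_frame(ph, noise_params(seed = 2, motion_line_rate = 0,
                                              shadow_prob = 0))
  ep <- extract_patches(img, 64L, stride)
  lapply(seq_len(dim(ep$patches)[3]), function(i)
    structure(list(input = ep$patches[, , i], target = ep$patches[, , i],
                   mask = matrix(TRUE, 64, 64), kind = "single_to_average",
                   source_eye = "fx"), class = "training_pair"))
}

# A small identity-trained model reused by inference tests.
fx_identity_model <- function() {
  if (is.null(fixture_env$id_model)) {
    fixture_env$id_model <- fit_pseudoaverager(
      fx_identity_pairs(), unet_spec(levels = 3L, base_channels = 8L),
      train_config(epochs = 30L, learning_rate = 0.02, momentum = 0.5,
                   seed = 1L))
  }
  fixture_env$id_model
}

# Brute-force Wilcoxon signed-rank null: enumerate all 2^n sign assignments.
brute_wilcoxon <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- signs %*% r
  p_ge <- mean(vs >= v - 1e-9)
  p_le <- mean(vs <= v + 1e-9)
  p <- switch(alternative,
              two.sided = min(1, 2 * min(p_ge, p_le)),
              greater = p_ge, less = p_le)
  list(statistic = v, p.value = p)
}
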