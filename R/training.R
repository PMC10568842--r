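#' Training pairs for the pseudoaveraging denoiser
#'
#' `make_single_to_average_pairs()` cuts a registered (single frame,
#' averaged frame) scan pair into patch pairs on a [patch_grid()].
#' An optional artifact mask marks target regions that must not act as
#' training targets (residual motion lines, shadowed areas of the average);
#' the mask restricts the loss only - masked pixels still enter the network
#' input. Pairs whose validity mask is entirely false are dropped.
#'
#' `make_peer_to_peer_pairs()` builds pairs from a low-quality and a
#' high-quality single frame of the same eye (both registered to a common
#' reference). The quality ordering is enforced with [quality_score()];
#' peer-to-peer pairs teach the denoiser to raise low-signal but perfused
#' regions instead of erasing them (false-negative perfusion safety).
#'
#' @param single,averaged,low_quality,high_quality Same-shape
#'   [enface_image()]s or matrices.
#' @param artifact_mask Optional logical matrix, `TRUE` where the target is
#'   valid (all-valid if absent).
#' @param grid A [patch_grid()] for the scan shape.
#' @param source_eye Eye label carried on each pair.
#' @return List of `training_pair` objects: `input`, `target`, `mask`
#'   (patch-size matrices), `kind`, `source_eye`.
#' @export
make_single_to_average_pairs <- function(single, averaged, artifact_mask = NULL,
                                         grid = patch_grid(single, stride = 64L),
                                         source_eye = "eye") {
  inp <- as_pixels(single); tgt <- as_pixels(averaged)
  if (!all(dim(inp) == dim(tgt)))
    stop("input and target scans must have the same shape", call. = FALSE)
  if (is.null(artifact_mask)) artifact_mask <- matrix(TRUE, nrow(inp), ncol(inp))
  if (!all(dim(artifact_mask) == dim(inp)))
    stop("artifact mask shape mismatch", call. = FALSE)
  cut_pairs(inp, tgt, artifact_mask, grid, "single_to_average", source_eye)
}

#' @rdname make_single_to_average_pairs
#' @export
make_peer_to_peer_pairs <- function(low_quality, high_quality,
                                    grid = patch_grid(low_quality, stride = 64L),
                                    artifact_mask = NULL,
                                    source_eye = "eye") {
  if (quality_score(low_quality) >= quality_score(high_quality))
    stop(paste("peer-to-peer pairs need quality_score(low_quality) <",
               "quality_score(high_quality); swap the arguments?"),
         call. = FALSE)
  inp <- as_pixels(low_quality); tgt <- as_pixels(high_quality)
  if (!all(dim(inp) == dim(tgt)))
    stop("input and target scans must have the same shape", call. = FALSE)
  if (is.null(artifact_mask)) artifact_mask <- matrix(TRUE, nrow(inp), ncol(inp))
  cut_pairs(inp, tgt, artifact_mask, grid, "peer_to_peer", source_eye)
}

cut_pairs <- function(inp, tgt, mask, grid, kind, source_eye) {
  p <- grid$patch_size
  out <- vector("list", nrow(grid$positions))
  for (i in seq_len(nrow(grid$positions))) {
    r <- grid$positions[i, 1]; c <- grid$positions[i, 2]
    m <- mask[r:(r + p - 1L), c:(c + p - 1L)]
    if (!any(m)) next                     # all-false pairs are dropped
    out[[i]] <- structure(list(
      input = inp[r:(r + p - 1L), c:(c + p - 1L)],
      target = tgt[r:(r + p - 1L), c:(c + p - 1L)],
      mask = m, kind = kind, source_eye = source_eye),
      class = "training_pair")
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Masked L1 loss
#'
#' Mean absolute difference over the valid pixels only. The cost function
#' of the denoiser: an L1 norm of the difference with the target, restricted
#' to unmasked target regions.
#'
#' @param pred,target Same-shape numeric matrices.
#' @param valid_mask Logical matrix; must contain at least one `TRUE` pixel.
#' @return Non-negative scalar.
#' @export
masked_l1_loss <- function(pred, target, valid_mask = NULL) {
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, nrow(pred), ncol(pred))
  if (!all(dim(pred) == dim(target)) || !all(dim(pred) == dim(valid_mask)))
    stop("shapes of pred, target and valid_mask must agree", call. = FALSE)
  if (!any(valid_mask))
    stop("valid_mask has no TRUE pixels", call. = FALSE)
  mean(abs(pred - target)[valid_mask])
}

#' Training configuration
#'
#' Defaults chosen to converge on the synthetic study set within a
#' desk-scale run: plain SGD with momentum, masked-L1 cost.
#'
#' @param learning_rate SGD step size, > 0.
#' @param momentum Momentum coefficient in `[0, 1)`.
#' @param epochs Number of passes over the pair set, >= 1.
#' @param batch_size Mini-batch size.
#' @param seed Seed controlling shuffling, augmentation and (with the model
#'   seed) the full run: identical config + seed gives identical weights.
#' @param augmentations Character subset of `c("hflip", "vflip", "rot90")`.
#'   When enabled, every pair appears once per epoch under each element of
#'   the dihedral subgroup the selection generates (up to 8 variants).
#' @param p2p_ratio Peer-to-peer pairs drawn per epoch, as a fraction of the
#'   single-to-average pair count (default 1:4 mixing; 0 disables).
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.05, momentum = 0.9, epochs = 20L,
                         batch_size = 32L, seed = 0L,
                         augmentations = character(0), p2p_ratio = 0.25) {
  stopifnot_scalar(learning_rate, "learning_rate", lo = 1e-12)
  stopifnot_scalar(momentum, "momentum", lo = 0, hi = 1 - 1e-9)
  if (epochs < 1L) stop("'epochs' must be >= 1", call. = FALSE)
  bad <- setdiff(augmentations, c("hflip", "vflip", "rot90"))
  if (length(bad) > 0)
    stop("unknown augmentations: ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(optimizer = "sgd", learning_rate = learning_rate,
                 momentum = momentum, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 augmentations = augmentations, p2p_ratio = p2p_ratio),
            class = "train_config")
}

# D4 codes generated by the selected augmentations (0 = identity;
# bit 1 = hflip, bit 2 = vflip, bit 4 = transpose).
augment_codes <- function(augmentations) {
  gens <- c(0L)
  if ("hflip" %in% augmentations) gens <- c(gens, 1L)
  if ("vflip" %in% augmentations) gens <- c(gens, 2L)
  if ("rot90" %in% augmentations) gens <- c(gens, 5L)  # transpose + hflip
  # close the generated subgroup of D4 (composition on codes)
  comp <- function(a, b) {
    # apply a then b, both in (transpose, hflip, vflip) encoding
    m <- diag(2)[, , drop = FALSE]
    apply_code <- function(code, state) {
      # state: permutation+flips as 2x2 signed permutation matrix
      t_m <- if (bitwAnd(code, 4L)) matrix(c(0, 1, 1, 0), 2) else diag(2)
      f_m <- diag(c(if (bitwAnd(code, 1L)) -1 else 1,
                    if (bitwAnd(code, 2L)) -1 else 1))
      f_m %*% t_m %*% state
    }
    s <- apply_code(b, apply_code(a, diag(2)))
    # decode back to a code
    for (code in 0:7) {
      if (identical(apply_code(code, diag(2)), s)) return(code)
    }
    stop("unreachable")
  }
  set <- gens
  repeat {
    new <- unique(c(set, as.integer(outer(set, set, Vectorize(comp)))))
    if (length(new) == length(set)) break
    set <- new
  }
  sort(set)
}

#' Fit the pseudoaveraging denoiser
#'
#' Trains the patch U-Net with stochastic gradient descent on a masked-L1
#' cost over single-to-average (and optionally peer-to-peer) training
#' pairs. Pair order is reshuffled every epoch; when `p2p_ratio > 0` and
#' peer-to-peer pairs exist, each epoch mixes in a freshly drawn sample of
#' them sized `p2p_ratio` times the single-to-average count. The whole run
#' is a deterministic function of the pairs, spec and config.
#'
#' @param pairs List of `training_pair`s (see
#'   [make_single_to_average_pairs()]); at least one.
#' @param spec A [unet_spec()].
#' @param config A [train_config()].
#' @return Object of class `pseudoaverager` (inherits `octa_unet`):
#'   `layers` (trained weights), `spec`, `config`, `loss_history` (mean
#'   masked L1 per epoch), `n_pairs`, `pair_kinds`, `n_params`.
#' @seealso [predict.pseudoaverager()] for tiled whole-scan inference.
#' @export
fit_pseudoaverager <- function(pairs, spec = unet_spec(),
                               config = train_config()) {
  if (length(pairs) < 1L) stop("no training pairs supplied", call. = FALSE)
  kinds <- vapply(pairs, `[[`, character(1), "kind")
  p <- nrow(pairs[[1]]$input)
  check_divisible(p, p, spec)

  n <- length(pairs)
  inputs <- array(0, c(p, p, n)); targets <- array(0, c(p, p, n))
  masks <- array(0, c(p, p, n))
  for (i in seq_len(n)) {
    inputs[, , i] <- pairs[[i]]$input
    targets[, , i] <- pairs[[i]]$target
    masks[, , i] <- pairs[[i]]$mask * 1
  }

  i_s2a <- which(kinds == "single_to_average")
  i_p2p <- which(kinds == "peer_to_peer")
  if (length(i_s2a) == 0L) i_s2a <- seq_len(n)   # p2p-only corpus: use all
  codes <- augment_codes(config$augmentations)

  sched <- with_seed(config$seed, {
    lapply(seq_len(config$epochs), function(e) {
      idx <- i_s2a
      if (length(i_p2p) > 0L && config$p2p_ratio > 0) {
        n_draw <- ceiling(config$p2p_ratio * length(i_s2a))
        idx <- c(idx, sample(i_p2p, n_draw, replace = n_draw > length(i_p2p)))
      }
      idx <- rep(idx, each = length(codes))
      aug <- rep(codes, times = length(idx) / length(codes))
      o <- sample.int(length(idx))
      list(idx = as.integer(idx[o]), aug = as.integer(aug[o]))
    })
  })

  model <- build_unet(spec, seed = config$seed)
  t0 <- proc.time()[["elapsed"]]
  res <- cpp_unet_train(model$layers, spec$channels, inputs, targets, masks,
                        lapply(sched, `[[`, "idx"), lapply(sched, `[[`, "aug"),
                        config$learning_rate, config$momentum,
                        config$batch_size,
                        identical(spec$residual_head, "logit") == FALSE)
  structure(list(spec = spec, layers = res$layers, config = config,
                 loss_history = as.numeric(res$loss),
                 n_pairs = n, pair_kinds = table(kinds),
                 n_params = model$n_params, init_seed = model$init_seed,
                 elapsed_s = proc.time()[["elapsed"]] - t0),
            class = c("pseudoaverager", "octa_unet"))
}

#' @export
print.pseudoaverager <- function(x, ...) {
  cat(sprintf("Pseudoaveraging U-Net denoiser (%d levels, %d parameters)\n",
              x$spec$levels, x$n_params))
  cat(sprintf("  trained on %d pairs (%s), %d epochs of SGD (lr %.3g, momentum %.2g)\n",
              x$n_pairs,
              paste(sprintf("%s: %d", names(x$pair_kinds), x$pair_kinds),
                    collapse = ", "),
              x$config$epochs, x$config$learning_rate, x$config$momentum))
  cat(sprintf("  masked L1: %.4f (first epoch) -> %.4f (final epoch)\n",
              x$loss_history[1], x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' @export
summary.pseudoaverager <- function(object, ...) {
  print(object)
  cat(sprintf("  loss history: %s\n",
              paste(sprintf("%.4f", object$loss_history), collapse = " ")))
  cat(sprintf("  training time: %.1f s\n", object$elapsed_s))
  invisible(object)
}

#' @export
plot.pseudoaverager <- function(x, ...) {
  graphics::plot(seq_along(x$loss_history), x$loss_history, type = "b",
                 xlab = "epoch", ylab = "mean masked L1",
                 main = "Pseudoaverager training loss", ...)
  invisible(x)
}

#' @export
coef.pseudoaverager <- function(object, ...) object$layers
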