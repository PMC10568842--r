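#' U-Net architecture specification
#'
#' A symmetric encoder-decoder ("U") convolutional network with `levels`
#' resolution levels, two 3x3 convolutions per level, 2x2 max-pool
#' downsampling, nearest-neighbour + 1x1-conv upsampling, skip
#' concatenation at every level, and a final 1x1 convolution head whose
#' output is clamped (or sigmoid-squashed) to `[0, 1]`. Channel width
#' doubles per level from `base_channels`. The head predicts a *correction*
#' added to the input (a global residual path) and is initialized near
#' zero, so the untrained network starts close to the identity map: the
#' denoiser learns deviations from the input rather than the image itself,
#' which preserves brightness and biases it against erasing low-signal
#' perfusion. With `residual_head = "linear"` (default) the output is
#' `clamp(input + g, 0, 1)`; with `"logit"` it is
#' `sigmoid(logit(input) + g)`.
#'
#' A "5-layer" U-Net is read here as 5 resolution levels (the standard
#' Ronneberger-style depth); with `levels = 5` the input sides must be
#' divisible by `2^(levels-1) = 16`, which holds for the 64 x 64 patches
#' the denoiser trains on.
#'
#' @param levels Number of resolution levels (default 5).
#' @param base_channels Channel width of the first level (default 16).
#' @param convs_per_level Convolutions per level; the compiled kernels
#'   implement the standard choice of 2.
#' @param residual_head `"linear"` (clamp) or `"logit"` (sigmoid) form of
#'   the global residual output stage.
#' @return An object of class `unet_spec`.
#' @export
unet_spec <- function(levels = 5L, base_channels = 16L, convs_per_level = 2L,
                      residual_head = c("linear", "logit")) {
  levels <- as.integer(levels); base_channels <- as.integer(base_channels)
  residual_head <- match.arg(residual_head)
  if (levels < 2L) stop("'levels' must be >= 2", call. = FALSE)
  if (base_channels < 1L) stop("'base_channels' must be >= 1", call. = FALSE)
  if (convs_per_level != 2L)
    stop("the compiled kernels implement convs_per_level = 2", call. = FALSE)
  structure(list(levels = levels, base_channels = base_channels,
                 convs_per_level = 2L, residual_head = residual_head,
                 channels = base_channels * 2L^(0:(levels - 1L))),
            class = "unet_spec")
}

#' @export
print.unet_spec <- function(x, ...) {
  cat(sprintf("<unet_spec> %d levels, channels %s; input sides must be divisible by %d\n",
              x$levels, paste(x$channels, collapse = "-"), 2^(x$levels - 1)))
  invisible(x)
}

# Layer dimensions in the order the compiled kernels expect
# (encoder convs, then up/decA/decB per decoder level, then the 1x1 head).
unet_layer_dims <- function(spec) {
  ch <- spec$channels; L <- spec$levels
  cin <- integer(0); cout <- integer(0); k <- integer(0)
  for (i in seq_len(L)) {
    cin <- c(cin, if (i == 1L) 1L else ch[i - 1L], ch[i])
    cout <- c(cout, ch[i], ch[i]); k <- c(k, 3L, 3L)
  }
  for (i in seq(L - 1L, 1L)) {
    cin <- c(cin, ch[i + 1L], 2L * ch[i], ch[i])
    cout <- c(cout, ch[i], ch[i], ch[i]); k <- c(k, 1L, 3L, 3L)
  }
  cin <- c(cin, ch[1L]); cout <- c(cout, 1L); k <- c(k, 1L)
  data.frame(cin = cin, cout = cout, k = k)
}

#' Build an (untrained) U-Net model
#'
#' Weights are He-initialized (final residual head near-zero, all biases
#' zero) from the given seed; the parameter count is a deterministic
#' function of the spec.
#'
#' @param spec A [unet_spec()].
#' @param seed Integer seed for the weight initialization.
#' @return An object of class `octa_unet` with elements `spec`, `layers`
#'   (list of `W` (cin*k*k x cout) / `b` pairs) and `n_params`.
#' @export
build_unet <- function(spec = unet_spec(), seed = 0L) {
  stopifnot(inherits(spec, "unet_spec"))
  dims <- unet_layer_dims(spec)
  layers <- with_seed(seed, {
    lapply(seq_len(nrow(dims)), function(l) {
      fan_in <- dims$cin[l] * dims$k[l]^2
      ## residual head: near-zero init keeps the fresh network close to the
      ## identity map while leaving a gradient path into the encoder
      sd <- if (l == nrow(dims)) 0.03 * sqrt(1 / fan_in) else sqrt(2 / fan_in)
      list(W = matrix(stats::rnorm(fan_in * dims$cout[l], 0, sd),
                      fan_in, dims$cout[l]),
           b = numeric(dims$cout[l]))
    })
  })
  structure(list(spec = spec, layers = layers,
                 n_params = sum(dims$cin * dims$k^2 * dims$cout + dims$cout),
                 init_seed = as.integer(seed)),
            class = "octa_unet")
}

#' @export
print.octa_unet <- function(x, ...) {
  cat(sprintf("<octa_unet> %d levels, base %d channels, %d parameters\n",
              x$spec$levels, x$spec$base_channels, x$n_params))
  invisible(x)
}

check_divisible <- function(h, w, spec) {
  f <- 2L^(spec$levels - 1L)
  if (h %% f != 0L || w %% f != 0L)
    stop(sprintf(paste0("input size %d x %d is not divisible by %d ",
                        "(= 2^(levels-1) for levels = %d); pad or crop the input"),
                 h, w, f, spec$levels), call. = FALSE)
  invisible(TRUE)
}

#' Run a U-Net forward over a batch of images
#'
#' @param model An `octa_unet` (or fitted `pseudoaverager`).
#' @param x Numeric matrix `H x W` or array `H x W x N`; `H` and `W` must be
#'   divisible by `2^(levels-1)`.
#' @return Array of the same shape with values in `(0, 1)`.
#' @export
unet_forward <- function(model, x) {
  stopifnot(inherits(model, "octa_unet"))
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  check_divisible(dim(x)[1], dim(x)[2], model$spec)
  cpp_unet_forward(model$layers, model$spec$channels, x,
                   identical(model$spec$residual_head, "logit") == FALSE)
}
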