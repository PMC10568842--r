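#' Patch grid over an image
#'
#' Top-left patch positions on a stride lattice, with a final row/column of
#' positions snapped to the image edge so the union of patches covers every
#' pixel. The number of positions per dimension is
#' `ceiling((D - patch_size) / stride) + 1`.
#'
#' The default stride is 14 for 500 x 500 scans (giving 32 x 32 = 1024
#' patches, about a thousand per scan) and `patch_size / 4` otherwise.
#'
#' @param dim_hw Integer `c(H, W)`, or an [enface_image()]/matrix whose
#'   dimensions are used.
#' @param patch_size Patch side in pixels (default 64).
#' @param stride Lattice stride in pixels, > 0.
#' @return Object of class `patch_grid`: list with `positions` (n x 2 matrix
#'   of 1-based top-left `(row, col)`, sorted row-major), `patch_size`,
#'   `stride`, `dim`.
#' @export
patch_grid <- function(dim_hw, patch_size = 64L, stride = NULL) {
  if (inherits(dim_hw, "enface_image") || is.matrix(dim_hw))
    dim_hw <- dim(as_pixels(dim_hw))
  dim_hw <- as.integer(dim_hw)
  patch_size <- as.integer(patch_size)
  if (any(dim_hw < patch_size))
    stop("image smaller than the patch size", call. = FALSE)
  if (is.null(stride))
    stride <- if (all(dim_hw == 500L)) 14L else max(1L, patch_size %/% 4L)
  stride <- as.integer(stride)
  if (stride <= 0L) stop("'stride' must be positive", call. = FALSE)
  starts <- function(d) {
    s <- seq.int(1L, d - patch_size + 1L, by = stride)
    if (s[length(s)] != d - patch_size + 1L) s <- c(s, d - patch_size + 1L)
    s
  }
  rs <- starts(dim_hw[1]); cs <- starts(dim_hw[2])
  positions <- cbind(row = rep(rs, each = length(cs)),
                     col = rep(cs, times = length(rs)))
  structure(list(positions = positions, patch_size = patch_size,
                 stride = stride, dim = dim_hw),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("<patch_grid> %d patches of %d px (stride %d) over %d x %d\n",
              nrow(x$positions), x$patch_size, x$stride, x$dim[1], x$dim[2]))
  invisible(x)
}

#' Extract patches from an image
#'
#' @param image An [enface_image()] or matrix.
#' @inheritParams patch_grid
#' @return List with the [patch_grid()] and `patches`, an array
#'   `patch_size x patch_size x n`.
#' @export
extract_patches <- function(image, patch_size = 64L, stride = NULL) {
  px <- as_pixels(image)
  grid <- patch_grid(dim(px), patch_size, stride)
  n <- nrow(grid$positions); p <- grid$patch_size
  patches <- array(0, c(p, p, n))
  for (i in seq_len(n)) {
    r <- grid$positions[i, 1]; c <- grid$positions[i, 2]
    patches[, , i] <- px[r:(r + p - 1L), c:(c + p - 1L)]
  }
  list(grid = grid, patches = patches)
}

# Reassemble patches on a grid (used by tests; exact when stride == size).
reassemble_patches <- function(grid, patches) {
  out <- matrix(0, grid$dim[1], grid$dim[2])
  p <- grid$patch_size
  for (i in seq_len(nrow(grid$positions))) {
    r <- grid$positions[i, 1]; c <- grid$positions[i, 2]
    out[r:(r + p - 1L), c:(c + p - 1L)] <- patches[, , i]
  }
  out
}
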