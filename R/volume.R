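#' Volume stack container
#'
#' A `VolumeStack` is a 3D grid of fluorescence intensities indexed
#' `[z, y, x]` (0-based voxel coordinates in all user-facing output)
#' together with its physical voxel size in micrometres and a channel tag.
#'
#' @param voxels numeric 3D array indexed `[z, y, x]`; finite intensities.
#' @param voxel_size numeric length-3, micrometres per voxel along
#'   `(z, y, x)`; all entries must be positive.
#' @param channel character scalar channel tag (e.g. `"ribbon"`, `"psd"`).
#'
#' @return An object of class `VolumeStack`: a list with elements
#'   `voxels`, `voxel_size`, `channel`.
#' @examples
#' vs <- volume_stack(array(0, c(4, 8, 8)), c(0.3, 0.05, 0.05), "ribbon")
#' dim(vs$voxels)
#' @export
volume_stack <- function(voxels, voxel_size, channel = "unknown") {
  if (length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3D array indexed [z, y, x]")
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("'voxel_size' must be 3 positive values (z, y, x) in um")
  if (any(!is.finite(voxels)))
    stop("'voxels' must contain only finite intensities")
  structure(list(voxels = voxels,
                 voxel_size = as.numeric(voxel_size),
                 channel = as.character(channel)[1]),
            class = "VolumeStack")
}

#' @export
print.VolumeStack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("VolumeStack [%s]: %d x %d x %d voxels (z,y,x), voxel %s um\n",
              x$channel, d[1], d[2], d[3],
              paste(signif(x$voxel_size, 3), collapse = " x ")))
  invisible(x)
}

#' Maximum-intensity projection along z
#'
#' @param stack a `VolumeStack` or a 3D array indexed `[z, y, x]`.
#' @return A `[y, x]` matrix of per-pixel maxima.
#' @export
max_project <- function(stack) {
  v <- if (inherits(stack, "VolumeStack")) stack$voxels else stack
  apply(v, c(2, 3), max)
}

# ---- internal image primitives ----------------------------------------

# 1D Gaussian kernel, truncated at 3 sigma, normalized to sum 1.
.gauss_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# 2D Gaussian smoothing with replicate borders.  Uses EBImage::filter2
# (FFT) when the kernel fits inside the image, otherwise a direct
# separable convolution that works for arbitrarily small images.
.gauss2d <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k1 <- .gauss_kernel1d(sigma)
  n <- length(k1)
  if (all(dim(img) > n)) {
    k2 <- outer(k1, k1)
    return(EBImage::filter2(img, k2, boundary = "replicate"))
  }
  r <- (n - 1L) %/% 2L
  pad_idx <- function(len) pmin(pmax(seq(1L - r, len + r), 1L), len)
  p <- img[pad_idx(nrow(img)), , drop = FALSE]
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_len(n))                       # rows
    out <- out + k1[i] * p[seq_len(nrow(img)) + (i - 1L), , drop = FALSE]
  p <- out[, pad_idx(ncol(img)), drop = FALSE]
  out2 <- matrix(0, nrow(img), ncol(img))
  for (i in seq_len(n))                       # columns
    out2 <- out2 + k1[i] * p[, seq_len(ncol(img)) + (i - 1L), drop = FALSE]
  out2
}

# Per-slice 2D Gaussian smoothing of a [z,y,x] array.
.gauss_slices <- function(vol, sigma) {
  for (z in seq_len(dim(vol)[1]))
    vol[z, , ] <- .gauss2d(vol[z, , ], sigma)
  vol
}

# Otsu threshold from a 256-bin histogram of values in [lo, hi].
.otsu <- function(x, n_bins = 256L) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(lo)
  h <- tabulate(pmin(as.integer((x - lo) / (hi - lo) * n_bins) + 1L, n_bins),
                nbins = n_bins)
  p <- h / sum(h)
  mids <- lo + (seq_len(n_bins) - 0.5) * (hi - lo) / n_bins
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  ok <- w0 > 0 & w1 > 0
  between <- rep(-Inf, n_bins)
  between[ok] <- (mu_t * w0[ok] - mu[ok])^2 / (w0[ok] * w1[ok])
  mids[which.max(between)]
}

# Chebyshev (box) max filter of half-width r along each axis of a 3D
# array, computed separably with shifted pmax.
.maxfilter3d <- function(vol, r) {
  d <- dim(vol)
  shift_max <- function(v, axis) {
    out <- v
    for (s in seq_len(r)) {
      n <- d[axis]
      idx_f <- c(seq_len(n - s) + s, rep(n, s))   # pull from +s, clamp
      idx_b <- c(rep(1L, s), seq_len(n - s))      # pull from -s, clamp
      out <- switch(axis,
        pmax(out, v[idx_f, , , drop = FALSE], v[idx_b, , , drop = FALSE]),
        pmax(out, v[, idx_f, , drop = FALSE], v[, idx_b, , drop = FALSE]),
        pmax(out, v[, , idx_f, drop = FALSE], v[, , idx_b, drop = FALSE]))
    }
    out
  }
  for (ax in 1:3) vol <- shift_max(vol, ax)
  vol
}
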