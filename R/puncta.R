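#' Segmentation parameters for punctum detection
#'
#' Bundles the tunable parameters of the morphology pipeline: rolling-ball
#' radius for background subtraction, the band-pass pixel band used on the
#' postsynaptic channel, the binarization rule applied to the
#' intensity-normalized stack, the minimum separation of watershed seeds,
#' and the per-channel minimum 2D area filter (ribbon 0.08 um^2, PSD
#' 0.04 um^2 by convention).
#'
#' @param rolling_ball_radius background ball radius in pixels.
#' @param bandpass_small,bandpass_large band-pass feature band in pixels
#'   (structures smaller than `bandpass_small` or larger than
#'   `bandpass_large` are suppressed); `bandpass_small < bandpass_large`.
#' @param threshold_method `"otsu"` for an automatic threshold on the
#'   min-max normalized stack, or a number in (0, 1) used as an absolute
#'   threshold on that normalized scale.
#' @param maxima_min_distance minimum Chebyshev separation (voxels) of the
#'   local maxima that seed the watershed; `NULL` derives it from
#'   `min_area` (expected punctum diameter in pixels) at segmentation time.
#' @param min_area minimum projected 2D area in um^2 (inclusive) for
#'   [apply_min_area()]; 0 disables the filter.
#'
#' @return A list of class `SegmentationParams`.
#' @export
segmentation_params <- function(rolling_ball_radius = 50,
                                bandpass_small = 6,
                                bandpass_large = 20,
                                threshold_method = "otsu",
                                maxima_min_distance = NULL,
                                min_area = 0) {
  if (bandpass_small >= bandpass_large)
    stop("'bandpass_small' must be smaller than 'bandpass_large'")
  if (bandpass_small <= 0)
    stop("band-pass sizes must be positive")
  if (min_area < 0) stop("'min_area' must be >= 0")
  if (is.numeric(threshold_method)) {
    if (threshold_method <= 0 || threshold_method >= 1)
      stop("absolute 'threshold_method' must lie in (0, 1)")
  } else if (!identical(threshold_method, "otsu")) {
    stop("'threshold_method' must be \"otsu\" or a number in (0, 1)")
  }
  structure(list(rolling_ball_radius = rolling_ball_radius,
                 bandpass_small = bandpass_small,
                 bandpass_large = bandpass_large,
                 threshold_method = threshold_method,
                 maxima_min_distance = maxima_min_distance,
                 min_area = min_area),
            class = "SegmentationParams")
}

# ---- rolling-ball background ------------------------------------------

# Height profile of a ball of the given radius: (2r+1)^2 matrix, NA
# outside the circular support.
.ball_height <- function(radius) {
  w <- seq(-radius, radius)
  d2 <- outer(w^2, w^2, "+")
  h <- sqrt(pmax(radius^2 - d2, 0))
  h[d2 > radius^2] <- NA
  h
}

# Grayscale erosion/dilation with a non-flat structuring element,
# replicate borders.
.morph_nonflat <- function(m, se, dilate = FALSE) {
  r <- (nrow(se) - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  pi <- pmin(pmax(seq(1L - r, nr + r), 1L), nr)
  pj <- pmin(pmax(seq(1L - r, nc + r), 1L), nc)
  mp <- m[pi, pj, drop = FALSE]
  acc <- matrix(if (dilate) -Inf else Inf, nr, nc)
  for (a in seq_len(nrow(se))) {
    for (b in seq_len(ncol(se))) {
      h <- se[a, b]
      if (is.na(h)) next
      sub <- mp[a:(a + nr - 1L), b:(b + nc - 1L), drop = FALSE]
      acc <- if (dilate) pmax(acc, sub + h) else pmin(acc, sub - h)
    }
  }
  acc
}

# Block-minimum downsampling by integer factor s (edge-replicated).
.block_min <- function(m, s) {
  nr <- nrow(m); nc <- ncol(m)
  nr2 <- ceiling(nr / s); nc2 <- ceiling(nc / s)
  ri <- pmin(seq_len(nr2 * s), nr)
  ci <- pmin(seq_len(nc2 * s), nc)
  mp <- m[ri, ci, drop = FALSE]
  a <- array(mp, c(s, nr2, s, nc2))
  apply(a, c(2, 4), min)
}

.upsample_bilinear <- function(m, nr, nc, s) {
  rpos <- (seq_len(nr) - 0.5) / s + 0.5
  cpos <- (seq_len(nc) - 0.5) / s + 0.5
  up <- apply(m, 2, function(col)
    stats::approx(seq_along(col), col, xout = rpos, rule = 2)$y)
  up <- matrix(up, nrow = nr)
  t(apply(up, 1, function(row)
    stats::approx(seq_along(row), row, xout = cpos, rule = 2)$y))
}

# Rolling-ball background of one slice: grayscale opening with a ball
# structuring element, computed on a block-min downsampled grid for
# large radii (the ball is correspondingly shrunk) and interpolated back.
.rolling_ball_bg <- function(slice, radius) {
  s <- max(1L, as.integer(radius) %/% 10L)
  red <- if (s > 1L) .block_min(slice, s) else slice
  se <- .ball_height(max(1L, round(radius / s)))
  bg <- .morph_nonflat(.morph_nonflat(red, se, dilate = FALSE), se,
                       dilate = TRUE)
  if (s > 1L) bg <- .upsample_bilinear(bg, nrow(slice), ncol(slice), s)
  pmin(bg, slice)
}

#' Rolling-ball background subtraction
#'
#' Removes slowly varying background from each z-slice by grayscale
#' opening with a ball structuring element of the given radius (the
#' classic rolling-ball estimate) and subtracting the resulting
#' background. Output intensities are non-negative; a constant slice maps
#' to zero and a planar gradient is removed.
#'
#' @param stack a [volume_stack()].
#' @param radius ball radius in pixels; must be at least 1 and no larger
#'   than the slice.
#' @return A `VolumeStack` with the background removed.
#' @export
subtract_background <- function(stack, radius = 50) {
  stopifnot(inherits(stack, "VolumeStack"))
  if (radius < 1) stop("'radius' must be >= 1 pixel")
  d <- dim(stack$voxels)
  if (radius > min(d[2], d[3]))
    stop(sprintf("rolling-ball radius %d exceeds slice size %d x %d",
                 as.integer(radius), d[2], d[3]))
  v <- stack$voxels
  for (z in seq_len(d[1]))
    v[z, , ] <- stack$voxels[z, , ] - .rolling_ball_bg(stack$voxels[z, , ],
                                                      radius)
  stack$voxels <- pmax(v, 0)
  stack
}

#' Band-pass filter (difference of Gaussians)
#'
#' Suppresses structures smaller than `small` pixels and larger than
#' `large` pixels in every z-slice, using a difference of Gaussians with
#' `sigma = size / 2.355` (FWHM-matched). The mean response to a constant
#' image is ~0.
#'
#' @param stack a [volume_stack()].
#' @param small,large feature band in pixels, `small < large`, both > 0.
#' @return A filtered `VolumeStack` (values may be negative).
#' @export
bandpass <- function(stack, small = 6, large = 20) {
  stopifnot(inherits(stack, "VolumeStack"))
  if (small <= 0 || large <= 0) stop("band-pass sizes must be positive")
  if (small >= large) stop("'small' must be less than 'large'")
  s1 <- small / 2.355
  s2 <- large / 2.355
  v <- stack$voxels
  for (z in seq_len(dim(v)[1])) {
    sl <- stack$voxels[z, , ]
    v[z, , ] <- .gauss2d(sl, s1) - .gauss2d(sl, s2)
  }
  stack$voxels <- v
  stack
}

# ---- seeded 3D watershed ----------------------------------------------

# Seeded watershed by descending-intensity flooding over a foreground
# mask (26-connectivity).  Voxels are visited from brightest to dimmest;
# an unlabeled voxel takes the label of its brightest already-labeled
# neighbor, so basins grow downhill from the seeds.  Foreground
# components containing no seed start a fresh label at their brightest
# voxel, which makes the flood a superset of connected-component
# labeling.
.watershed_flood <- function(intensity, mask, seed_idx) {
  d <- dim(intensity)
  pd <- d + 2L
  pv <- array(-Inf, pd)
  pm <- array(FALSE, pd)
  core_z <- 2:(pd[1] - 1L); core_y <- 2:(pd[2] - 1L); core_x <- 2:(pd[3] - 1L)
  pv[core_z, core_y, core_x] <- intensity
  pm[core_z, core_y, core_x] <- mask
  # map original linear index -> padded linear index
  to_pad <- function(idx) {
    co <- arrayInd(idx, d)
    (co[, 1] + 1L) + pd[1] * ((co[, 2]) + pd[2] * (co[, 3]))
  }
  lab <- integer(prod(pd))
  n_seed <- length(seed_idx)
  if (n_seed > 0) lab[to_pad(seed_idx)] <- seq_len(n_seed)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  noffs <- offs[, 1] + pd[1] * (offs[, 2] + pd[2] * offs[, 3])
  fg <- which(pm)
  ord <- fg[order(pv[fg], decreasing = TRUE)]
  next_label <- n_seed
  for (v in ord) {
    if (lab[v] > 0L) next
    nb <- v + noffs
    nl <- lab[nb]
    pos <- nl > 0L
    if (any(pos)) {
      nbp <- nb[pos]
      lab[v] <- nl[pos][which.max(pv[nbp])]
    } else {
      next_label <- next_label + 1L
      lab[v] <- next_label
    }
  }
  out <- array(lab, pd)[core_z, core_y, core_x]
  array(as.integer(out), d)
}

# ---- segmentation -----------------------------------------------------

#' Segment puncta in a 3D stack
#'
#' Reproduces the punctum-identification stage of the morphology
#' pipeline: the (already background-subtracted, and band-passed for the
#' PSD channel) stack is min-max normalized, binarized, and split into
#' individual puncta by a watershed seeded at local intensity maxima, so
#' touching structures are separated. Each labeled 3D object is then
#' measured: its intensity-weighted centroid in micrometres, the area of
#' its max-projection footprint, and the integrated intensity of that
#' footprint on the max projection of the *input* (non-normalized) stack.
#'
#' @param stack a [volume_stack()], background subtracted.
#' @param params a [segmentation_params()].
#' @return A list with `labels` (integer `[z,y,x]` array, 0 = background)
#'   and `puncta`, a data frame with one row per punctum: `id`, `channel`,
#'   `z`, `y`, `x` (centroid, um), `area2d` (um^2),
#'   `integrated_intensity`, `voxel_count`.
#' @export
segment_puncta <- function(stack, params = segmentation_params()) {
  stopifnot(inherits(stack, "VolumeStack"),
            inherits(params, "SegmentationParams"))
  v <- stack$voxels
  d <- dim(v)
  empty <- data.frame(id = integer(), channel = character(),
                      z = numeric(), y = numeric(), x = numeric(),
                      area2d = numeric(), integrated_intensity = numeric(),
                      voxel_count = integer())
  if (length(v) == 0 || max(v) <= min(v))
    return(list(labels = array(0L, d), puncta = empty))

  norm <- (v - min(v)) / (max(v) - min(v))
  thr <- if (is.numeric(params$threshold_method)) params$threshold_method
         else .otsu(norm)
  mask <- norm >= thr
  if (!any(mask)) return(list(labels = array(0L, d), puncta = empty))

  smooth <- .gauss_slices(norm, sigma = 1)
  mind <- params$maxima_min_distance
  if (is.null(mind)) {
    # expected punctum diameter in pixels, from the min-area prior
    area_px <- if (params$min_area > 0) params$min_area else 0.08
    mind <- max(3L, round(2 * sqrt(area_px / pi) / stack$voxel_size[3]))
  }
  mind <- as.integer(mind)
  mf <- .maxfilter3d(smooth, mind)
  cand <- which(mask & smooth >= mf)
  # greedy separation: keep the brightest candidate of every cluster
  if (length(cand) > 1) {
    co <- arrayInd(cand, d)
    o <- order(smooth[cand], decreasing = TRUE)
    keep <- logical(length(cand))
    for (i in o) {
      ok <- TRUE
      if (any(keep)) {
        ch <- pmax(abs(co[keep, 1, drop = FALSE] - co[i, 1]),
                   abs(co[keep, 2, drop = FALSE] - co[i, 2]),
                   abs(co[keep, 3, drop = FALSE] - co[i, 3]))
        ok <- all(ch >= mind)
      }
      keep[i] <- ok
    }
    cand <- cand[keep]
  }

  labels <- .watershed_flood(smooth, mask, cand)
  proj <- max_project(v)

  idx <- which(labels > 0L)
  by_label <- split(idx, labels[idx])
  vox <- stack$voxel_size
  px_area <- vox[2] * vox[3]
  rows <- lapply(seq_along(by_label), function(i) {
    ii <- by_label[[i]]
    co <- arrayInd(ii, d)
    w <- norm[ii]
    cen <- colSums(co * w) / sum(w) - 1  # 0-based voxel coordinates
    yx <- unique((co[, 2] - 1L) + d[2] * (co[, 3] - 1L))
    foot_y <- (yx %% d[2]) + 1L
    foot_x <- (yx %/% d[2]) + 1L
    data.frame(id = i,
               channel = stack$channel,
               z = cen[1] * vox[1], y = cen[2] * vox[2], x = cen[3] * vox[3],
               area2d = length(yx) * px_area,
               integrated_intensity = sum(proj[cbind(foot_y, foot_x)]),
               voxel_count = length(ii))
  })
  puncta <- do.call(rbind, rows)
  # relabel to match row order (split() orders labels as character)
  relab <- integer(max(labels))
  relab[as.integer(names(by_label))] <- seq_along(by_label)
  labels[idx] <- relab[labels[idx]]
  puncta$id <- seq_len(nrow(puncta))
  list(labels = labels, puncta = puncta)
}

#' Minimum projected-area filter
#'
#' Retains puncta whose max-projection footprint area is at least
#' `min_area` square micrometres (inclusive boundary: a punctum exactly
#' at the minimum is kept). Input order is preserved. The conventional
#' thresholds are 0.08 um^2 for the ribbon channel and 0.04 um^2 for the
#' postsynaptic channel; for extrasynaptic aggregate counts the filter is
#' skipped entirely.
#'
#' @param puncta data frame as returned by [segment_puncta()].
#' @param min_area minimum area in um^2 (>= 0).
#' @return The filtered data frame.
#' @export
apply_min_area <- function(puncta, min_area) {
  if (min_area < 0) stop("'min_area' must be >= 0")
  puncta[puncta$area2d >= min_area, , drop = FALSE]
}
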