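# Shared fixtures and independent oracles used across test files.

# Render a 3D Gaussian blob directly (independent of the package's
# renderer): center/sigma in voxel units, peak amplitude.
blob_array <- function(dims, center, sigma, peak = 1) {
  g <- lapply(1:3, function(ax)
    exp(-(seq_len(dims[ax]) - center[ax])^2 / (2 * sigma[ax]^2)))
  peak * outer(g[[1]], outer(g[[2]], g[[3]]))
}

# Naive grayscale opening with a ball structuring element: double-loop
# reference implementation (replicate borders), the oracle for
# rolling-ball background subtraction.
naive_ball_opening <- function(m, radius) {
  w <- seq(-radius, radius)
  d2 <- outer(w^2, w^2, "+")
  hb <- sqrt(pmax(radius^2 - d2, 0))
  hb[d2 > radius^2] <- NA
  nr <- nrow(m); nc <- ncol(m)
  px <- function(i, j) m[min(max(i, 1), nr), min(max(j, 1), nc)]
  ero <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    v <- Inf
    for (a in w) for (b in w) {
      h <- hb[a + radius + 1, b + radius + 1]
      if (!is.na(h)) v <- min(v, px(i + a, j + b) - h)
    }
    ero[i, j] <- v
  }
  pe <- function(i, j) ero[min(max(i, 1), nr), min(max(j, 1), nc)]
  opn <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    v <- -Inf
    for (a in w) for (b in w) {
      h <- hb[a + radius + 1, b + radius + 1]
      if (!is.na(h)) v <- max(v, pe(i + a, j + b) + h)
    }
    opn[i, j] <- v
  }
  opn
}

# Standard small phantom used by segmentation/pairing tests.
small_phantom <- function(noise = c(0, 0), seed = 7, channel3 = 0,
                          paired_fraction = 1, n_extrasynaptic = 0) {
  image_phantom_spec(stack_shape = c(12, 160, 160),
                     n_cells = 2, ribbons_per_cell = 3,
                     paired_fraction = paired_fraction,
                     gap_distance = c(0.15, 0.03),
                     n_extrasynaptic = n_extrasynaptic,
                     channel3_coefficient = channel3,
                     background = c(5, 5), noise = noise, seed = seed)
}

# Match detected puncta to ground-truth puncta of one channel by
# nearest centroid (um); returns the matched truth id or NA.
match_to_truth <- function(detected, truth_channel, tol = 0.3) {
  if (nrow(detected) == 0) return(integer(0))
  d2 <- outer(detected$z, truth_channel$z, "-")^2 +
        outer(detected$y, truth_channel$y, "-")^2 +
        outer(detected$x, truth_channel$x, "-")^2
  apply(sqrt(d2), 1, function(r)
    if (min(r) < tol) truth_channel$id[which.min(r)] else NA_integer_)
}

# Precision/recall of a detected pair set against the ground truth.
pair_scores <- function(pairs, rib, psd, truth) {
  tr <- truth$puncta[truth$puncta$channel == "ribbon", ]
  tp <- truth$puncta[truth$puncta$channel == "psd", ]
  mr <- match_to_truth(rib, tr)
  mp <- match_to_truth(psd, tp)
  det <- paste(mr[match(pairs$ribbon_id, rib$id)],
               mp[match(pairs$psd_id, psd$id)])
  tru <- paste(truth$pairs$ribbon_id, truth$pairs$psd_id)
  hits <- sum(det %in% tru)
  list(precision = hits / max(nrow(pairs), 1),
       recall = hits / max(nrow(truth$pairs), 1))
}

# Full morphology pass on a simulated phantom (background subtraction,
# PSD band-pass, segmentation, min-area filters, pairing).
segment_and_pair <- function(sim, threshold_method = "otsu") {
  rib_bg <- subtract_background(sim$channels$ribbon, 50)
  psd_bg <- subtract_background(sim$channels$psd, 50)
  psd_bp <- bandpass(psd_bg, 6, 20)
  seg_r <- segment_puncta(rib_bg,
    segmentation_params(min_area = 0.08, threshold_method = threshold_method))
  seg_p <- segment_puncta(psd_bp,
    segmentation_params(min_area = 0.04, threshold_method = threshold_method))
  rib <- apply_min_area(seg_r$puncta, 0.08)
  psd <- apply_min_area(seg_p$puncta, 0.04)
  list(rib = rib, psd = psd, seg_r = seg_r, seg_p = seg_p,
       pairing = pair_synapses(rib, psd))
}
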