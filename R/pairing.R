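#' Radius-sum pairing threshold
#'
#' Converts the projected 2D areas of a ribbon and a postsynaptic punctum
#' into an approximate radius each (`sqrt(area / pi)`) and returns the sum
#' of the two radii. A ribbon--PSD pair whose 3D centroid separation is at
#' most this threshold is considered a complete synapse.
#'
#' @param area_ribbon,area_psd projected 2D areas in um^2; must be > 0.
#' @return Threshold distance in micrometres.
#' @examples
#' pair_radius_threshold(0.08, 0.04)  # ~0.2724 um
#' @export
pair_radius_threshold <- function(area_ribbon, area_psd) {
  if (any(area_ribbon <= 0) || any(area_psd <= 0))
    stop("areas must be positive")
  sqrt(area_ribbon / pi) + sqrt(area_psd / pi)
}

#' Pair ribbons with postsynaptic densities by centroid distance
#'
#' For every ribbon--PSD combination the 3D Euclidean centroid distance
#' (in micrometres) is compared against the radius-sum threshold computed
#' from the two projected areas. Candidates within threshold are matched
#' greedily in ascending distance order (ties broken by ribbon id then
#' PSD id), one-to-one; every punctum joins at most one pair. Remaining
#' puncta are reported unpaired -- unpaired PSDs are the orphan
#' postsynapses, and unpaired ribbon puncta from an unfiltered
#' segmentation pass are the extrasynaptic Ribeye count.
#'
#' @param ribbons,psds punctum data frames (see [segment_puncta()]) with
#'   `id`, centroid columns `z`, `y`, `x` in um, and `area2d`.
#' @return A list with `pairs` (data frame `ribbon_id`, `psd_id`,
#'   `distance`, `threshold`) and `summary` (list `n_pairs`,
#'   `n_unpaired_ribbons`, `n_unpaired_psds`, `unpaired_ribbon_ids`,
#'   `unpaired_psd_ids`).
#' @export
pair_synapses <- function(ribbons, psds) {
  empty_pairs <- data.frame(ribbon_id = integer(), psd_id = integer(),
                            distance = numeric(), threshold = numeric())
  nr <- NROW(ribbons); np <- NROW(psds)
  if (nr == 0 || np == 0) {
    return(list(pairs = empty_pairs,
                summary = list(n_pairs = 0L,
                               n_unpaired_ribbons = nr,
                               n_unpaired_psds = np,
                               unpaired_ribbon_ids = ribbons$id,
                               unpaired_psd_ids = psds$id)))
  }
  dz <- outer(ribbons$z, psds$z, "-")
  dy <- outer(ribbons$y, psds$y, "-")
  dx <- outer(ribbons$x, psds$x, "-")
  dist <- sqrt(dz^2 + dy^2 + dx^2)
  thr <- outer(ribbons$area2d, psds$area2d, pair_radius_threshold)
  cand <- which(dist <= thr, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    pairs <- empty_pairs
  } else {
    o <- order(dist[cand],
               ribbons$id[cand[, 1]],
               psds$id[cand[, 2]])
    cand <- cand[o, , drop = FALSE]
    used_r <- logical(nr); used_p <- logical(np)
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (!used_r[i] && !used_p[j]) {
        used_r[i] <- TRUE; used_p[j] <- TRUE; keep[k] <- TRUE
      }
    }
    cand <- cand[keep, , drop = FALSE]
    pairs <- data.frame(ribbon_id = ribbons$id[cand[, 1]],
                        psd_id = psds$id[cand[, 2]],
                        distance = dist[cand],
                        threshold = thr[cand])
    pairs <- pairs[order(pairs$ribbon_id), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  list(pairs = pairs,
       summary = list(
         n_pairs = nrow(pairs),
         n_unpaired_ribbons = nr - nrow(pairs),
         n_unpaired_psds = np - nrow(pairs),
         unpaired_ribbon_ids = setdiff(ribbons$id, pairs$ribbon_id),
         unpaired_psd_ids = setdiff(psds$id, pairs$psd_id)))
}

#' Proximity summary of distance measurements
#'
#' Summarizes a set of distances (e.g. ribbon-to-mitochondrion distances
#' measured on electron micrographs) against a proximity cutoff: the
#' percentage of distances strictly below the cutoff, rounded to the
#' nearest integer percent, and the median of the within-cutoff subset.
#'
#' @param distances numeric vector of distances in um; must be non-empty.
#' @param cutoff proximity cutoff in um (> 0); strict `<` comparison.
#' @return A list with `percent_within`, `median_within` (um; `NA` if no
#'   distance falls below the cutoff), and `n`.
#' @examples
#' # 17 of 21 ribbons with a mitochondrion closer than 1 um -> 81%
#' proximity_summary(c(runif(17, 0, 0.99), 1 + runif(4)), cutoff = 1)$percent_within
#' @export
proximity_summary <- function(distances, cutoff = 1) {
  if (length(distances) == 0) stop("'distances' must be non-empty")
  if (cutoff <= 0) stop("'cutoff' must be positive")
  within <- distances[distances < cutoff]
  list(percent_within = round(100 * length(within) / length(distances)),
       median_within = if (length(within)) stats::median(within) else NA_real_,
       n = length(distances))
}

#' Integrated channel intensity inside punctum footprints
#'
#' Measures, for each punctum ROI (typically ribbon footprints), the
#' integrated intensity of another channel -- e.g. the Ca_V_1.3
#' immunolabel -- inside the 2D footprint on the max z-projection of that
#' channel's stack. Footprints are reconstructed from the label volume.
#'
#' @param labels integer label volume from [segment_puncta()].
#' @param ids punctum ids (label values) to measure.
#' @param stack a [volume_stack()] of the channel to quantify; must have
#'   the same y/x dimensions as `labels`.
#' @return Named numeric vector of integrated intensities (AU), one per id.
#' @export
roi_channel_intensity <- function(labels, ids, stack) {
  stopifnot(inherits(stack, "VolumeStack"))
  d <- dim(labels)
  ds <- dim(stack$voxels)
  if (!all(d[2:3] == ds[2:3]))
    stop("label volume and stack differ in y/x size")
  proj <- max_project(stack)
  out <- vapply(ids, function(i) {
    idx <- which(labels == i)
    if (length(idx) == 0)
      stop(sprintf("ROI id %s not present in label volume", i))
    co <- arrayInd(idx, d)
    yx <- unique(co[, 2:3, drop = FALSE])
    sum(proj[yx])
  }, numeric(1))
  names(out) <- ids
  out
}
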