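test_that("rolling-ball subtraction flattens constants and matches the explicit opening", {
  vox <- c(0.3, 0.05, 0.05)
  cst <- volume_stack(array(7, c(2, 24, 24)), vox)
  out <- subtract_background(cst, 8)
  expect_true(all(abs(out$voxels) < 1e-9))

  # oracle: naive double-loop ball opening on a small noisy slice
  set.seed(11)
  sl <- matrix(runif(24 * 24, 0, 1), 24, 24) +
    blob_array(c(1, 24, 24), c(1, 12, 12), c(1, 2, 2), peak = 5)[1, , ]
  st <- volume_stack(array(sl, c(1, 24, 24)), vox)
  got <- subtract_background(st, 4)$voxels[1, , ]
  want <- pmax(sl - pmin(naive_ball_opening(sl, 4), sl), 0)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("rolling ball preserves blobs and removes planar gradients", {
  vox <- c(0.3, 0.05, 0.05)
  blob <- blob_array(c(1, 64, 64), c(1, 32, 32), c(1, 2, 2), peak = 100)
  st <- volume_stack(blob, vox)
  out <- subtract_background(st, 50)
  expect_gt(max(out$voxels), 95)  # peak preserved within 5%

  grad <- array(rep(seq(0, 30, length.out = 64), each = 64), c(1, 64, 64))
  st2 <- volume_stack(blob + grad, vox)
  out2 <- subtract_background(st2, 50)
  expect_lt(abs(max(out2$voxels) - 100) / 100, 0.10)

  expect_error(subtract_background(st, 100), "radius")
})

test_that("band-pass nulls constants and prefers in-band structure sizes", {
  vox <- c(0.3, 0.05, 0.05)
  cst <- volume_stack(array(50, c(1, 64, 64)), vox)
  expect_true(all(abs(bandpass(cst, 6, 20)$voxels) < 1e-6 * 50))

  mk <- function(sig) {
    v <- blob_array(c(1, 96, 96), c(1, 48, 48), c(1, sig, sig), peak = 1)
    max(bandpass(volume_stack(v, vox), 6, 20)$voxels)
  }
  impulse <- array(0, c(1, 96, 96)); impulse[1, 48, 48] <- 1
  pk_impulse <- max(bandpass(volume_stack(impulse, vox), 6, 20)$voxels)
  pk_10px <- mk(10 / 2.355)   # 10 px FWHM, inside the band
  pk_40px <- mk(40 / 2.355)   # 40 px FWHM, beyond the band
  expect_lt(pk_impulse, 0.5 * pk_10px)
  # closed-form DoG response to a Gaussian of variance sb2:
  # sb2/(sb2+s1) - sb2/(sb2+s2)
  s1 <- (6 / 2.355)^2; s2 <- (20 / 2.355)^2
  cf <- function(sb2) sb2 / (sb2 + s1) - sb2 / (sb2 + s2)
  expect_equal(pk_40px / pk_10px,
               cf((40 / 2.355)^2) / cf((10 / 2.355)^2),
               tolerance = 0.05)
  expect_lt(pk_40px, 0.4 * pk_10px)

  expect_error(bandpass(cst, 20, 6), "small")
})

test_that("segmentation finds isolated blobs and watershed splits touching ones", {
  vox <- c(0.3, 0.05, 0.05)
  # one blob
  v1 <- blob_array(c(9, 64, 64), c(5, 32, 32), c(1.2, 3, 3), peak = 100)
  s1 <- segment_puncta(volume_stack(v1, vox), segmentation_params())
  expect_equal(nrow(s1$puncta), 1)
  expect_lt(abs(s1$puncta$y / vox[2] - 31), 1)   # centroid within 1 voxel
  expect_lt(abs(s1$puncta$x / vox[3] - 31), 1)

  # two blobs 3 x FWHM apart: plain connected components suffice
  fwhm <- 2.355 * 3
  v2 <- blob_array(c(9, 80, 80), c(5, 40, 30), c(1.2, 3, 3), peak = 100) +
        blob_array(c(9, 80, 80), c(5, 40, 30 + 3 * fwhm), c(1.2, 3, 3), peak = 100)
  s2 <- segment_puncta(volume_stack(v2, vox), segmentation_params())
  expect_equal(nrow(s2$puncta), 2)

  # 1.2 x FWHM apart: merged at threshold, split by the seeded watershed
  v3 <- blob_array(c(9, 64, 64), c(5, 32, 26), c(1.2, 3, 3), peak = 100) +
        blob_array(c(9, 64, 64), c(5, 32, 26 + 1.2 * fwhm), c(1.2, 3, 3), peak = 100)
  s3 <- segment_puncta(volume_stack(v3, vox),
                       segmentation_params(threshold_method = 0.3,
                                           maxima_min_distance = 4))
  expect_equal(nrow(s3$puncta), 2)

  # the threshold really merges them: the bridge between the two
  # centers stays above threshold, so only the watershed separates them
  xline <- v3[5, 32, ] / max(v3)
  expect_true(all(xline[26:round(26 + 1.2 * fwhm)] >= 0.3))
})

test_that("empty and all-zero stacks give empty punctum lists", {
  vox <- c(0.3, 0.05, 0.05)
  s <- segment_puncta(volume_stack(array(0, c(4, 16, 16)), vox),
                      segmentation_params())
  expect_equal(nrow(s$puncta), 0)
  expect_true(all(s$labels == 0))
})

test_that("every above-threshold voxel carries exactly one label", {
  spec <- small_phantom(seed = 13)
  sim <- simulate_stack(spec)
  st <- subtract_background(sim$channels$ribbon, 50)
  seg <- segment_puncta(st, segmentation_params())
  norm <- (st$voxels - min(st$voxels)) / diff(range(st$voxels))
  thr <- ribbonq:::.otsu(norm)
  expect_true(all((seg$labels > 0) == (norm >= thr)))
  expect_equal(length(unique(seg$labels[seg$labels > 0])), nrow(seg$puncta))
})

test_that("minimum-area filter has an inclusive boundary and is monotone", {
  puncta <- data.frame(id = 1:3, area2d = c(0.079, 0.08, 0.2))
  kept <- apply_min_area(puncta, 0.08)
  expect_equal(kept$id, c(2, 3))         # 0.079 removed, 0.08 retained
  expect_equal(apply_min_area(puncta, 0), puncta)  # identity at 0
  counts <- vapply(seq(0, 0.3, by = 0.02),
                   function(a) nrow(apply_min_area(puncta, a)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(apply_min_area(puncta, -1), "min_area")
})

test_that("intensity gain rescales integrated intensity but not counts", {
  vox <- c(0.3, 0.05, 0.05)
  v <- blob_array(c(9, 64, 64), c(5, 32, 32), c(1.2, 3, 3), peak = 50)
  a <- segment_puncta(volume_stack(v, vox), segmentation_params())
  b <- segment_puncta(volume_stack(3 * v, vox), segmentation_params())
  expect_equal(nrow(a$puncta), nrow(b$puncta))
  expect_equal(b$puncta$integrated_intensity,
               3 * a$puncta$integrated_intensity, tolerance = 1e-9)
})

test_that("segmentation matches phantom ground truth on well-separated blobs", {
  sim <- simulate_stack(small_phantom(seed = 17))
  res <- segment_and_pair(sim)
  tr <- sim$truth$puncta[sim$truth$puncta$channel == "ribbon", ]
  expect_equal(nrow(res$rib), nrow(tr))
  m <- match_to_truth(res$rib, tr, tol = sqrt(sum((c(0.3, 0.05, 0.05))^2)))
  expect_false(any(is.na(m)))
  expect_equal(sort(m), sort(tr$id))
})
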