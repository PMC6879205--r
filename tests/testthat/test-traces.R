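test_that("translation registration recovers planted drift and handles constants", {
  set.seed(1)
  base <- matrix(runif(64 * 64), 64, 64)
  mov <- array(0, c(4, 64, 64))
  mov[1, , ] <- base
  for (f in 2:4)  # content moved +3 px in x
    mov[f, , ] <- base[, c(rep(1, 3), 1:61)]
  r <- register_translation(mov)
  expect_equal(r$shifts[2:4, 2], rep(3L, 3))
  expect_equal(r$shifts[, 1], rep(0L, 4))
  # aligned frames match the reference away from the replicated edge
  expect_equal(r$movie[2, , 1:58], base[, 1:58], tolerance = 1e-12)

  still <- array(rep(base, each = 3), c(3, 64, 64))
  expect_true(all(register_translation(still)$shifts == 0))

  flat <- array(5, c(3, 16, 16))
  expect_true(all(register_translation(flat)$shifts == 0))
})

test_that("circular ROI traces average the pixels whose centers fall inside", {
  mov <- array(3, c(5, 40, 40))
  tr <- roi_trace(mov, center = c(1, 1), diameter = 0.8, pixel_size = 0.05)
  expect_equal(tr, rep(3, 5))

  blob <- blob_array(c(1, 40, 40), c(1, 20, 20), c(1, 3, 3), peak = 10)
  mov2 <- array(rep(blob[1, , ], each = 2), c(2, 40, 40))
  on_blob <- roi_trace(mov2, c(1, 1), 0.4, 0.05)
  off_blob <- roi_trace(mov2, c(1, 1.8), 0.4, 0.05)  # displaced by 2 diameters
  expect_gt(on_blob[1], off_blob[1])

  expect_error(roi_trace(mov, c(1, 1), 0.01, 0.05), "diameter|pixel")
  expect_error(roi_trace(mov, c(0.1, 0.1), 0.8, 0.05), "outside")
})

test_that("evoked dF/F0 uses a strict activity threshold and is gain invariant", {
  f <- c(rep(100, 20), rep(125, 20))  # F0 = 100, peak F = 125
  ts <- trace_set(matrix(f, 1), frame_rate = 10,
                  stimulus_windows = list(c(2, 3)), channel = "GCaMP6sCAAX")
  r <- evoked_dff(ts)
  expect_equal(r$peak, 0.25)
  expect_false(r$active)         # strict >, boundary is inactive
  expect_equal(r$threshold_used, 0.25)

  ts_mito <- trace_set(matrix(f, 1), 10, list(c(2, 3)), channel = "MitoRGECO1")
  r_mito <- evoked_dff(ts_mito)
  expect_equal(r_mito$threshold_used, 0.05)
  expect_true(r_mito$active)

  ts_k <- trace_set(matrix(7 * f, 1), 10, list(c(2, 3)), "GCaMP6sCAAX")
  expect_equal(attr(evoked_dff(ts_k), "dff"), attr(r, "dff"))

  expect_error(evoked_dff(trace_set(matrix(f - 200, 1), 10, list(c(2, 3)))),
               "F0")
})

test_that("simulated evoked plateau is recovered as the dF/F0 peak", {
  spec <- trace_sim_spec(frame_rate = 50, duration = 20,
                         stimulus_windows = list(c(5, 7)),
                         channels = list(cyto = list(rise = 0.06, decay = 4,
                                                     plateau = 0.5)),
                         seed = 2)
  ev <- simulate_evoked_traces(spec)
  r <- evoked_dff(ev$traces$cyto)
  expect_equal(r$peak, 0.5, tolerance = 0.01)
  expect_true(r$active)
})

test_that("dF maps localize intensity steps and respect binning", {
  mov <- array(10, c(20, 8, 8))
  mov[11:20, 3, 5] <- 20                       # one pixel steps +10
  m <- dff_map(mov, frame_rate = 1, prestim_window = c(0, 10), bin = 1)
  expect_equal(dim(m$dF)[1], 10)               # bin = 1 keeps frame count
  expect_equal(m$dF[1, 3, 5], 10)
  expect_true(all(abs(m$dF[, -3, ]) < 1e-12))

  still <- array(4, c(12, 6, 6))
  ms <- dff_map(still, 1, c(0, 6), bin = 2)
  expect_true(all(abs(ms$dF) < 1e-12))
  expect_error(dff_map(still, 1, c(0, 6), bin = 10), "bin")
})

test_that("bleach correction flattens exponential decay and spares events", {
  t <- seq(0, 897, by = 3)
  pure <- 100 * exp(-t / 600)
  bc <- bleach_correct(pure, frame_rate = 1 / 3)
  expect_true(bc$corrected)
  expect_lt(max(abs(bc$trace / bc$trace[1] - 1)), 0.02)
  expect_equal(bc$tau, 600, tolerance = 0.05)

  flat <- rep(80, 300)
  bf <- bleach_correct(flat, 1 / 3)
  expect_lt(max(abs(bf$trace - flat) / flat), 0.01)

  # planted decay + 3 events: flat baseline, amplitudes preserved
  spec <- trace_sim_spec(frame_rate = 1, duration = 900,
                         stimulus_windows = list(),
                         channels = list(c1 = list(rise = 2, decay = 15)),
                         n_events = 3, amplitude = c(1, 0.01), coupling = 1,
                         bleach_tau = 600, noise_sd = 0, seed = 3)
  sp <- simulate_spontaneous_traces(spec)
  bc3 <- bleach_correct(sp$traces$c1$values[1, ], 1)
  st <- spontaneous_stats(bc3$trace, 1)
  truth <- sp$truth$events
  expect_equal(length(st$event_times), 3)
  expect_true(all(abs(st$event_amplitudes - truth$amplitude) /
                  truth$amplitude < 0.10))
  # baseline = frames well clear of any planted transient
  tt <- (seq_along(bc3$trace) - 1)
  clear <- sapply(tt, function(x) all(x < truth$time - 5 | x > truth$time + 120))
  base <- bc3$trace[clear]
  expect_lt(diff(range(base)) / stats::median(base), 0.02)

  expect_error(bleach_correct(1:5), "20 frames")
})

test_that("spontaneous statistics follow the percentile baseline and 10% threshold", {
  # all dF/F0 at 0.05: below threshold, so magnitude and frequency are 0
  sub <- c(rep(100, 250), rep(105, 50))
  st <- spontaneous_stats(sub, frame_rate = 1 / 3)
  expect_equal(st$magnitude, 0)
  expect_equal(st$frequency, 0)

  # one event whose suprathreshold dff sums to 3.0 over 300 frames
  dff <- rep(0, 300); dff[150:154] <- c(0.5, 1.0, 0.8, 0.5, 0.2)
  tr <- 100 * (1 + dff)
  st2 <- spontaneous_stats(tr, 1 / 3)
  expect_equal(st2$F0, 100)
  expect_equal(st2$magnitude, 3.0 / 300, tolerance = 1e-9)

  # 9 planted well-separated events in 900 s -> exactly 0.01 Hz
  spec <- trace_sim_spec(frame_rate = 1 / 3, duration = 900,
                         stimulus_windows = list(),
                         channels = list(c1 = list(rise = 2, decay = 10)),
                         n_events = 9, amplitude = c(1, 0.1), coupling = 1,
                         noise_sd = 0, seed = 5)
  sp <- simulate_spontaneous_traces(spec)
  st3 <- spontaneous_stats(sp$traces$c1$values[1, ], 1 / 3)
  expect_equal(st3$frequency, 0.01)

  # magnitude grows with event amplitude
  spec2 <- spec; spec2$amplitude <- c(2, 0.1)
  sp2 <- simulate_spontaneous_traces(spec2)
  st4 <- spontaneous_stats(sp2$traces$c1$values[1, ], 1 / 3)
  expect_gt(st4$magnitude, st3$magnitude)
})

test_that("Pearson matrix honors its bounds and flags zero variance", {
  set.seed(8)
  x <- matrix(rnorm(3 * 50), 3, 50)
  A <- trace_set(x, 1)
  expect_equal(unname(diag(pearson_matrix(A, A))), rep(1, 3),
               tolerance = 1e-12)
  B <- trace_set(-x, 1)
  expect_equal(unname(diag(pearson_matrix(A, B))), rep(-1, 3),
               tolerance = 1e-12)
  r <- pearson_matrix(A, B)
  expect_true(all(r >= -1 - 1e-12 & r <= 1 + 1e-12))
  expect_true(isSymmetric(unname(pearson_matrix(A, A)), tol = 1e-12))

  z <- trace_set(rbind(x[1, ], rep(2, 50)), 1)
  rz <- pearson_matrix(z, A)
  expect_true(all(is.na(rz[2, ])))
  expect_false(any(is.na(rz[1, ])))
})

test_that("coupled phantom channels correlate; uncoupled ones do not", {
  mk <- function(coup, seed, noise)
    trace_sim_spec(frame_rate = 0.2, duration = 900, stimulus_windows = list(),
                   channels = list(a = list(rise = 2, decay = 12),
                                   b = list(rise = 2, decay = 12)),
                   event_rate = 0.01, amplitude = c(0.8, 0.2),
                   coupling = coup, noise_sd = noise, n_cells = 6, seed = seed)
  s1 <- simulate_spontaneous_traces(mk(1, 11, 0))
  r1 <- pearson_matrix(s1$traces$a, s1$traces$b)
  expect_true(all(diag(r1) > 0.95))
  s0 <- simulate_spontaneous_traces(mk(0, 12, 2))
  r0 <- pearson_matrix(s0$traces$a, s0$traces$b)
  expect_equal(ncol(s0$traces$a$values), 180)
  expect_lt(median(abs(r0)), 0.2)
})

test_that("mock normalization and replicate averaging behave as identities", {
  mock <- data.frame(pre = c(100, 100), post = c(80, 80))
  treated <- data.frame(pre = 100, post = 80)
  expect_equal(normalize_to_mock(treated, mock)$normalized_change, 1)
  expect_equal(normalize_to_mock(data.frame(pre = 100, post = 40),
                                 mock)$normalized_change, 0.5)
  self <- normalize_to_mock(mock, mock)
  expect_equal(mean(self$normalized_change), 1)
  expect_error(normalize_to_mock(treated, mock[0, ]), "non-empty")

  expect_equal(average_replicate_stacks(c(10, 10, 10, 10)), 10)
  expect_equal(average_replicate_stacks(c(8, 12, 9, 11)), 10)
  expect_equal(average_replicate_stacks(42), 42)
  expect_error(average_replicate_stacks(numeric(0)), "average")
})

test_that("4PL fit recovers planted parameters and flags degeneracy", {
  tab <- simulate_dose_response(1.37, hill = 1, bottom = 0, top = 1,
                                doses = c(0, 0.5, 2, 5, 10), noise_sd = 0)
  f <- fit_4pl(tab$dose, tab$response)
  expect_lt(abs(f$ic50 - 1.37) / 1.37, 0.01)
  expect_equal(f$hill, 1, tolerance = 0.01)

  flat <- fit_4pl(c(0, 0.5, 2, 5, 10), rep(0.7, 5))
  expect_true(flat$degenerate)
  expect_true(is.na(flat$ic50))

  ics <- vapply(1:20, function(s) {
    tb <- simulate_dose_response(1.37, 1, 0, 1, noise_sd = 0.02, seed = s)
    fit_4pl(tb$dose, tb$response)$ic50
  }, numeric(1))
  expect_lt(abs(median(ics) - 1.37) / 1.37, 0.10)

  expect_error(fit_4pl(c(0, 1, 2), c(1, 0.5, 0.2)), "4 distinct")
})
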