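#' Specification of a synthetic neuromast image phantom
#'
#' Describes a multi-channel 3D phantom emulating an immunostained
#' neuromast: paired ribbon/postsynaptic-density puncta rendered as
#' anisotropic 3D Gaussian blobs, optional extrasynaptic ribbon
#' aggregates, a third channel (calcium-channel immunolabel) deposited at
#' ribbon sites, a constant-plus-planar-gradient background, and
#' Poisson-then-Gaussian detector noise.
#'
#' @param stack_shape integer length-3 `(z, y, x)` voxel counts.
#' @param voxel_size um per voxel `(z, y, x)`; defaults to an
#'   Airyscan-like 0.3 um axial / 0.05 um lateral grid.
#' @param n_cells number of hair cells contributing ribbons.
#' @param ribbons_per_cell ribbons per cell; a single count or a
#'   length-2 inclusive range sampled per cell.
#' @param paired_fraction fraction of ribbons given a paired PSD, in
#'   `[0, 1]`; the paired count is `round(paired_fraction * n_ribbons)`.
#' @param gap_distance `c(mean, sd)` in um of the ribbon--PSD centroid
#'   separation (drawn as `|Normal|`, random 3D direction).
#' @param ribbon_area,psd_area `c(min, max)` um^2 range of true projected
#'   punctum areas (half-max footprint of the rendered blob).
#' @param n_extrasynaptic number of extrasynaptic ribbon-channel
#'   aggregates (never paired; excluded from channel-3 deposition).
#' @param extrasynaptic_area `c(min, max)` um^2 range for aggregates.
#' @param peak_intensities named `c(ribbon=, psd=)` peak amplitudes (AU);
#'   each blob's amplitude is jittered uniformly within +/-30%.
#' @param channel3_coefficient channel-3 peak amplitude per unit ribbon
#'   peak amplitude (0 disables the third channel).
#' @param axial_fwhm um axial extent (FWHM) of rendered blobs.
#' @param background `c(constant, gradient)` AU; the gradient term adds a
#'   plane rising linearly along x from 0 to `gradient`.
#' @param noise `c(poisson_gain, gaussian_sd)`; `poisson_gain > 0`
#'   applies photon noise (`rpois(F/gain) * gain`) before additive
#'   Gaussian read noise of the given sd; `c(0, 0)` disables noise.
#' @param min_separation um minimum distance between distinct synapse
#'   sites (keeps phantom puncta resolvable).
#' @param seed integer RNG seed; identical specs produce identical
#'   phantoms.
#' @return A list of class `ImagePhantomSpec`.
#' @export
image_phantom_spec <- function(stack_shape = c(12, 256, 256),
                               voxel_size = c(0.3, 0.05, 0.05),
                               n_cells = 4,
                               ribbons_per_cell = 3,
                               paired_fraction = 1,
                               gap_distance = c(0.15, 0.03),
                               ribbon_area = c(0.1, 0.3),
                               psd_area = c(0.05, 0.2),
                               n_extrasynaptic = 0,
                               extrasynaptic_area = c(0.02, 0.06),
                               peak_intensities = c(ribbon = 100, psd = 100),
                               channel3_coefficient = 0,
                               axial_fwhm = 0.9,
                               background = c(0, 0),
                               noise = c(0, 0),
                               min_separation = 1.2,
                               seed = 1) {
  fail <- function(field, why) stop(sprintf("invalid '%s': %s", field, why))
  if (length(stack_shape) != 3 || any(stack_shape < 1))
    fail("stack_shape", "must be 3 positive voxel counts (z, y, x)")
  if (any(voxel_size <= 0)) fail("voxel_size", "must be positive")
  if (paired_fraction < 0 || paired_fraction > 1)
    fail("paired_fraction", "must lie in [0, 1]")
  if (any(ribbon_area <= 0)) fail("ribbon_area", "must be positive")
  if (any(psd_area <= 0)) fail("psd_area", "must be positive")
  if (any(extrasynaptic_area <= 0))
    fail("extrasynaptic_area", "must be positive")
  if (any(peak_intensities <= 0))
    fail("peak_intensities", "must be positive")
  if (any(gap_distance < 0)) fail("gap_distance", "must be >= 0")
  if (n_cells < 1) fail("n_cells", "must be >= 1")
  structure(as.list(environment())[setdiff(ls(), "fail")],
            class = "ImagePhantomSpec")
}

# sigma (um) of a lateral Gaussian whose half-max footprint has the
# given area: area = 2 * pi * ln(2) * sigma^2
.sigma_from_area <- function(area) sqrt(area / (2 * pi * log(2)))

# Add one 3D Gaussian blob (center um, sigma um per axis, peak AU) to a
# [z,y,x] volume in place; returns list(vol, total) with the deposited sum.
.render_blob <- function(vol, voxel_size, center, sigma, peak) {
  d <- dim(vol)
  rng <- lapply(1:3, function(ax) {
    lo <- max(1L, floor((center[ax] - 4 * sigma[ax]) / voxel_size[ax]) + 1L)
    hi <- min(d[ax], ceiling((center[ax] + 4 * sigma[ax]) / voxel_size[ax]) + 1L)
    if (lo > hi) integer(0) else lo:hi
  })
  if (any(lengths(rng) == 0)) return(list(vol = vol, total = 0))
  gs <- lapply(1:3, function(ax) {
    pos <- (rng[[ax]] - 1) * voxel_size[ax]
    exp(-(pos - center[ax])^2 / (2 * sigma[ax]^2))
  })
  blob <- peak * outer(gs[[1]], outer(gs[[2]], gs[[3]]))
  vol[rng[[1]], rng[[2]], rng[[3]]] <-
    vol[rng[[1]], rng[[2]], rng[[3]]] + blob
  list(vol = vol, total = sum(blob))
}

.apply_noise <- function(vol, noise) {
  if (noise[1] > 0) {
    v <- stats::rpois(length(vol), pmax(vol, 0) / noise[1]) * noise[1]
    vol <- array(v, dim(vol))
  }
  if (noise[2] > 0)
    vol <- vol + array(stats::rnorm(length(vol), 0, noise[2]), dim(vol))
  vol
}

#' Simulate a multi-channel neuromast image phantom
#'
#' Renders the phantom described by an [image_phantom_spec()] and returns
#' both the image channels and the exact ground truth needed to score any
#' downstream segmentation and pairing result. Ribbons are placed with a
#' minimum mutual separation; each paired PSD sits at a sampled gap
#' distance from its ribbon in a random 3D direction; the half-max
#' projected footprint of every rendered blob equals its sampled true
#' area by construction.
#'
#' @param spec an [image_phantom_spec()].
#' @return A list with `channels` (named list of [volume_stack()]:
#'   `ribbon`, `psd`, and `channel3` when enabled) and `truth`, a list
#'   with `puncta` (id, channel, centroid um, true area um^2, true total
#'   intensity AU, synaptic flag, cell), `pairs` (ribbon_id, psd_id, gap
#'   um) and `spec`.
#' @export
simulate_stack <- function(spec) {
  stopifnot(inherits(spec, "ImagePhantomSpec"))
  set.seed(spec$seed)
  d <- spec$stack_shape
  vox <- spec$voxel_size
  extent <- (d - 1) * vox  # physical size, um

  sig_lat_max <- .sigma_from_area(max(spec$ribbon_area, spec$psd_area))
  sig_z <- spec$axial_fwhm / (2 * sqrt(2 * log(2)))
  if (8 * sig_lat_max > min(extent[2:3]) || 6 * sig_z > extent[1])
    stop("blob larger than stack: increase 'stack_shape' or shrink areas")

  # margins keep blobs and their PSD partners inside the stack
  margin <- c(max(2 * sig_z, max(spec$gap_distance[1] + 3 * spec$gap_distance[2], 0.2)),
              rep(4 * sig_lat_max + spec$gap_distance[1] + 3 * spec$gap_distance[2], 2))
  margin <- pmin(margin, extent / 2.5)

  rpc <- spec$ribbons_per_cell
  per_cell <- if (length(rpc) == 2)
    sample(rpc[1]:rpc[2], spec$n_cells, replace = TRUE)
  else rep(rpc, spec$n_cells)
  n_rib <- sum(per_cell)
  n_total_sites <- n_rib + spec$n_extrasynaptic

  # rejection-sample site positions with minimum mutual separation
  sites <- matrix(NA_real_, n_total_sites, 3)
  n_ok <- 0L; tries <- 0L
  while (n_ok < n_total_sites && tries < 20000L) {
    tries <- tries + 1L
    p <- margin + stats::runif(3) * (extent - 2 * margin)
    if (n_ok == 0L ||
        min(sqrt(colSums((t(sites[seq_len(n_ok), , drop = FALSE]) - p)^2))) >=
        spec$min_separation) {
      n_ok <- n_ok + 1L
      sites[n_ok, ] <- p
    }
  }
  if (n_ok < n_total_sites)
    stop("could not place all puncta: stack too small for ",
         n_total_sites, " sites at min_separation ", spec$min_separation)

  cell_of <- c(rep(seq_len(spec$n_cells), per_cell),
               rep(NA_integer_, spec$n_extrasynaptic))
  n_paired <- round(spec$paired_fraction * n_rib)
  paired_idx <- if (n_paired > 0) sort(sample.int(n_rib, n_paired)) else integer(0)

  runif_range <- function(n, r) stats::runif(n, r[1], r[2])
  rib_area <- runif_range(n_rib, spec$ribbon_area)
  ex_area <- if (spec$n_extrasynaptic > 0)
    runif_range(spec$n_extrasynaptic, spec$extrasynaptic_area) else numeric(0)
  psd_area <- runif_range(n_paired, spec$psd_area)
  rib_peak <- spec$peak_intensities[["ribbon"]] * stats::runif(n_total_sites, 0.7, 1.3)
  psd_peak <- spec$peak_intensities[["psd"]] * stats::runif(n_paired, 0.7, 1.3)

  # PSD positions: sampled gap along a uniform random 3D direction
  if (n_paired > 0) {
    gaps <- abs(stats::rnorm(n_paired, spec$gap_distance[1], spec$gap_distance[2]))
    dir <- matrix(stats::rnorm(3 * n_paired), ncol = 3)
    dir <- dir / pmax(sqrt(rowSums(dir^2)), 1e-12)
    psd_pos <- sites[paired_idx, , drop = FALSE] + dir * gaps
    psd_pos <- pmin(pmax(psd_pos, 0),
                    matrix(extent, n_paired, 3, byrow = TRUE))
    gaps <- sqrt(rowSums((psd_pos - sites[paired_idx, , drop = FALSE])^2))
  } else {
    gaps <- numeric(0)
    psd_pos <- matrix(numeric(0), 0, 3)
  }

  vol_rib <- array(0, d); vol_psd <- array(0, d)
  vol_ch3 <- if (spec$channel3_coefficient > 0) array(0, d) else NULL
  all_area <- c(rib_area, ex_area)
  tot_rib <- numeric(n_total_sites)
  for (i in seq_len(n_total_sites)) {
    sg <- c(sig_z, rep(.sigma_from_area(all_area[i]), 2))
    rb <- .render_blob(vol_rib, vox, sites[i, ], sg, rib_peak[i])
    vol_rib <- rb$vol; tot_rib[i] <- rb$total
    if (!is.null(vol_ch3) && i <= n_rib)
      vol_ch3 <- .render_blob(vol_ch3, vox, sites[i, ], sg,
                              spec$channel3_coefficient * rib_peak[i])$vol
  }
  tot_psd <- numeric(n_paired)
  for (j in seq_len(n_paired)) {
    sg <- c(sig_z, rep(.sigma_from_area(psd_area[j]), 2))
    rb <- .render_blob(vol_psd, vox, psd_pos[j, ], sg, psd_peak[j])
    vol_psd <- rb$vol; tot_psd[j] <- rb$total
  }

  add_bg <- function(vol) {
    if (all(spec$background == 0)) return(vol)
    grad <- spec$background[2] * (seq_len(d[3]) - 1) / max(d[3] - 1, 1)
    plane <- matrix(grad, d[2], d[3], byrow = TRUE) + spec$background[1]
    for (z in seq_len(d[1])) vol[z, , ] <- vol[z, , ] + plane
    vol
  }
  vol_rib <- .apply_noise(add_bg(vol_rib), spec$noise)
  vol_psd <- .apply_noise(add_bg(vol_psd), spec$noise)
  if (!is.null(vol_ch3)) vol_ch3 <- .apply_noise(add_bg(vol_ch3), spec$noise)

  synaptic <- c(seq_len(n_rib) %in% paired_idx, rep(FALSE, spec$n_extrasynaptic))
  puncta <- data.frame(
    id = c(seq_len(n_total_sites), seq_len(n_paired)),
    channel = c(rep("ribbon", n_total_sites), rep("psd", n_paired)),
    z = c(sites[, 1], psd_pos[, 1]),
    y = c(sites[, 2], psd_pos[, 2]),
    x = c(sites[, 3], psd_pos[, 3]),
    area_true = c(all_area, psd_area),
    total_intensity_true = c(tot_rib, tot_psd),
    synaptic = c(synaptic, rep(TRUE, n_paired)),
    cell = c(cell_of, cell_of[paired_idx]))
  pairs <- data.frame(ribbon_id = paired_idx,
                      psd_id = seq_len(n_paired),
                      gap = gaps)

  channels <- list(ribbon = volume_stack(vol_rib, vox, "ribbon"),
                   psd = volume_stack(vol_psd, vox, "psd"))
  if (!is.null(vol_ch3))
    channels$channel3 <- volume_stack(vol_ch3, vox, "channel3")
  list(channels = channels,
       truth = list(puncta = puncta, pairs = pairs, spec = spec))
}

# ---- fluorescence trace phantoms --------------------------------------

#' Specification of simulated fluorescence traces
#'
#' Parameters for evoked and spontaneous trace phantoms. Each channel has
#' single-exponential rise/decay kinetics; evoked responses follow the
#' stimulus (saturating rise toward `plateau` while the stimulus is on,
#' exponential return after it ends), spontaneous events use a
#' difference-of-exponentials kernel normalized to unit peak. Defaults
#' mirror a fast cytosolic indicator (0.06 s rise, return to baseline
#' within ~12 s) and a slow mitochondrial one (detectable rise within
#' ~0.6 s, ~5 min return).
#'
#' @param frame_rate Hz (> 0).
#' @param duration recording length, s (> 0).
#' @param stimulus_windows list of `c(start, end)` s (evoked only).
#' @param baseline_F baseline fluorescence, AU (> 0).
#' @param channels named list; each entry `list(rise =, decay =,
#'   plateau =)` with time constants in s and plateau in dF/F0 units.
#' @param event_rate spontaneous events per second per cell (>= 0).
#' @param n_events if not `NULL`, plant exactly this many events per cell
#'   instead of drawing a Poisson count.
#' @param amplitude `c(mean, sd)` of spontaneous event dF/F0 amplitudes
#'   (negatives are redrawn as their absolute value).
#' @param coupling fraction in `[0, 1]` of events shared between the two
#'   channels at identical times.
#' @param bleach_tau photobleaching time constant, s (`Inf` = none);
#'   multiplies the whole trace by `exp(-t / bleach_tau)`.
#' @param noise_sd additive Gaussian noise sd, AU.
#' @param n_cells number of cells/ROIs.
#' @param seed integer RNG seed.
#' @return A list of class `TraceSimSpec`.
#' @export
trace_sim_spec <- function(frame_rate = 10,
                           duration = 30,
                           stimulus_windows = list(c(10, 12)),
                           baseline_F = 100,
                           channels = list(
                             cyto = list(rise = 0.06, decay = 3, plateau = 0.5),
                             mito = list(rise = 1.5, decay = 100, plateau = 0.3)),
                           event_rate = 0.01,
                           n_events = NULL,
                           amplitude = c(0.5, 0.1),
                           coupling = 0,
                           bleach_tau = Inf,
                           noise_sd = 0,
                           n_cells = 1,
                           seed = 1) {
  fail <- function(field, why) stop(sprintf("invalid '%s': %s", field, why))
  if (frame_rate <= 0) fail("frame_rate", "must be > 0")
  if (duration <= 0) fail("duration", "must be > 0")
  if (baseline_F <= 0) fail("baseline_F", "must be > 0")
  if (coupling < 0 || coupling > 1) fail("coupling", "must lie in [0, 1]")
  if (event_rate < 0) fail("event_rate", "must be >= 0")
  if (any(amplitude < 0)) fail("amplitude", "must be >= 0")
  if (bleach_tau <= 0) fail("bleach_tau", "must be > 0 (Inf disables)")
  for (w in stimulus_windows)
    if (length(w) != 2 || w[1] < 0 || w[2] <= w[1] || w[2] > duration)
      fail("stimulus_windows", "each window must satisfy 0 <= start < end <= duration")
  structure(as.list(environment())[setdiff(ls(), c("fail", "w"))],
            class = "TraceSimSpec")
}

#' Trace set container
#'
#' @param values numeric matrix, cells x frames, raw fluorescence AU.
#' @param frame_rate Hz.
#' @param stimulus_windows list of `c(start, end)` s.
#' @param channel channel tag.
#' @param cell_ids cell identifiers (default row numbers).
#' @return An object of class `TraceSet`.
#' @export
trace_set <- function(values, frame_rate, stimulus_windows = list(),
                      channel = "unknown", cell_ids = NULL) {
  values <- rbind(values)
  if (frame_rate <= 0) stop("'frame_rate' must be > 0")
  dur <- ncol(values) / frame_rate
  for (w in stimulus_windows)
    if (w[2] > dur) stop("stimulus window extends beyond the recording")
  if (is.null(cell_ids)) cell_ids <- seq_len(nrow(values))
  structure(list(values = values, frame_rate = frame_rate,
                 stimulus_windows = stimulus_windows,
                 channel = channel, cell_ids = cell_ids),
            class = "TraceSet")
}

# stimulus-driven response: saturating rise during each window,
# exponential decay after it ends
.evoked_response <- function(t, windows, rise, decay, plateau) {
  r <- numeric(length(t))
  for (w in windows) {
    on <- t >= w[1] & t <= w[2]
    r[on] <- r[on] + plateau * (1 - exp(-(t[on] - w[1]) / rise))
    after <- t > w[2]
    peak <- plateau * (1 - exp(-(w[2] - w[1]) / rise))
    r[after] <- r[after] + peak * exp(-(t[after] - w[2]) / decay)
  }
  r
}

#' Simulate evoked fluorescence traces
#'
#' Noise-free model: `F(t) = baseline_F * (1 + response(t)) *
#' exp(-t / bleach_tau)`, where the response rises toward the channel
#' plateau while the stimulus is on and decays exponentially afterwards.
#' Additive Gaussian noise is applied last.
#'
#' @param spec a [trace_sim_spec()] with at least one stimulus window.
#' @return A list with `traces` (named list of [trace_set()], one per
#'   channel) and `truth` (data frame: cell, channel, `peak_dff` = true
#'   noise-free peak dF/F0).
#' @export
simulate_evoked_traces <- function(spec) {
  stopifnot(inherits(spec, "TraceSimSpec"))
  if (length(spec$stimulus_windows) == 0)
    stop("evoked simulation needs at least one stimulus window")
  set.seed(spec$seed)
  n <- floor(spec$duration * spec$frame_rate)
  t <- (seq_len(n) - 1) / spec$frame_rate
  bleach <- if (is.finite(spec$bleach_tau)) exp(-t / spec$bleach_tau) else rep(1, n)
  traces <- list(); truth <- list()
  for (ch in names(spec$channels)) {
    k <- spec$channels[[ch]]
    resp <- .evoked_response(t, spec$stimulus_windows, k$rise, k$decay, k$plateau)
    vals <- matrix(rep(spec$baseline_F * (1 + resp) * bleach, spec$n_cells),
                   nrow = spec$n_cells, byrow = TRUE)
    if (spec$noise_sd > 0)
      vals <- vals + matrix(stats::rnorm(length(vals), 0, spec$noise_sd),
                            nrow = spec$n_cells)
    traces[[ch]] <- trace_set(vals, spec$frame_rate, spec$stimulus_windows, ch)
    truth[[ch]] <- data.frame(cell = seq_len(spec$n_cells), channel = ch,
                              peak_dff = max(resp))
  }
  list(traces = traces, truth = do.call(rbind, truth))
}

# difference-of-exponentials event kernel, normalized to unit peak
.event_kernel <- function(t, rise, decay) {
  if (rise >= decay) rise <- decay * 0.99
  k <- exp(-t / decay) - exp(-t / rise)
  tpk <- log(decay / rise) / (1 / rise - 1 / decay)
  k / (exp(-tpk / decay) - exp(-tpk / rise))
}

#' Simulate spontaneous two-channel fluorescence traces
#'
#' Events are drawn per cell as a Poisson process of rate `event_rate`
#' (or exactly `n_events` well-separated planted events when that field
#' is set). A fraction `coupling` of events is shared between the first
#' two channels at identical times; the remainder is channel-specific.
#' Each event adds an `amplitude x` unit-peak difference-of-exponentials
#' transient to the dF/F0 response; the trace is `baseline_F * (1 +
#' response) * exp(-t / bleach_tau)` plus Gaussian noise.
#'
#' @param spec a [trace_sim_spec()].
#' @return A list with `traces` (named list of [trace_set()]) and
#'   `truth$events` (data frame: cell, channel, time s, amplitude dF/F0).
#' @export
simulate_spontaneous_traces <- function(spec) {
  stopifnot(inherits(spec, "TraceSimSpec"))
  set.seed(spec$seed)
  n <- floor(spec$duration * spec$frame_rate)
  t <- (seq_len(n) - 1) / spec$frame_rate
  bleach <- if (is.finite(spec$bleach_tau)) exp(-t / spec$bleach_tau) else rep(1, n)
  chn <- names(spec$channels)

  # planted events (n_events set): one per stratum, guaranteeing a
  # minimum separation of half the stratum width; Poisson-rate events:
  # plain uniform order statistics (a Poisson process given its count)
  planted <- !is.null(spec$n_events)
  draw_times <- function(n_ev) {
    if (n_ev == 0) return(numeric(0))
    lo <- 0.02 * spec$duration; hi <- 0.95 * spec$duration
    if (!planted) return(sort(stats::runif(n_ev, lo, hi)))
    w <- (hi - lo) / n_ev
    min_sep <- min(w / 2, 60)
    lo + (seq_len(n_ev) - 1) * w + stats::runif(n_ev, 0, w - min_sep)
  }
  events <- list()
  for (cell in seq_len(spec$n_cells)) {
    n_tot <- if (!is.null(spec$n_events)) spec$n_events
             else stats::rpois(1, spec$event_rate * spec$duration)
    n_shared <- round(spec$coupling * n_tot)
    t_shared <- draw_times(n_shared)
    a_shared <- abs(stats::rnorm(n_shared, spec$amplitude[1], spec$amplitude[2]))
    for (ch in chn) {
      n_own <- n_tot - n_shared
      t_own <- draw_times(n_own)
      a_own <- abs(stats::rnorm(n_own, spec$amplitude[1], spec$amplitude[2]))
      o <- order(c(t_shared, t_own))
      tt <- c(t_shared, t_own)[o]
      if (length(tt) == 0) next
      events[[length(events) + 1L]] <-
        data.frame(cell = cell, channel = ch, time = tt,
                   amplitude = c(a_shared, a_own)[o])
    }
  }
  ev <- if (length(events)) do.call(rbind, events)
        else data.frame(cell = integer(), channel = character(),
                        time = numeric(), amplitude = numeric())

  traces <- list()
  for (ch in chn) {
    k <- spec$channels[[ch]]
    vals <- matrix(0, spec$n_cells, n)
    for (cell in seq_len(spec$n_cells)) {
      resp <- numeric(n)
      sel <- ev$cell == cell & ev$channel == ch
      for (j in which(sel)) {
        after <- t >= ev$time[j]
        resp[after] <- resp[after] +
          ev$amplitude[j] * .event_kernel(t[after] - ev$time[j], k$rise, k$decay)
      }
      vals[cell, ] <- spec$baseline_F * (1 + resp) * bleach
    }
    if (spec$noise_sd > 0)
      vals <- vals + matrix(stats::rnorm(length(vals), 0, spec$noise_sd),
                            nrow = spec$n_cells)
    traces[[ch]] <- trace_set(vals, spec$frame_rate, list(), ch)
  }
  list(traces = traces, truth = list(events = ev))
}

#' Simulate a four-parameter logistic dose--response table
#'
#' `response(d) = bottom + (top - bottom) / (1 + (d / ic50)^hill)` plus
#' optional Gaussian noise; at `d = 0` the response equals `top` and at
#' `d = ic50` the midpoint `(top + bottom) / 2`.
#'
#' @param ic50 half-maximal inhibitory concentration, uM (> 0).
#' @param hill Hill slope (> 0).
#' @param bottom,top response asymptotes.
#' @param doses uM concentrations (>= 0).
#' @param noise_sd Gaussian noise sd in response units.
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @return Data frame with columns `dose` and `response`.
#' @export
simulate_dose_response <- function(ic50, hill = 1, bottom = 0, top = 1,
                                   doses = c(0, 0.5, 2, 5, 10),
                                   noise_sd = 0, seed = 1) {
  if (ic50 <= 0) stop("'ic50' must be positive")
  if (any(doses < 0)) stop("'doses' must be >= 0")
  resp <- bottom + (top - bottom) / (1 + (doses / ic50)^hill)
  if (noise_sd > 0) {
    set.seed(seed)
    resp <- resp + stats::rnorm(length(doses), 0, noise_sd)
  }
  data.frame(dose = doses, response = resp)
}
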