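#' Translation registration of a time series
#'
#' Estimates an integer-pixel `(dy, dx)` shift for every frame against
#' the first frame by maximizing the cross-correlation (computed via
#' FFT), then applies the inverse shift. Among equal correlation maxima
#' the smallest shift magnitude wins, so constant frames register at
#' `(0, 0)`.
#'
#' @param movie numeric array `[frame, y, x]` with at least 2 frames.
#' @return A list with `movie` (aligned, edge pixels replicated) and
#'   `shifts` (frames x 2 matrix of the estimated `(dy, dx)` drift of
#'   each frame relative to frame 1; the inverse shift is applied).
#' @export
register_translation <- function(movie) {
  d <- dim(movie)
  if (length(d) != 3 || d[1] < 2)
    stop("'movie' must be a [frame, y, x] array with >= 2 frames")
  ref <- movie[1, , ]
  ref0 <- ref - mean(ref)
  fref <- stats::fft(ref0)
  ny <- d[2]; nx <- d[3]
  # candidate shifts in FFT order, wrapped to the centered range
  wrap <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  sy <- wrap(seq_len(ny), ny); sx <- wrap(seq_len(nx), nx)
  penalty <- outer(sy^2, sx^2, "+")  # tie-break toward zero shift
  shifts <- matrix(0L, d[1], 2)
  out <- movie
  for (f in 2:d[1]) {
    fr <- movie[f, , ]
    fr0 <- fr - mean(fr)
    if (sum(fr0^2) == 0 || sum(ref0^2) == 0) next
    cc <- Re(stats::fft(fref * Conj(stats::fft(fr0)), inverse = TRUE))
    best <- which(cc >= max(cc) - 1e-9 * abs(max(cc)))
    best <- best[which.min(penalty[best])]
    iy <- (best - 1) %% ny + 1; ix <- (best - 1) %/% ny + 1
    dyx <- -c(wrap(iy, ny), wrap(ix, nx))  # estimated drift vs frame 1
    shifts[f, ] <- as.integer(dyx)
    src_y <- pmin(pmax(seq_len(ny) + dyx[1], 1), ny)
    src_x <- pmin(pmax(seq_len(nx) + dyx[2], 1), nx)
    out[f, , ] <- fr[src_y, src_x]
  }
  list(movie = out, shifts = shifts)
}

#' Mean-intensity trace inside a circular ROI
#'
#' Draws a circle of the given physical diameter at `center` and returns
#' the per-frame mean intensity over pixels whose *centers* fall inside
#' the circle (pixel `(i, j)` has center `((i - 0.5) * px, (j - 0.5) *
#' px)` um), the convention that makes ROI pixel counts reproducible.
#'
#' @param movie numeric array `[frame, y, x]`.
#' @param center `c(y, x)` circle center in um.
#' @param diameter circle diameter in um.
#' @param pixel_size um per pixel (`c(y, x)` or a scalar).
#' @return Numeric vector, one mean per frame.
#' @export
roi_trace <- function(movie, center, diameter, pixel_size) {
  d <- dim(movie)
  if (length(d) != 3) stop("'movie' must be a [frame, y, x] array")
  pixel_size <- rep(pixel_size, length.out = 2)
  yc <- (seq_len(d[2]) - 0.5) * pixel_size[1]
  xc <- (seq_len(d[3]) - 0.5) * pixel_size[2]
  inside <- outer((yc - center[1])^2, (xc - center[2])^2, "+") <=
    (diameter / 2)^2
  if (!any(inside))
    stop("ROI contains no pixel centers: diameter smaller than one pixel?")
  r <- diameter / 2
  if (center[1] - r < 0 || center[2] - r < 0 ||
      center[1] + r > d[2] * pixel_size[1] ||
      center[2] + r > d[3] * pixel_size[2])
    stop("ROI circle extends outside the image")
  idx <- which(inside)
  apply(movie, 1, function(fr) mean(fr[idx]))
}

#' Evoked dF/F0 analysis of a trace set
#'
#' `F0` is the mean fluorescence over the pre-stimulus window; the trace
#' is converted to `dF/F0 = (F - F0) / F0`; the peak is the maximum over
#' all frames from stimulus onset to the end of the recording. A cell is
#' classified active when its peak *exceeds* (strictly) the channel's
#' activity threshold: 0.25 for the presynaptic membrane indicator
#' (GCaMP6sCAAX), 0.05 for the mitochondrial indicators.
#'
#' @param traces a [trace_set()].
#' @param prestim_window `c(start, end)` s; must end by the first
#'   stimulus onset.
#' @param threshold activity threshold in dF/F0 units; the default picks
#'   0.05 for channels tagged `mito`-like, else 0.25.
#' @return A data frame per cell: `cell`, `F0`, `peak`, `active`,
#'   `threshold_used`, plus attribute `dff` (cells x frames matrix).
#' @export
evoked_dff <- function(traces, prestim_window = NULL, threshold = NULL) {
  stopifnot(inherits(traces, "TraceSet"))
  if (length(traces$stimulus_windows) == 0)
    stop("trace set has no stimulus windows")
  onset <- min(vapply(traces$stimulus_windows, `[`, numeric(1), 1))
  if (is.null(prestim_window)) prestim_window <- c(0, onset)
  if (prestim_window[2] > onset + 1e-9)
    stop("pre-stimulus window must end by the first stimulus onset")
  n <- ncol(traces$values)
  t <- (seq_len(n) - 1) / traces$frame_rate
  pre <- t >= prestim_window[1] & t < prestim_window[2]
  if (!any(pre)) stop("pre-stimulus window contains no frames")
  if (is.null(threshold))
    threshold <- if (grepl("mito", traces$channel, ignore.case = TRUE))
      0.05 else 0.25
  F0 <- rowMeans(traces$values[, pre, drop = FALSE])
  if (any(F0 <= 0)) stop("non-positive F0 in pre-stimulus window")
  dff <- sweep(sweep(traces$values, 1, F0, "-"), 1, F0, "/")
  post <- t >= onset
  peak <- apply(dff[, post, drop = FALSE], 1, max)
  res <- data.frame(cell = traces$cell_ids, F0 = F0, peak = peak,
                    active = peak > threshold, threshold_used = threshold)
  attr(res, "dff") <- dff
  res
}

#' Spatial dF map of a movie
#'
#' Computes the per-pixel baseline image `F0` (mean of the pre-stimulus
#' frames), subtracts it from every subsequent frame, and bins the
#' resulting dF images temporally (mean of `bin` consecutive frames).
#' The returned scaling record supports color-map encoding.
#'
#' @param movie numeric array `[frame, y, x]`.
#' @param frame_rate Hz.
#' @param prestim_window `c(start, end)` s defining the baseline frames.
#' @param bin frames per temporal bin (>= 1).
#' @return A list with `dF` (array `[bin, y, x]`), `F0` (matrix), and
#'   `scale` = `c(min, max)` of the dF values.
#' @export
dff_map <- function(movie, frame_rate, prestim_window, bin = 1) {
  d <- dim(movie)
  t <- (seq_len(d[1]) - 1) / frame_rate
  pre <- t >= prestim_window[1] & t < prestim_window[2]
  if (!any(pre)) stop("pre-stimulus window contains no frames")
  post <- which(!pre & t >= prestim_window[2])
  if (bin > length(post)) stop("'bin' exceeds the post-baseline frame count")
  F0 <- apply(movie[pre, , , drop = FALSE], c(2, 3), mean)
  n_bins <- length(post) %/% bin
  dF <- array(0, c(n_bins, d[2], d[3]))
  for (b in seq_len(n_bins)) {
    fr <- post[((b - 1) * bin + 1):(b * bin)]
    m <- apply(movie[fr, , , drop = FALSE], c(2, 3), mean)
    dF[b, , ] <- m - F0
  }
  list(dF = dF, F0 = F0, scale = range(dF))
}

#' Photobleaching correction of a fluorescence trace
#'
#' Fits a mono-exponential-plus-offset bleaching model `a * exp(-t /
#' tau) + c` to the trace, iteratively masking samples more than 2
#' robust standard deviations above the fit (transient events must not
#' bias the baseline), and divides the trace by the fitted curve
#' normalized to its value at `t = 0`. Division preserves dF/F0 ratios;
#' an already-flat trace changes by well under 1%. If the fit cannot
#' converge the trace is returned unchanged with `corrected = FALSE`.
#'
#' @param trace numeric vector (>= 20 frames).
#' @param frame_rate Hz.
#' @return A list with `trace` (corrected), `fit` (fitted bleach curve),
#'   `tau`, and `corrected` (logical).
#' @export
bleach_correct <- function(trace, frame_rate = 1) {
  n <- length(trace)
  if (n < 20) stop("bleach correction needs at least 20 frames")
  t <- (seq_len(n) - 1) / frame_rate
  keep <- rep(TRUE, n)
  fit_vals <- NULL; tau <- NA_real_
  for (iter in 1:6) {
    df <- data.frame(t = t[keep], y = trace[keep])
    f <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(-t / tau) + c0, data = df,
                        start = list(a = max(diff(range(trace)), 1e-6),
                                     tau = max(t) / 2,
                                     c0 = min(trace)),
                        lower = c(a = 0, tau = max(t) / 1e4, c0 = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(f)) break
    cf <- stats::coef(f)
    fit_vals <- cf[["a"]] * exp(-t / cf[["tau"]]) + cf[["c0"]]
    tau <- cf[["tau"]]
    resid <- trace - fit_vals
    s <- stats::mad(resid[keep])
    if (s <= 0) break
    new_keep <- resid <= 2 * s
    if (all(new_keep == keep)) break
    keep <- new_keep
    if (sum(keep) < 10) break
  }
  if (is.null(fit_vals) || fit_vals[1] <= 0)
    return(list(trace = trace, fit = rep(NA_real_, n), tau = NA_real_,
                corrected = FALSE))
  list(trace = trace / (fit_vals / fit_vals[1]), fit = fit_vals,
       tau = tau, corrected = TRUE)
}

# local maxima of a vector above a height, with minimum separation
# (greedy, larger peaks first) and minimum prominence relative to the
# surrounding minima
.find_peaks <- function(x, min_height, min_sep = 3, min_prom = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n] &
                x[2:(n - 1)] > min_height) + 1L
  # drop plateau duplicates: keep the first index of any run
  if (length(cand) > 1)
    cand <- cand[c(TRUE, diff(cand) > 1 | x[cand[-1]] != x[cand[-length(cand)]])]
  if (min_prom > 0 && length(cand)) {
    prom_ok <- vapply(cand, function(i) {
      left <- min(x[max(1, i - 50):i]); right <- min(x[i:min(n, i + 50)])
      x[i] - max(left, right) >= min_prom
    }, logical(1))
    cand <- cand[prom_ok]
  }
  if (length(cand) <= 1) return(cand)
  o <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in o)
    if (!length(kept) || min(abs(kept - i)) >= min_sep) kept <- c(kept, i)
  sort(kept)
}

#' Spontaneous activity statistics of a trace
#'
#' Baseline `F0` is the bottom 15th percentile of the (bleach-corrected)
#' fluorescence values; `dF/F0` samples below the noise threshold
#' (default 10%) are zeroed; the per-cell magnitude is the sum of the
#' remaining `dF/F0` divided by the number of frames; events are local
#' maxima of the thresholded `dF/F0` (minimum separation 3 frames,
#' minimum prominence equal to the noise threshold) and the frequency is
#' their count divided by the recording duration.
#'
#' @param trace numeric vector of bleach-corrected fluorescence (AU).
#' @param frame_rate Hz.
#' @param noise_threshold dF/F0 below which samples count as noise.
#' @param percentile baseline percentile (default 0.15).
#' @param percentile_mode `"value"` for the percentile value (linear
#'   interpolation), `"mean_below"` for the mean of the lowest
#'   `percentile` fraction of samples.
#' @return A list: `F0`, `dff` (thresholded dF/F0 vector), `magnitude`,
#'   `frequency` (Hz), `event_times` (s), `event_amplitudes` (dF/F0).
#' @export
spontaneous_stats <- function(trace, frame_rate, noise_threshold = 0.10,
                              percentile = 0.15,
                              percentile_mode = c("value", "mean_below")) {
  percentile_mode <- match.arg(percentile_mode)
  n <- length(trace)
  if (n == 0) stop("empty trace")
  F0 <- if (percentile_mode == "value")
    stats::quantile(trace, percentile, names = FALSE)
  else mean(sort(trace)[seq_len(max(1, floor(percentile * n)))])
  if (F0 <= 0) stop("non-positive F0 baseline")
  dff <- (trace - F0) / F0
  dff[dff < noise_threshold] <- 0
  peaks <- .find_peaks(dff, min_height = noise_threshold, min_sep = 3,
                       min_prom = noise_threshold)
  duration <- n / frame_rate
  list(F0 = F0,
       dff = dff,
       magnitude = sum(dff) / n,
       frequency = length(peaks) / duration,
       event_times = (peaks - 1) / frame_rate,
       event_amplitudes = dff[peaks])
}

#' Pearson correlation matrix between two trace sets
#'
#' Correlates every cell of `setA` with every cell of `setB` over
#' frames. Zero-variance traces yield `NA` entries (flagged, never
#' silently zero).
#'
#' @param setA,setB [trace_set()] objects with equal frame counts.
#' @return Numeric matrix (`cells_A` x `cells_B`) of Pearson r in
#'   `[-1, 1]`, with `NA` for undefined entries.
#' @export
pearson_matrix <- function(setA, setB) {
  stopifnot(inherits(setA, "TraceSet"), inherits(setB, "TraceSet"))
  if (ncol(setA$values) != ncol(setB$values))
    stop("trace sets differ in frame count")
  a <- t(setA$values); b <- t(setB$values)
  sd0a <- apply(a, 2, stats::sd) == 0
  sd0b <- apply(b, 2, stats::sd) == 0
  r <- suppressWarnings(stats::cor(a, b))
  r[sd0a, ] <- NA_real_
  r[, sd0b] <- NA_real_
  rownames(r) <- setA$cell_ids; colnames(r) <- setB$cell_ids
  r
}

#' Normalize post-treatment intensities to mock-treated controls
#'
#' Mock-treated controls imaged in every trial estimate the
#' photobleaching that accrues between the pre and post measurements;
#' each treated neuromast's post/pre ratio is divided by the mean mock
#' post/pre ratio, so the mock set's own mean normalized change is 1 by
#' construction.
#'
#' @param treated,mock data frames with columns `pre` and `post`
#'   (intensities, `pre > 0`); `mock` must be non-empty.
#' @return `treated` with an added `normalized_change` column.
#' @export
normalize_to_mock <- function(treated, mock) {
  if (NROW(mock) == 0) stop("mock control set must be non-empty")
  if (any(treated$pre <= 0) || any(mock$pre <= 0))
    stop("all 'pre' intensities must be positive")
  mock_mean <- mean(mock$post / mock$pre)
  treated$normalized_change <- (treated$post / treated$pre) / mock_mean
  treated
}

#' Average intensity over replicate stacks
#'
#' Arithmetic mean of the per-stack intensities acquired at one time
#' point (the study averaged 4 z-stacks per time point).
#'
#' @param intensities non-empty numeric vector (AU).
#' @return The mean intensity.
#' @export
average_replicate_stacks <- function(intensities) {
  if (length(intensities) == 0) stop("no intensities to average")
  mean(intensities)
}

#' Four-parameter logistic (variable-slope) dose--response fit
#'
#' Least-squares fit of `response = bottom + (top - bottom) / (1 +
#' (dose / ic50)^hill)`, the 4PL model with variable slope, yielding the
#' IC50. Starting values come from the data extremes and the dose whose
#' response is nearest the midpoint; dose 0 is handled by the model's
#' closed form (`0^hill = 0`, so the response at dose 0 is `top`).
#'
#' @param doses uM concentrations (>= 4 distinct values).
#' @param responses observed responses, same length.
#' @return A list of class `DoseResponseFit`: `ic50`, `hill`, `bottom`,
#'   `top`, `fitted`, `residual_norm`, `degenerate` (TRUE when the
#'   responses carry no dose information), `converged`.
#' @export
fit_4pl <- function(doses, responses) {
  if (length(doses) != length(responses))
    stop("'doses' and 'responses' must have equal length")
  if (length(unique(doses)) < 4)
    stop("need at least 4 distinct doses")
  if (stats::sd(responses) == 0 ||
      stats::sd(tapply(responses, doses, mean)) < 1e-12 * max(abs(responses), 1)) {
    return(structure(list(ic50 = NA_real_, hill = NA_real_,
                          bottom = NA_real_, top = NA_real_,
                          fitted = rep(mean(responses), length(doses)),
                          residual_norm = 0, degenerate = TRUE,
                          converged = FALSE),
                     class = "DoseResponseFit"))
  }
  top0 <- mean(responses[doses == min(doses)])
  bot0 <- mean(responses[doses == max(doses)])
  mid <- (top0 + bot0) / 2
  pos <- doses > 0
  ic0 <- doses[pos][which.min(abs(responses[pos] - mid))]
  if (!is.finite(ic0) || ic0 <= 0) ic0 <- stats::median(doses[pos])
  df <- data.frame(d = doses, y = responses)
  f <- tryCatch(
    minpack.lm::nlsLM(y ~ bottom + (top - bottom) / (1 + (d / ic50)^hill),
                      data = df,
                      start = list(bottom = bot0, top = top0,
                                   ic50 = ic0, hill = 1),
                      lower = c(bottom = -Inf, top = -Inf,
                                ic50 = 1e-6, hill = 0.05),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(f, "error"))
    stop("4PL fit failed to converge: ", conditionMessage(f))
  cf <- stats::coef(f)
  fitted <- cf[["bottom"]] + (cf[["top"]] - cf[["bottom"]]) /
    (1 + (doses / cf[["ic50"]])^cf[["hill"]])
  structure(list(ic50 = cf[["ic50"]], hill = cf[["hill"]],
                 bottom = cf[["bottom"]], top = cf[["top"]],
                 fitted = fitted,
                 residual_norm = sqrt(sum((responses - fitted)^2)),
                 degenerate = FALSE, converged = TRUE),
            class = "DoseResponseFit")
}

#' @export
print.DoseResponseFit <- function(x, ...) {
  if (x$degenerate) {
    cat("DoseResponseFit: degenerate (responses carry no dose information)\n")
  } else {
    cat(sprintf(
      "DoseResponseFit: IC50 = %.4g uM, hill = %.3g, top = %.4g, bottom = %.4g\n",
      x$ic50, x$hill, x$top, x$bottom))
  }
  invisible(x)
}
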