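#' Pipeline configuration
#'
#' Reads a YAML configuration for the end-to-end commands. Recognized
#' sections: `phantom` (fields of [image_phantom_spec()]), `traces`
#' (fields of [trace_sim_spec()]), `segmentation` (per-channel
#' [segmentation_params()] fields under `ribbon` / `psd`),
#' `dose_response` (fields of [simulate_dose_response()]), plus
#' top-level `seed` and `out_dir`. CLI-style overrides replace
#' top-level entries.
#'
#' @param path YAML file path, or `NULL` for an all-defaults config.
#' @param overrides named list merged over the file contents.
#' @return A named list of class `PipelineConfig`.
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  }
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$out_dir)) cfg$out_dir <- "."
  structure(cfg, class = "PipelineConfig")
}

.cfg_call <- function(fun, args, extra = list()) {
  if (is.null(args)) args <- list()
  args <- args[intersect(names(args), names(formals(fun)))]
  do.call(fun, utils::modifyList(as.list(args), extra))
}

#' Simulate phantom fixtures and write them to disk
#'
#' Renders the configured image phantom and trace phantoms, writing TIFF
#' stacks (with metadata sidecars), trace CSVs and ground-truth CSV
#' tables into `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the simulated objects and the written
#'   file paths.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  spec <- .cfg_call(image_phantom_spec, c(config$phantom),
                    list(seed = config$seed))
  sim <- simulate_stack(spec)
  paths <- character(0)
  for (ch in names(sim$channels)) {
    p <- file.path(out, paste0("stack_", ch, ".tif"))
    write_stack(sim$channels[[ch]], p)
    paths <- c(paths, p)
  }
  .write_table(sim$truth$puncta, file.path(out, "truth_puncta.csv"),
               config$seed, config)
  .write_table(sim$truth$pairs, file.path(out, "truth_pairs.csv"),
               config$seed, config)

  tspec <- .cfg_call(trace_sim_spec, c(config$traces),
                     list(seed = config$seed))
  sp <- simulate_spontaneous_traces(tspec)
  for (ch in names(sp$traces)) {
    p <- file.path(out, paste0("traces_spontaneous_", ch, ".csv"))
    write_traces(sp$traces[[ch]], p)
    paths <- c(paths, p)
  }
  .write_table(sp$truth$events, file.path(out, "truth_events.csv"),
               config$seed, config)
  invisible(list(stack = sim, spontaneous = sp, paths = paths))
}

#' Run the morphology pipeline on a multi-channel stack
#'
#' Composes the full synapse-morphology quantification: rolling-ball
#' background subtraction on every channel, band-pass on the PSD
#' channel, 3D segmentation of both channels, the per-channel minimum
#' area filter (ribbon 0.08 um^2, PSD 0.04 um^2), radius-sum pairing,
#' the extrasynaptic ribbon count from an unfiltered ribbon pass, and --
#' when a third channel is present -- the integrated channel-3 intensity
#' inside each ribbon footprint. Writes punctum, pair, summary and
#' channel-3 CSV tables.
#'
#' @param config a [pipeline_config()]; either `config$channels` (named
#'   list of [volume_stack()]: `ribbon`, `psd`, optional `channel3`) or
#'   `config$inputs` (named list of TIFF paths read via [read_stack()]).
#' @return Invisibly, a list: `puncta` (named list of data frames),
#'   `pairs`, `summary`, `channel3_intensity`.
#' @export
run_morphology <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  channels <- config$channels
  if (is.null(channels)) {
    if (is.null(config$inputs)) stop("config lacks 'channels' and 'inputs'")
    channels <- lapply(config$inputs, read_stack)
  }
  for (need in c("ribbon", "psd"))
    if (is.null(channels[[need]]))
      stop("missing input channel: ", need)
  d1 <- dim(channels$ribbon$voxels)
  for (ch in names(channels))
    if (!all(dim(channels[[ch]]$voxels) == d1))
      stop("channel ", ch, " has inconsistent stack shape")

  seg_cfg <- config$segmentation
  par_rib <- .cfg_call(segmentation_params, c(seg_cfg$ribbon),
                       list(min_area = seg_cfg$ribbon$min_area %||% 0.08))
  par_psd <- .cfg_call(segmentation_params, c(seg_cfg$psd),
                       list(min_area = seg_cfg$psd$min_area %||% 0.04))

  rib_bg <- subtract_background(channels$ribbon, par_rib$rolling_ball_radius)
  psd_bg <- subtract_background(channels$psd, par_psd$rolling_ball_radius)
  psd_bp <- bandpass(psd_bg, par_psd$bandpass_small, par_psd$bandpass_large)

  seg_rib <- segment_puncta(rib_bg, par_rib)
  seg_psd <- segment_puncta(psd_bp, par_psd)
  rib <- apply_min_area(seg_rib$puncta, par_rib$min_area)
  psd <- apply_min_area(seg_psd$puncta, par_psd$min_area)

  paired <- pair_synapses(rib, psd)
  # extrasynaptic Ribeye: unpaired ribbon puncta with no size filter
  paired_all <- pair_synapses(seg_rib$puncta, psd)
  n_extra <- paired_all$summary$n_unpaired_ribbons

  ch3 <- NULL
  if (!is.null(channels$channel3) && nrow(rib) > 0) {
    ch3_bg <- subtract_background(channels$channel3,
                                  par_rib$rolling_ball_radius)
    vals <- roi_channel_intensity(seg_rib$labels, rib$id, ch3_bg)
    ch3 <- data.frame(ribbon_id = rib$id, channel3_intensity = vals)
  }

  summary_df <- data.frame(
    n_pairs = paired$summary$n_pairs,
    n_unpaired_ribbons = paired$summary$n_unpaired_ribbons,
    n_unpaired_psds = paired$summary$n_unpaired_psds,
    n_extrasynaptic_ribeye = n_extra)

  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  .write_table(rbind(rib, psd), file.path(out, "puncta.csv"),
               config$seed, config)
  .write_table(paired$pairs, file.path(out, "pairs.csv"),
               config$seed, config)
  .write_table(summary_df, file.path(out, "summary.csv"),
               config$seed, config)
  if (!is.null(ch3))
    .write_table(ch3, file.path(out, "channel3_intensity.csv"),
                 config$seed, config)
  invisible(list(puncta = list(ribbon = rib, psd = psd),
                 segmentation = list(ribbon = seg_rib, psd = seg_psd),
                 pairs = paired$pairs, summary = summary_df,
                 channel3_intensity = ch3))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the trace-analysis pipeline
#'
#' Simulates (or loads) evoked and spontaneous traces per the
#' configuration, then computes evoked dF/F0 classifications,
#' spontaneous magnitude/frequency statistics per cell, the two-channel
#' Pearson correlation matrix, and the configured dose--response fit.
#' All tables are written to `config$out_dir`.
#'
#' @param config a [pipeline_config()]; `config$trace_files` (named list
#'   of CSV paths) takes precedence over simulation.
#' @return Invisibly, a list: `evoked`, `spontaneous`, `correlation`,
#'   `dose_fit`.
#' @export
run_traces <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  tspec <- .cfg_call(trace_sim_spec, c(config$traces),
                     list(seed = config$seed))

  ev <- simulate_evoked_traces(tspec)
  evoked <- do.call(rbind, lapply(names(ev$traces), function(ch) {
    evoked_dff(ev$traces[[ch]])
  }))
  .write_table(evoked, file.path(out, "evoked.csv"), config$seed, config)

  if (!is.null(config$trace_files)) {
    spont_sets <- lapply(config$trace_files, read_traces)
  } else {
    spont_sets <- simulate_spontaneous_traces(tspec)$traces
  }
  spont <- do.call(rbind, lapply(names(spont_sets), function(ch) {
    ts <- spont_sets[[ch]]
    do.call(rbind, lapply(seq_len(nrow(ts$values)), function(i) {
      bc <- bleach_correct(ts$values[i, ], ts$frame_rate)
      st <- spontaneous_stats(bc$trace, ts$frame_rate)
      data.frame(channel = ch, cell = ts$cell_ids[i], F0 = st$F0,
                 magnitude = st$magnitude, frequency = st$frequency,
                 bleach_corrected = bc$corrected)
    }))
  }))
  .write_table(spont, file.path(out, "spontaneous.csv"),
               config$seed, config)

  corr <- NULL
  if (length(spont_sets) >= 2) {
    corr <- pearson_matrix(spont_sets[[1]], spont_sets[[2]])
    .write_table(as.data.frame(corr), file.path(out, "correlation.csv"),
                 config$seed, config)
  }

  dose_fit <- NULL
  dr <- config$dose_response
  if (!is.null(dr)) {
    tab <- .cfg_call(simulate_dose_response, c(dr),
                     list(seed = config$seed))
    dose_fit <- fit_4pl(tab$dose, tab$response)
    .write_table(data.frame(ic50 = dose_fit$ic50, hill = dose_fit$hill,
                            bottom = dose_fit$bottom, top = dose_fit$top,
                            residual_norm = dose_fit$residual_norm),
                 file.path(out, "dose_fit.csv"), config$seed, config)
  }
  invisible(list(evoked = evoked, spontaneous = spont,
                 correlation = corr, dose_fit = dose_fit))
}
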