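#' Write a volume stack as multi-page TIFF with sidecar metadata
#'
#' One z-slice per TIFF page. Intensities are stored scaled into `[0, 1]`
#' (32-bit float); the scale factor, voxel sizes and channel tag go to a
#' YAML sidecar (`<path>.yml`) so [read_stack()] restores the stack
#' exactly.
#'
#' @param stack a [volume_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "VolumeStack"))
  v <- stack$voxels
  lo <- min(v)
  scale <- max(max(v) - lo, 1e-12)
  pages <- lapply(seq_len(dim(v)[1]), function(z) (v[z, , ] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(voxel_size = as.list(stack$voxel_size),
               channel = stack$channel,
               intensity_offset = lo,
               intensity_scale = scale)
  yaml::write_yaml(meta, paste0(path, ".yml"))
  invisible(path)
}

#' Read a volume stack written by [write_stack()]
#'
#' @param path TIFF path; `<path>.yml` must exist alongside.
#' @return A [volume_stack()].
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("stack file not found: ", path)
  meta_path <- paste0(path, ".yml")
  if (!file.exists(meta_path))
    stop("metadata sidecar not found: ", meta_path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- yaml::read_yaml(meta_path)
  d <- c(length(pages), dim(pages[[1]]))
  v <- array(0, d)
  for (z in seq_along(pages))
    v[z, , ] <- pages[[z]] * meta$intensity_scale + meta$intensity_offset
  volume_stack(v, unlist(meta$voxel_size), meta$channel)
}

# short content hash (polynomial rolling hash over the deparsed object)
# for provenance headers
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# CSV with provenance comment header; read back with
# read.csv(..., comment.char = "#")
.write_table <- function(df, path, seed = NA, config = NULL) {
  if (!is.null(config)) {
    # hash only the parameter part of the config: output location and
    # in-memory data objects don't define the analysis
    config <- config[setdiff(names(config),
                             c("out_dir", "channels", "trace_files"))]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ribbonq %s seed=%s config=%s",
                     as.character(utils::packageVersion("ribbonq")),
                     seed,
                     if (is.null(config)) "-" else .config_hash(config)),
             con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write a trace set as CSV with metadata header
#'
#' Frames are rows, cells are columns; frame rate, channel and stimulus
#' windows are stored as `#`-comment header lines.
#'
#' @param traces a [trace_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  stopifnot(inherits(traces, "TraceSet"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# frame_rate: %.10g", traces$frame_rate),
               sprintf("# channel: %s", traces$channel),
               sprintf("# stimulus_windows: %s",
                       paste(vapply(traces$stimulus_windows,
                                    function(w) sprintf("%g-%g", w[1], w[2]),
                                    character(1)),
                             collapse = ";"))),
             con)
  df <- as.data.frame(t(traces$values))
  names(df) <- paste0("cell_", traces$cell_ids)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a trace set written by [write_traces()]
#'
#' @param path CSV path.
#' @return A [trace_set()].
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  get <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) return(NA_character_)
    trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
  }
  fr <- as.numeric(get("frame_rate"))
  ch <- get("channel")
  sw <- get("stimulus_windows")
  windows <- list()
  if (!is.na(sw) && nzchar(sw)) {
    for (tok in strsplit(sw, ";")[[1]])
      windows[[length(windows) + 1L]] <-
        as.numeric(strsplit(tok, "-")[[1]])
  }
  df <- utils::read.csv(path, comment.char = "#")
  if (nrow(df) == 0) stop("trace file contains no frames: ", path)
  ids <- sub("^cell_", "", names(df))
  trace_set(t(as.matrix(df)), fr, windows, ch, cell_ids = ids)
}
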