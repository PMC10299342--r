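#' Construct a video stack
#'
#' The raw analysis substrate: a `height x width x T` array of non-negative
#' intensities with its frame rate. Pixel coordinates are 1-based `(row, col)`
#' with rows increasing downward; frames are 1-based.
#'
#' @param data Numeric array with `dim = c(height, width, T)`, `T >= 2`, all
#'   values finite and non-negative.
#' @param frame_rate Frames per second (> 0).
#' @return An object of class `video_stack`.
#' @export
video_stack <- function(data, frame_rate) {
  if (!is.array(data) || length(dim(data)) != 3)
    fail_input("video data must be a 3-d array (height x width x frames)")
  if (dim(data)[3] < 2) fail_input("video must have at least 2 frames")
  if (!all(is.finite(data)) || min(data) < 0)
    fail_input("video intensities must be finite and >= 0")
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    fail_input("frame_rate must be > 0")
  structure(list(data = data, frame_rate = frame_rate), class = "video_stack")
}

#' @export
print.video_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("video_stack: %d x %d px, %d frames @ %g fps (%.2f s)\n",
              d[1], d[2], d[3], x$frame_rate, d[3] / x$frame_rate))
  invisible(x)
}

#' @export
dim.video_stack <- function(x) dim(x$data)

#' Write a video stack as multi-page 16-bit TIFF
#'
#' Intensities are rescaled to the 16-bit range on write; the scale factor
#' and frame rate are recorded in a YAML sidecar (`<path>.yaml`) so that
#' [read_stack()] restores the original values. Integer-valued stacks not
#' exceeding 65535 round-trip losslessly; other stacks are quantized to
#' 16 bits of their full range.
#'
#' @param video A [video_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(video, path) {
  stopifnot(inherits(video, "video_stack"))
  mx <- max(video$data)
  integral <- mx <= 65535 && all(video$data == round(video$data))
  scale <- if (integral) 65535 else if (mx > 0) mx else 1
  pages <- lapply(seq_len(dim(video$data)[3]),
                  function(t) video$data[, , t] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  yaml::write_yaml(list(frame_rate = video$frame_rate,
                        intensity_scale = scale),
                   sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".yaml")

#' Read a multi-page TIFF video stack
#'
#' @param path TIFF path. A YAML sidecar written by [write_stack()] supplies
#'   the frame rate and intensity scale; otherwise `frame_rate` must be given.
#' @param frame_rate Frames per second; overrides the sidecar when supplied.
#' @return A [video_stack()].
#' @export
read_stack <- function(path, frame_rate = NULL) {
  if (!file.exists(path)) fail_input("no such file: %s", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) fail_input("unreadable TIFF: %s", path))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2)
    fail_input("video stack must have at least 2 frames (got %d)", length(pages))
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    fail_input("inconsistent page shapes in %s", path)
  scale <- 1
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    meta <- yaml::read_yaml(sp)
    if (is.null(frame_rate)) frame_rate <- meta$frame_rate
    if (!is.null(meta$intensity_scale)) scale <- meta$intensity_scale
  }
  if (is.null(frame_rate))
    fail_input("frame_rate not supplied and no sidecar found for %s", path)
  data <- array(0, dim = c(dims[1, 1], dims[2, 1], length(pages)))
  for (t in seq_along(pages)) data[, , t] <- pages[[t]] * scale
  video_stack(data, frame_rate = frame_rate)
}

#' Write calcium traces to CSV
#'
#' Columns: `cell_id, frame, time_s, raw, dff` with `time_s = (frame-1) /
#' frame_rate`. Values are written as decimal text with full double
#' precision, so a round trip via [read_traces()] preserves them.
#'
#' @param traces A list of [calcium_trace()] objects sharing one frame rate.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (length(traces)) {
    frs <- vapply(traces, function(tr) tr$frame_rate, numeric(1))
    if (length(unique(frs)) != 1)
      fail_input("all traces must share one frame_rate")
    rows <- do.call(rbind, lapply(traces, function(tr) {
      n <- length(tr$raw)
      data.frame(cell_id = tr$cell_id, frame = seq_len(n),
                 time_s = (seq_len(n) - 1) / tr$frame_rate,
                 raw = tr$raw,
                 dff = if (is.null(tr$dff)) rep(NA_real_, n) else tr$dff)
    }))
  } else {
    rows <- data.frame(cell_id = integer(0), frame = integer(0),
                       time_s = numeric(0), raw = numeric(0),
                       dff = numeric(0))
  }
  utils::write.csv(format(rows, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read calcium traces written by [write_traces()]
#'
#' @param path CSV path.
#' @param frame_rate Frames per second of the recording.
#' @return A list of [calcium_trace()] objects, one per `cell_id`.
#' @export
read_traces <- function(path, frame_rate) {
  df <- utils::read.csv(path)
  need <- c("cell_id", "frame", "time_s", "raw", "dff")
  if (!all(need %in% names(df)))
    fail_input("trace CSV must have columns %s", paste(need, collapse = ","))
  lapply(split(df, df$cell_id), function(d) {
    d <- d[order(d$frame), ]
    dff <- if (all(is.na(d$dff))) NULL else d$dff
    calcium_trace(d$cell_id[1], raw = d$raw, frame_rate = frame_rate,
                  dff = dff)
  })
}

#' Read an animal presence/absence table
#'
#' Expects a CSV with columns `group` (one of `C`, `MP`, `MPC`), `timepoint`,
#' `animal`, `fluorescence_present` (logical or 0/1). Each
#' `(group, timepoint, animal)` key must be unique.
#'
#' @param path CSV path.
#' @return A validated `data.frame` with a logical `fluorescence_present`.
#' @export
read_presence_table <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("group", "timepoint", "animal", "fluorescence_present")
  if (!all(need %in% names(df)))
    fail_input("presence table must have columns %s", paste(need, collapse = ","))
  pres <- tolower(trimws(df$fluorescence_present))
  ok <- pres %in% c("true", "false", "1", "0")
  if (nrow(df) && !all(ok))
    fail_input("non-boolean fluorescence_present values: %s",
               paste(unique(df$fluorescence_present[!ok]), collapse = ", "))
  df$fluorescence_present <- pres %in% c("true", "1")
  key <- paste(df$group, df$timepoint, df$animal, sep = "\r")
  if (anyDuplicated(key))
    fail_input("duplicate (group, timepoint, animal) rows in %s", path)
  df
}

#' Write scene ground truth to plain-text files
#'
#' Writes `truth_cells.csv` (one row per cell per frame: `cell_id, frame,
#' row, col, label, event_flag`), `truth_systole.csv` (systole onset frames)
#' and `scene_config.yaml` (the resolved configuration) into `dir`.
#'
#' @param truth A `scene_truth` from [render_scene()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "scene_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(truth$cells)
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    ctr <- truth$centers[[i]]
    nf <- nrow(ctr)
    data.frame(cell_id = i, frame = seq_len(nf),
               row = ctr[, 1], col = ctr[, 2],
               label = truth$cells$label[i],
               event_flag = as.integer(seq_len(nf) %in% truth$event_onsets[[i]]))
  }))
  if (is.null(rows))
    rows <- data.frame(cell_id = integer(0), frame = integer(0),
                       row = numeric(0), col = numeric(0),
                       label = character(0), event_flag = integer(0))
  utils::write.csv(rows, file.path(dir, "truth_cells.csv"), row.names = FALSE)
  utils::write.csv(data.frame(onset_frame = truth$systole_onsets),
                   file.path(dir, "truth_systole.csv"), row.names = FALSE)
  cfg <- unclass(truth$config)
  yaml::write_yaml(cfg, file.path(dir, "scene_config.yaml"))
  invisible(dir)
}
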