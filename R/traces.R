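#' Construct a calcium trace
#'
#' @param cell_id Identifier.
#' @param raw Per-frame mean intensity within the tracked k x k window
#'   (`NA` where the trajectory was truncated).
#' @param frame_rate Frames per second.
#' @param dff Optional normalized dF/dF_max series (same length as `raw`,
#'   values in \[0, 1\] where defined).
#' @return An object of class `calcium_trace`.
#' @export
calcium_trace <- function(cell_id, raw, frame_rate, dff = NULL) {
  raw <- as.numeric(raw)
  if (frame_rate <= 0) fail_input("frame_rate must be > 0")
  if (!is.null(dff)) {
    dff <- as.numeric(dff)
    if (length(dff) != length(raw))
      fail_input("dff must have the same length as raw")
    dv <- dff[is.finite(dff)]
    if (length(dv) && (min(dv) < -1e-9 || max(dv) > 1 + 1e-9))
      fail_input("dff values must lie in [0, 1]")
  }
  structure(list(cell_id = cell_id, raw = raw, dff = dff,
                 frame_rate = frame_rate),
            class = "calcium_trace")
}

#' @export
print.calcium_trace <- function(x, ...) {
  cat(sprintf("calcium_trace: cell %s, %d frames @ %g fps%s\n",
              x$cell_id, length(x$raw), x$frame_rate,
              if (is.null(x$dff)) "" else ", dff normalized"))
  invisible(x)
}

#' Extract the mean-ROI calcium trace along a trajectory
#'
#' `raw[t]` is the mean of the k x k window at the trajectory's placement in
#' frame `t`. Frames from the trajectory's truncation point onward are
#' marked missing (`NA`).
#'
#' @param video A [video_stack()].
#' @param traj A [track_roi()] trajectory valid for this video.
#' @return A [calcium_trace()] with `raw` filled and `dff` unset.
#' @export
extract_trace <- function(video, traj) {
  stopifnot(inherits(video, "video_stack"), inherits(traj, "roi_trajectory"))
  d <- dim(video$data)
  n_frames <- d[3]
  if (nrow(traj$centers) != n_frames)
    fail_input("trajectory length (%d) does not match video (%d frames)",
               nrow(traj$centers), n_frames)
  raw <- vapply(seq_len(n_frames), function(t)
    roi_mean(video$data, traj$centers[t, 1], traj$centers[t, 2], t, traj$k),
    numeric(1))
  if (!is.na(traj$truncated_from))
    raw[seq(traj$truncated_from, n_frames)] <- NA_real_
  calcium_trace(traj$cell_id, raw, video$frame_rate)
}

#' Normalize a trace to dF/dF_max
#'
#' `F0` is the mean raw intensity over an explicit diastolic baseline window;
#' `dff = (raw - F0) / (max(raw) - F0)`, clipped below at 0 so the series
#' stays in \[0, 1\]. A flat trace (`max(raw) = F0`) maps to all zeros. The
#' result is invariant to affine rescaling `a * raw + b` (`a > 0`).
#'
#' @param trace A [calcium_trace()].
#' @param baseline_window 1-based frame indices of the diastolic baseline
#'   (e.g. the longest detected diastole, see [longest_diastole()]).
#' @return The trace with `dff` filled.
#' @export
normalize_dff <- function(trace, baseline_window) {
  stopifnot(inherits(trace, "calcium_trace"))
  baseline_window <- as.integer(baseline_window)
  if (!length(baseline_window) ||
      min(baseline_window) < 1 || max(baseline_window) > length(trace$raw))
    fail_input("baseline_window must be a nonempty set of frames inside the trace")
  f0_vals <- trace$raw[baseline_window]
  if (anyNA(f0_vals))
    fail_input("baseline_window contains missing raw values")
  f0 <- mean(f0_vals)
  fmax <- max(trace$raw, na.rm = TRUE)
  dff <- if (fmax > f0) pmax((trace$raw - f0) / (fmax - f0), 0)
  else rep(0, length(trace$raw))
  dff[is.na(trace$raw)] <- NA_real_
  calcium_trace(trace$cell_id, trace$raw, trace$frame_rate, dff = dff)
}

#' Global motion signal: normalized inter-frame absolute difference
#'
#' For each adjacent frame pair, `d[t] = sum(|frame(t+1) - frame(t)|)` over
#' all pixels (L1 norm), normalized by the maximum change between adjacent
#' frames in the video so that values lie in \[0, 1\]. A static video yields
#' all zeros. The growth of this derivative marks the beginning of systole.
#'
#' @param video A [video_stack()].
#' @param mask Optional logical `height x width` matrix restricting the sum
#'   to a sub-region (default: whole frame).
#' @return An object of class `global_motion_signal`: list with `values`
#'   (length `T - 1`), `raw` (unnormalized sums) and `frame_rate`.
#' @export
global_frame_derivative <- function(video, mask = NULL) {
  stopifnot(inherits(video, "video_stack"))
  d <- dim(video$data)
  if (!is.null(mask)) {
    if (!identical(dim(mask), d[1:2]))
      fail_input("mask must match the frame size")
    mask <- as.logical(mask)
  }
  n <- d[3] - 1L
  raw <- numeric(n)
  for (t in seq_len(n)) {
    df <- abs(video$data[, , t + 1L] - video$data[, , t])
    raw[t] <- if (is.null(mask)) sum(df) else sum(df[mask])
  }
  m <- max(raw)
  values <- if (m > 0) raw / m else rep(0, n)
  structure(list(values = values, raw = raw, frame_rate = video$frame_rate),
            class = "global_motion_signal")
}

#' Segment systole/diastole from the global motion signal
#'
#' The signal is baseline-corrected (its 25th percentile is subtracted and
#' the result clipped at 0 and renormalized; this removes the constant noise
#' floor that additive pixel noise contributes to the summed |difference|),
#' smoothed with a trailing 3-frame moving average, and thresholded with
#' hysteresis: a systole onset is the first index where the smoothed signal
#' crosses above `theta_on` after at least `min_quiet` consecutive frames
#' below `theta_off`; the offset is the first subsequent index beginning
#' `min_quiet` consecutive frames below `theta_off`. A quiescence guard
#' reports no systole when the signal's excursions are not significant
#' against its own quiet fluctuation — robust z-score
#' `(max - median) / (1.4826 * MAD)` below `min_z` — as under cardioplegic
#' arrest, where only the noise floor remains.
#'
#' @param signal A [global_frame_derivative()] result (or a numeric vector of
#'   normalized values).
#' @param theta_on,theta_off Hysteresis thresholds, `0 <= theta_off <
#'   theta_on <= 1` (defaults 0.3 and 0.1).
#' @param min_quiet Minimum quiet run in frames (default 3).
#' @param min_z Quiescence guard: minimum robust z-score of the signal's
#'   maximum excursion (default 6; the expected maximum of a few hundred
#'   quiet frames is about 3.5). Applied only when the MAD is positive.
#' @return An object of class `phase_segmentation`: data.frame with columns
#'   `interval_id`, `onset`, `offset` (half-open 1-based frame intervals
#'   `[onset, offset)`), with the total frame count in `attr(, "n_frames")`.
#' @export
segment_cardiac_phases <- function(signal, theta_on = 0.3, theta_off = 0.1,
                                   min_quiet = 3L, min_z = 6) {
  if (inherits(signal, "global_motion_signal")) {
    raw <- if (!is.null(signal$raw)) signal$raw else signal$values
  } else {
    raw <- as.numeric(signal)
  }
  if (!(theta_off >= 0 && theta_off < theta_on && theta_on <= 1))
    fail_input("need 0 <= theta_off < theta_on <= 1")
  n <- length(raw)
  empty <- data.frame(interval_id = integer(0), onset = integer(0),
                      offset = integer(0))
  out_cls <- function(df) {
    attr(df, "n_frames") <- n + 1L
    class(df) <- c("phase_segmentation", "data.frame")
    df
  }
  if (n == 0L || max(raw) <= 0) return(out_cls(empty))

  # quiet-floor fluctuation scale: MAD of the lower half about the median,
  # so genuine systolic excursions do not inflate the scale estimate
  med <- stats::median(raw)
  s_mad <- 1.4826 * stats::median(med - raw[raw <= med])
  if (s_mad > 0 && (max(raw) - med) / s_mad < min_z)
    return(out_cls(empty))
  q <- stats::quantile(raw, 0.25, names = FALSE)
  v0 <- pmax(raw - q, 0)
  m <- max(v0)
  if (m <= 0) return(out_cls(empty))
  v0 <- v0 / m                   # baseline-corrected, unsmoothed
  v <- moving_average(v0, 3L)    # what the hysteresis sees

  onsets <- integer(0); offsets <- integer(0)
  quiet_run <- 0L; armed <- FALSE; in_systole <- FALSE; onset <- NA_integer_
  last_off <- 0L
  for (i in seq_len(n)) {
    if (!in_systole) {
      quiet_run <- if (v[i] < theta_off) quiet_run + 1L else 0L
      if (quiet_run >= min_quiet) armed <- TRUE
      if (armed && v[i] > theta_on) {
        # the moving average delays the crossing; walk back to the first
        # frame of the unsmoothed excursion
        j <- i
        while (j > last_off + 1L && v0[j - 1L] >= theta_off) j <- j - 1L
        in_systole <- TRUE; onset <- j; quiet_run <- 0L; armed <- FALSE
      }
    } else {
      quiet_run <- if (v[i] < theta_off) quiet_run + 1L else 0L
      if (quiet_run >= min_quiet) {
        onsets <- c(onsets, onset)
        offsets <- c(offsets, i - min_quiet + 1L)
        last_off <- i - min_quiet + 1L
        in_systole <- FALSE; armed <- TRUE
      }
    }
  }
  if (in_systole) {
    onsets <- c(onsets, onset)
    offsets <- c(offsets, n + 1L)
  }
  df <- data.frame(interval_id = seq_along(onsets),
                   onset = onsets, offset = offsets)
  out_cls(df)
}

#' Frames of the longest diastole in a segmentation
#'
#' @param segmentation A [segment_cardiac_phases()] result.
#' @param n_frames Total frame count (defaults to the segmentation's own).
#' @return Integer frame indices of the longest systole-free run (the whole
#'   recording when no systole was detected).
#' @export
longest_diastole <- function(segmentation, n_frames = NULL) {
  if (is.null(n_frames)) n_frames <- attr(segmentation, "n_frames")
  in_sys <- rep(FALSE, n_frames)
  for (i in seq_len(nrow(segmentation))) {
    a <- segmentation$onset[i]
    b <- min(segmentation$offset[i] - 1L, n_frames)
    if (b >= a) in_sys[a:b] <- TRUE
  }
  r <- rle(in_sys)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dia <- which(!r$values)
  if (!length(dia)) return(seq_len(n_frames))
  best <- dia[which.max(r$lengths[dia])]
  seq(starts[best], ends[best])
}

#' Estimate the event rate of a periodic series
#'
#' Peaks are detected on the min-max-normalized series as excursions above
#' `min_prominence` (fraction of the full range); excursions separated by
#' less than `min_separation_s` are merged into one event, and each event's
#' peak is the local maximum of its excursion. The rate is
#' `(n_peaks - 1) / (time between first and last peak)`, or 0 when fewer
#' than two peaks are found (e.g. a flat series).
#'
#' @param series Numeric vector, a [calcium_trace()] (its `dff` series if
#'   present, else `raw`) or a [global_frame_derivative()] result.
#' @param frame_rate Frames per second (taken from the object if available).
#' @param min_prominence Detection threshold as a fraction of the series
#'   range (default 0.5).
#' @param min_separation_s Minimum event separation in seconds (default 0.3,
#'   merging the paired rise/fall excursions of a single contraction).
#' @return Estimated rate in Hz.
#' @export
estimate_event_rate <- function(series, frame_rate = NULL,
                                min_prominence = 0.5,
                                min_separation_s = 0.3) {
  if (inherits(series, "calcium_trace")) {
    if (is.null(frame_rate)) frame_rate <- series$frame_rate
    series <- if (!is.null(series$dff)) series$dff else series$raw
  } else if (inherits(series, "global_motion_signal")) {
    if (is.null(frame_rate)) frame_rate <- series$frame_rate
    series <- series$values
  }
  if (is.null(frame_rate) || frame_rate <= 0)
    fail_input("frame_rate must be supplied and > 0")
  x <- as.numeric(series)
  idx <- which(is.finite(x))
  if (length(idx) < 4) return(0)
  x <- x[idx]
  rng <- range(x)
  if (rng[2] <= rng[1]) return(0)
  s <- (x - rng[1]) / (rng[2] - rng[1])

  above <- s >= min_prominence
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (!length(runs)) return(0)
  seg <- cbind(starts[runs], ends[runs])
  min_gap <- max(1, round(min_separation_s * frame_rate))
  merged <- list(seg[1, ])
  if (nrow(seg) > 1) {
    for (i in 2:nrow(seg)) {
      last <- merged[[length(merged)]]
      if (seg[i, 1] - last[2] < min_gap)
        merged[[length(merged)]] <- c(last[1], seg[i, 2])
      else merged[[length(merged) + 1L]] <- seg[i, ]
    }
  }
  peaks <- vapply(merged, function(ab) {
    rel <- ab[1]:ab[2]
    rel[which.max(s[rel])]
  }, numeric(1))
  if (length(peaks) < 2) return(0)
  peaks <- idx[peaks]  # back to original frame indices
  (length(peaks) - 1) * frame_rate / (max(peaks) - min(peaks))
}

#' Write a phase segmentation to CSV (`interval_id, onset, offset`)
#' @param segmentation A [segment_cardiac_phases()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(segmentation, path) {
  utils::write.csv(as.data.frame(segmentation)[
    c("interval_id", "onset", "offset")], path, row.names = FALSE)
  invisible(path)
}
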