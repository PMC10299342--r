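#' Track a cell through systolic motion with the brightest-pixel rule
#'
#' Follows one cell with a small k x k reading frame. The initial placement
#' is given (chosen during diastole); at each subsequent video frame the
#' window starts from its previous placement, the brightest pixel inside it
#' is located, and the window is shifted so that this pixel returns to the
#' window center, iterating up to `max_iter` times or until stable. Shifts
#' are clamped to `max_step` pixels per axis per frame to bound runaway drift
#' on noisy frames. Ties for the brightest pixel are broken lexicographically
#' (smallest row, then smallest column).
#'
#' @param video A [video_stack()].
#' @param initial_center 1-based `(row, col)` of the window center in frame 1;
#'   the k x k window must lie fully inside the image.
#' @param k Odd window side length in pixels (default 3).
#' @param max_step Maximum window shift per axis per frame (default 2).
#' @param max_iter Maximum brightest-pixel re-centering iterations per frame
#'   (default 3).
#' @param cell_id Identifier carried into the trajectory (default 1).
#' @param median_filter If `TRUE`, window intensities are read through a
#'   3 x 3 median prefilter (off by default; tracking normally operates on
#'   raw intensities).
#' @return An object of class `roi_trajectory`: list with `cell_id`, `k`,
#'   `centers` (`T x 2` integer matrix of window centers), and
#'   `truncated_from` (first frame at which the window was driven against the
#'   image edge, or `NA`).
#' @export
track_roi <- function(video, initial_center, k = 3L, max_step = 2L,
                      max_iter = 3L, cell_id = 1L, median_filter = FALSE) {
  stopifnot(inherits(video, "video_stack"))
  k <- as.integer(k)
  if (k %% 2L != 1L || k < 1L) fail_input("k must be odd and >= 1")
  if (max_step < 1L) fail_input("max_step must be >= 1")
  d <- dim(video$data)
  hk <- (k - 1L) %/% 2L
  pos <- as.integer(round(initial_center))
  if (length(pos) != 2L ||
      pos[1] - hk < 1L || pos[1] + hk > d[1] ||
      pos[2] - hk < 1L || pos[2] + hk > d[2])
    fail_input("initial %dx%d window not fully inside the %dx%d image",
               k, k, d[1], d[2])

  n_frames <- d[3]
  centers <- matrix(0L, n_frames, 2L,
                    dimnames = list(NULL, c("row", "col")))
  centers[1L, ] <- pos
  truncated_from <- NA_integer_

  for (t in 2:n_frames) {
    prev <- centers[t - 1L, ]
    pos <- prev
    hit_edge <- FALSE
    for (it in seq_len(max_iter)) {
      win <- read_window(video$data, t, pos, hk, median_filter)
      off <- brightest_offset(win) - (hk + 1L)
      if (all(off == 0L)) break
      cand <- pos + off
      cand <- clamp(cand, prev - max_step, prev + max_step)
      bounded <- clamp(cand, c(1L + hk, 1L + hk), c(d[1] - hk, d[2] - hk))
      if (any(bounded != cand)) hit_edge <- TRUE
      if (all(bounded == pos)) break
      pos <- as.integer(bounded)
    }
    centers[t, ] <- pos
    if (hit_edge && is.na(truncated_from)) truncated_from <- t
  }

  structure(list(cell_id = cell_id, k = k, centers = centers,
                 truncated_from = truncated_from),
            class = "roi_trajectory")
}

# Window values at a center position; optional per-pixel 3x3 median.
read_window <- function(data, t, pos, hk, median_filter) {
  if (!median_filter)
    return(data[(pos[1] - hk):(pos[1] + hk),
                (pos[2] - hk):(pos[2] + hk), t, drop = FALSE][, , 1])
  d <- dim(data)
  k <- 2L * hk + 1L
  out <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      r <- pos[1] - hk - 1L + i
      c <- pos[2] - hk - 1L + j
      rs <- max(1L, r - 1L):min(d[1], r + 1L)
      cs <- max(1L, c - 1L):min(d[2], c + 1L)
      out[i, j] <- stats::median(data[rs, cs, t])
    }
  }
  out
}

# 1-based (row, col) of the brightest pixel; ties -> smallest row, then col.
brightest_offset <- function(win) {
  idx <- which(win == max(win), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  as.integer(idx[1, ])
}

#' @export
print.roi_trajectory <- function(x, ...) {
  cat(sprintf("roi_trajectory: cell %s, %dx%d window, %d frames%s\n",
              x$cell_id, x$k, x$k, nrow(x$centers),
              if (is.na(x$truncated_from)) ""
              else sprintf(", truncated from frame %d", x$truncated_from)))
  invisible(x)
}

#' Write trajectories to CSV (`cell_id, frame, row, col, truncated_flag`)
#'
#' @param trajectories List of [track_roi()] results.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  rows <- do.call(rbind, lapply(trajectories, function(tr) {
    n <- nrow(tr$centers)
    data.frame(cell_id = tr$cell_id, frame = seq_len(n),
               row = tr$centers[, 1], col = tr$centers[, 2],
               truncated_flag = as.integer(!is.na(tr$truncated_from) &
                                             seq_len(n) >= tr$truncated_from))
  }))
  if (is.null(rows))
    rows <- data.frame(cell_id = integer(0), frame = integer(0),
                       row = integer(0), col = integer(0),
                       truncated_flag = integer(0))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
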