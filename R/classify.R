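#' Cut fixed-length windows from a trace at given onsets
#'
#' Internal workhorse for [extract_systolic_windows()] and for cutting
#' control windows at spontaneous-event onsets. Onsets with fewer than
#' `window` frames remaining, or whose window contains missing values, are
#' skipped with a warning.
#'
#' @param trace A [calcium_trace()].
#' @param onsets 1-based onset frames.
#' @param window Window length in frames (default 20).
#' @param heart_id Identifier carried into the window metadata.
#' @return A `systolic_windows` object: list with `vectors` (n x window
#'   matrix of raw brightness values) and `info` (data.frame `cell_id`,
#'   `heart_id`, `onset_frame`).
#' @export
cut_windows <- function(trace, onsets, window = 20L, heart_id = NA) {
  stopifnot(inherits(trace, "calcium_trace"))
  window <- as.integer(window)
  n <- length(trace$raw)
  keep <- onsets[onsets >= 1L & onsets + window - 1L <= n]
  dropped <- length(onsets) - length(keep)
  rows <- list()
  for (on in keep) {
    v <- trace$raw[on:(on + window - 1L)]
    if (anyNA(v)) { dropped <- dropped + 1L; next }
    rows[[length(rows) + 1L]] <- list(onset = on, v = v)
  }
  if (dropped > 0)
    warning(sprintf("cell %s: skipped %d window(s) too close to the end or with missing frames",
                    trace$cell_id, dropped), call. = FALSE)
  vectors <- if (length(rows))
    do.call(rbind, lapply(rows, `[[`, "v"))
  else matrix(numeric(0), 0, window)
  info <- data.frame(
    cell_id = rep(trace$cell_id, length(rows)),
    heart_id = rep(heart_id, length(rows)),
    onset_frame = if (length(rows))
      vapply(rows, `[[`, numeric(1), "onset") else numeric(0))
  structure(list(vectors = vectors, info = info), class = "systolic_windows")
}

#' Extract systolic 20-frame windows from a calcium trace
#'
#' For every systole onset in the segmentation, records the raw mean-ROI
#' brightness over the following `window` frames as one vector (the
#' 20-dimensional representation of the cell's systolic signal). An empty
#' segmentation (cardioplegia) yields zero windows.
#'
#' @inheritParams cut_windows
#' @param segmentation A [segment_cardiac_phases()] result.
#' @return A `systolic_windows` object.
#' @export
extract_systolic_windows <- function(trace, segmentation, window = 20L,
                                     heart_id = NA) {
  cut_windows(trace, segmentation$onset, window = window, heart_id = heart_id)
}

#' Concatenate systolic window collections
#' @param ... `systolic_windows` objects (or a single list of them).
#' @return A combined `systolic_windows` object.
#' @export
bind_windows <- function(...) {
  ws <- list(...)
  if (length(ws) == 1L && !inherits(ws[[1]], "systolic_windows"))
    ws <- ws[[1]]
  ws <- ws[vapply(ws, function(w) nrow(w$vectors) > 0, logical(1))]
  if (!length(ws))
    return(structure(list(vectors = matrix(numeric(0), 0, 20),
                          info = data.frame(cell_id = integer(0),
                                            heart_id = integer(0),
                                            onset_frame = numeric(0))),
                     class = "systolic_windows"))
  structure(list(vectors = do.call(rbind, lapply(ws, `[[`, "vectors")),
                 info = do.call(rbind, lapply(ws, `[[`, "info"))),
            class = "systolic_windows")
}

#' @export
print.systolic_windows <- function(x, ...) {
  cat(sprintf("systolic_windows: %d window(s) of %d frames from %d cell(s)\n",
              nrow(x$vectors), ncol(x$vectors),
              length(unique(x$info$cell_id))))
  invisible(x)
}

#' Amplitude-normalize window vectors
#'
#' Each vector is shifted to zero minimum and scaled to unit maximum, making
#' the subsequent classification invariant to the absolute brightness of a
#' cell. Flat vectors map to all zeros.
#'
#' @param windows A `systolic_windows` object or a numeric matrix (one window
#'   per row).
#' @return A numeric matrix of normalized vectors.
#' @export
preprocess_windows <- function(windows) {
  m <- if (inherits(windows, "systolic_windows")) windows$vectors else
    as.matrix(windows)
  if (!nrow(m)) fail_input("no windows to preprocess")
  t(apply(m, 1L, function(v) {
    v <- v - min(v)
    mx <- max(v)
    if (mx > 0) v / mx else rep(0, length(v))
  }))
}

#' Embed control and test windows by principal component analysis
#'
#' Fits PCA on the pooled (control + test) normalized vectors, mean-centered
#' per dimension, and returns the first `n_components` scores for every
#' vector. Component signs are fixed so that each component's
#' largest-magnitude loading is positive, making the embedding deterministic.
#'
#' @param control_vectors,test_vectors Numeric matrices of normalized window
#'   vectors (same number of columns; typically 20).
#' @param n_components Number of retained components (default 2).
#' @return An object of class `embedding_result`: list with `scores`
#'   (n x n_components), `loadings`, `role` (`"control"`/`"test"` per row)
#'   and `sdev`.
#' @export
pca_embed <- function(control_vectors, test_vectors, n_components = 2L) {
  ctrl <- as.matrix(control_vectors)
  test <- as.matrix(test_vectors)
  if (nrow(test) && ncol(test) != ncol(ctrl))
    fail_input("control and test vectors must have the same dimension")
  x <- rbind(ctrl, test)
  if (nrow(x) < 3) fail_input("need at least 3 vectors for PCA")
  if (sum(apply(x, 2L, stats::var)) <= 0)
    fail_input("zero total variance: all vectors identical")
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  nc <- min(n_components, ncol(pr$rotation))
  scores <- pr$x[, seq_len(nc), drop = FALSE]
  loadings <- pr$rotation[, seq_len(nc), drop = FALSE]
  for (j in seq_len(nc)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 role = c(rep("control", nrow(ctrl)),
                          rep("test", nrow(test))),
                 sdev = pr$sdev[seq_len(nc)]),
            class = "embedding_result")
}

#' Label test windows sync/async with a Mahalanobis gate
#'
#' Fits the mean and covariance of the control scores; a test window belongs
#' to the sync group when its squared Mahalanobis distance to the control
#' cluster does not exceed the chi-square (2 df) quantile at
#' `chi2_quantile`. A singular control covariance is regularized by adding
#' `1e-6 * trace/2` to its diagonal.
#'
#' @param embedding An [pca_embed()] result with at least 3 control windows.
#' @param chi2_quantile Gate quantile (default 0.975).
#' @return A data.frame with one row per test window: `mahalanobis_d2` and
#'   `label` (`"sync"`/`"async"`); the gate threshold is attached as
#'   `attr(, "threshold")`.
#' @export
classify_windows <- function(embedding, chi2_quantile = 0.975) {
  stopifnot(inherits(embedding, "embedding_result"))
  ctrl <- embedding$scores[embedding$role == "control", , drop = FALSE]
  test <- embedding$scores[embedding$role == "test", , drop = FALSE]
  if (nrow(ctrl) < 3) fail_input("need at least 3 control windows")
  mu <- colMeans(ctrl)
  s <- stats::cov(ctrl)
  if (!is.finite(determinant(s, logarithm = FALSE)$modulus) ||
      rcond(s) < 1e-12)
    s <- s + diag(1e-6 * sum(diag(s)) / 2, ncol(s))
  thr <- stats::qchisq(chi2_quantile, df = ncol(ctrl))
  d2 <- if (nrow(test)) stats::mahalanobis(test, mu, s) else numeric(0)
  out <- data.frame(mahalanobis_d2 = d2,
                    label = ifelse(d2 <= thr, "sync", "async"))
  attr(out, "threshold") <- thr
  out
}

#' Aggregate window labels to per-cell sync/async calls
#'
#' A cell is sync when at least half of its windows are sync (and it has at
#' least one window). Cells listed in `all_cell_ids` with no windows (e.g.
#' under cardioplegia, when no systolic window exists) are labeled async.
#'
#' @param window_labels Character vector of per-window labels.
#' @param cell_ids Cell identifier per window.
#' @param all_cell_ids Optional full roster of examined cells.
#' @return data.frame `cell_id, n_windows, n_sync_windows, label`.
#' @export
classify_cells <- function(window_labels, cell_ids, all_cell_ids = NULL) {
  roster <- unique(c(all_cell_ids, cell_ids))
  rows <- lapply(roster, function(id) {
    lab <- window_labels[cell_ids == id]
    n <- length(lab)
    ns <- sum(lab == "sync")
    data.frame(cell_id = id, n_windows = n, n_sync_windows = ns,
               label = if (n >= 1 && ns >= n / 2) "sync" else "async")
  })
  do.call(rbind, rows)
}

#' Summarize sync/async calls per heart
#'
#' @param cell_labels data.frame with columns `heart_id` and `label`
#'   (`"sync"`/`"async"`), one row per cell.
#' @return An object of class `classification_summary`: list with
#'   `per_heart` (data.frame `heart_id, n_sync, n_async`) and `totals`
#'   (named vector `sync`, `async`).
#' @export
summarize_by_heart <- function(cell_labels) {
  if (!nrow(cell_labels)) fail_input("cell_labels is empty")
  hearts <- unique(cell_labels$heart_id)
  per <- do.call(rbind, lapply(hearts, function(h) {
    lab <- cell_labels$label[cell_labels$heart_id == h]
    data.frame(heart_id = h, n_sync = sum(lab == "sync"),
               n_async = sum(lab == "async"))
  }))
  structure(list(per_heart = per,
                 totals = c(sync = sum(per$n_sync),
                            async = sum(per$n_async))),
            class = "classification_summary")
}

#' @export
print.classification_summary <- function(x, ...) {
  print(x$per_heart, row.names = FALSE)
  cat(sprintf("total: %d sync / %d async (of %d cells)\n",
              x$totals["sync"], x$totals["async"], sum(x$totals)))
  invisible(x)
}

#' Balanced accuracy of predicted sync/async labels
#'
#' Mean of per-class recalls (sensitivity on sync, specificity on async).
#'
#' @param truth,predicted Character vectors of `"sync"`/`"async"` labels.
#' @return Balanced accuracy in \[0, 1\].
#' @export
balanced_accuracy <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  classes <- unique(truth)
  mean(vapply(classes, function(cl)
    mean(predicted[truth == cl] == cl), numeric(1)))
}
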