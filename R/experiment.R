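# High-level drivers that chain the per-module operations into the
# simulate -> track -> extract -> segment -> classify workflow.

#' Simulate a scene and add calibrated noise in one call
#'
#' @param config A [scene_config()].
#' @return List with `video` (noisy stack), `clean` (noiseless stack) and
#'   `truth`.
#' @export
simulate_experiment <- function(config) {
  scene <- render_scene(config)
  noisy <- add_noise_to_snr(scene$video, scene$truth,
                            config$target_snr_db, seed = config$seed)
  list(video = noisy, clean = scene$video, truth = scene$truth)
}

#' Track, extract, and segment one recording
#'
#' Runs the motion-compensated tracking and trace extraction for every seed
#' position, computes the global |df/dt| signal, segments systole, fills
#' dF/dF_max using the longest detected diastole as baseline, and cuts the
#' systolic 20-frame windows.
#'
#' @param video A [video_stack()].
#' @param initial_centers n x 2 matrix of 1-based `(row, col)` seed positions
#'   (the diastolic location of each cell, chosen manually in practice; in
#'   simulations, the ground-truth positions at frame 1).
#' @param heart_id Identifier attached to the windows (default 1).
#' @param k,max_step,max_iter Tracking parameters, see [track_roi()].
#' @param theta_on,theta_off,min_quiet Segmentation parameters, see
#'   [segment_cardiac_phases()].
#' @param window Systolic window length in frames (default 20).
#' @return List with `trajectories`, `traces` (dff-normalized
#'   [calcium_trace()]s), `motion`, `segmentation`, `windows` (combined
#'   `systolic_windows`), and `heart_rate_hz` (event rate of the motion
#'   signal; 0 under cardioplegia).
#' @export
analyze_scene <- function(video, initial_centers, heart_id = 1L,
                          k = 3L, max_step = 2L, max_iter = 3L,
                          theta_on = 0.3, theta_off = 0.1, min_quiet = 3L,
                          window = 20L) {
  initial_centers <- matrix(as.numeric(initial_centers), ncol = 2)
  n <- nrow(initial_centers)
  trajectories <- lapply(seq_len(n), function(i)
    track_roi(video, initial_centers[i, ], k = k, max_step = max_step,
              max_iter = max_iter, cell_id = i))
  traces <- lapply(trajectories, function(tr) extract_trace(video, tr))

  motion <- global_frame_derivative(video)
  segmentation <- segment_cardiac_phases(motion, theta_on = theta_on,
                                         theta_off = theta_off,
                                         min_quiet = min_quiet)
  baseline <- longest_diastole(segmentation, dim(video)[3])
  traces <- lapply(traces, function(tr) {
    ok <- baseline[!is.na(tr$raw[baseline])]
    if (!length(ok)) return(tr)
    normalize_dff(tr, ok)
  })

  windows <- bind_windows(lapply(traces, function(tr)
    extract_systolic_windows(tr, segmentation, window = window,
                             heart_id = heart_id)))

  list(trajectories = trajectories, traces = traces, motion = motion,
       segmentation = segmentation, windows = windows,
       heart_rate_hz = if (nrow(segmentation) >= 2)
         estimate_event_rate(motion) else 0)
}

#' Build the control window set from a dish recording
#'
#' Simulates (or accepts) a `dish_control` scene, tracks every cell, and
#' cuts 20-frame windows at the spontaneous-event onsets — the reference
#' transient shapes against which systolic windows are compared. Each onset
#' additionally contributes windows shifted by -1 and +1 frames
#' (`onset_jitter = 1`) so the control cluster spans the +/-1-frame onset
#' uncertainty inherent in systole detection.
#'
#' @param config A `dish_control` [scene_config()] (default: 16 cells at the
#'   ex vivo SNR, mirroring a 16-cell control recording set).
#' @param window Window length in frames (default 20).
#' @param onset_jitter Maximum onset shift (frames) for control augmentation
#'   (default 1; 0 disables).
#' @return A `systolic_windows` object with `heart_id = "control"`.
#' @export
make_control_windows <- function(config = NULL, window = 20L,
                                 onset_jitter = 1L) {
  if (is.null(config))
    config <- scene_config("dish_control", n_cells = 16L, seed = 1000L)
  if (config$mode != "dish_control")
    fail_input("control windows must come from a dish_control scene")
  sim <- simulate_experiment(config)
  ws <- lapply(seq_len(config$n_cells), function(i) {
    traj <- track_roi(sim$video, round(sim$truth$centers[[i]][1, ]),
                      cell_id = i)
    tr <- extract_trace(sim$video, traj)
    onsets <- sim$truth$event_onsets[[i]]
    shifts <- seq(-onset_jitter, onset_jitter)
    all_onsets <- sort(unique(as.vector(outer(onsets, shifts, "+"))))
    suppressWarnings(cut_windows(tr, all_onsets, window = window,
                                 heart_id = "control"))
  })
  bind_windows(ws)
}

#' Classify the cells of an analyzed scene against control windows
#'
#' Pools amplitude-normalized control and test windows, embeds them with
#' [pca_embed()], gates test windows by Mahalanobis distance to the control
#' cluster, and aggregates to per-cell sync/async calls (window majority;
#' cells with no systolic window are async).
#'
#' @param analysis An [analyze_scene()] result.
#' @param control_windows A `systolic_windows` object from
#'   [make_control_windows()].
#' @param all_cell_ids Roster of examined cells (default: the tracked cells).
#' @param chi2_quantile Gate quantile (default 0.975).
#' @return List with `cells` (data.frame `cell_id, n_windows,
#'   n_sync_windows, label`), `window_labels`, `embedding`.
#' @export
classify_scene <- function(analysis, control_windows, all_cell_ids = NULL,
                           chi2_quantile = 0.975) {
  if (is.null(all_cell_ids))
    all_cell_ids <- vapply(analysis$trajectories, `[[`, integer(1), "cell_id")
  test <- analysis$windows
  if (nrow(test$vectors) == 0) {
    cells <- data.frame(cell_id = all_cell_ids, n_windows = 0L,
                        n_sync_windows = 0L, label = "async")
    return(list(cells = cells, window_labels = NULL, embedding = NULL))
  }
  ctrl_m <- preprocess_windows(control_windows)
  test_m <- preprocess_windows(test)
  emb <- pca_embed(ctrl_m, test_m)
  wl <- classify_windows(emb, chi2_quantile = chi2_quantile)
  cells <- classify_cells(wl$label, test$info$cell_id,
                          all_cell_ids = all_cell_ids)
  list(cells = cells, window_labels = wl, embedding = emb)
}
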