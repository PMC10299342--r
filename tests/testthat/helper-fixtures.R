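# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# A small beating ex vivo scene (noiseless + noisy) used by several files.
small_beating_scene <- function() {
  fixture("small_beating", function() {
    cfg <- scene_config("ex_vivo", height = 128, width = 128, duration = 6,
                        n_cells = 4, sync_fraction = 0.5, seed = 3)
    sc <- render_scene(cfg)
    noisy <- add_noise_to_snr(sc$video, sc$truth, 32, seed = 3)
    list(config = cfg, clean = sc$video, noisy = noisy, truth = sc$truth)
  })
}

# A small dish-control scene for control windows.
small_control_windows <- function() {
  fixture("small_controls", function() {
    cfg <- scene_config("dish_control", height = 128, width = 128,
                        duration = 8, n_cells = 8, seed = 99)
    make_control_windows(cfg)
  })
}

# Truth-anchored trajectory: the ROI fixed at the rounded true cell centers,
# used to measure calibration independently of the tracker.
truth_trajectory <- function(truth, cell) {
  pos <- round(truth$centers[[cell]])
  structure(list(cell_id = cell, k = truth$roi_k, centers = pos,
                 truncated_from = NA_integer_),
            class = "roi_trajectory")
}

# Synthetic single-blob video: a Gaussian blob moving along given centers
# over a flat background. Returns the video and the integer center path.
moving_blob_video <- function(centers, h = 40, w = 40, sigma = 1.2,
                              amplitude = 300, background = 100,
                              frame_rate = 34) {
  n <- nrow(centers)
  data <- array(background, dim = c(h, w, n))
  for (t in seq_len(n)) {
    rr <- matrix(seq_len(h), h, w)
    cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    data[, , t] <- data[, , t] + amplitude *
      exp(-((rr - centers[t, 1])^2 + (cc - centers[t, 2])^2) / (2 * sigma^2))
  }
  video_stack(data, frame_rate = frame_rate)
}
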