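static_traj <- function(center, n, k = 3L) {
  structure(list(cell_id = 1L, k = k,
                 centers = matrix(rep(center, each = n), ncol = 2),
                 truncated_from = NA_integer_),
            class = "roi_trajectory")
}

test_that("extract_trace averages the k x k window", {
  v <- video_stack(array(7, c(10, 10, 4)), 34)
  tr <- extract_trace(v, static_traj(c(5, 5), 4))
  expect_equal(tr$raw, rep(7, 4))

  data <- array(0, c(5, 5, 2))
  data[2:4, 2:4, 1] <- matrix(1:9, 3, 3)
  data[2:4, 2:4, 2] <- matrix(1:9, 3, 3)
  tr <- extract_trace(video_stack(data, 34), static_traj(c(3, 3), 2))
  expect_equal(tr$raw, c(5, 5))
})

test_that("noiseless extraction reproduces the ground-truth clean trace", {
  sc <- small_beating_scene()
  for (i in 1:2) {
    traj <- track_roi(sc$clean, round(sc$truth$centers[[i]][1, ]),
                      cell_id = i)
    tr <- extract_trace(sc$clean, traj)
    clean <- sc$truth$clean_traces[[i]]
    expect_lt(max(abs(tr$raw - clean)), 0.02 * diff(range(clean)))
  }
})

test_that("dF/dF_max has its closed form and a flat-trace guard", {
  tr <- calcium_trace(1, c(1, 1, 3, 1), 34)
  out <- normalize_dff(tr, 1:2)
  expect_equal(out$dff, c(0, 0, 1, 0))
  flat <- normalize_dff(calcium_trace(1, rep(4, 6), 34), 1:3)
  expect_equal(flat$dff, rep(0, 6))
  expect_error(normalize_dff(tr, 0:2), "inside")
})

test_that("dF/dF_max is invariant to affine intensity rescaling", {
  set.seed(11)
  raw <- 100 + simulate_transient_train(c(5, 30), 60, 34, amplitude = 40) +
    rnorm(60)
  a <- normalize_dff(calcium_trace(1, raw, 34), 1:4)
  b <- normalize_dff(calcium_trace(1, 3.7 * raw + 55, 34), 1:4)
  expect_equal(a$dff, b$dff, tolerance = 1e-12)
})

test_that("the motion signal of a static video is identically zero", {
  v <- video_stack(array(5, c(16, 16, 10)), 34)
  sig <- global_frame_derivative(v)
  expect_equal(sig$values, rep(0, 9))
  expect_length(sig$values, 9)
})

test_that("the motion signal normalizes its largest inter-frame change to 1", {
  set.seed(2)
  data <- array(runif(16 * 16 * 8), c(16, 16, 8))
  data[, , 6] <- data[, , 6] + 5  # largest change at pairs (5,6) and (6,7)
  sig <- global_frame_derivative(video_stack(data, 34))
  expect_equal(max(sig$values), 1)
  expect_true(which.max(sig$values) %in% c(5, 6))
  expect_true(all(sig$values >= 0 & sig$values <= 1))
})

test_that("motion-signal peaks align with true systoles", {
  sc <- small_beating_scene()
  sig <- global_frame_derivative(sc$clean)
  for (on in sc$truth$systole_onsets) {
    # peak motion lies inside the systole's raised-cosine support
    win <- on:min(on + sc$config$systole_duration, length(sig$values))
    expect_gte(max(sig$values[win]), 0.8)
  }
})

test_that("segmentation handles zero signals and ideal square waves", {
  expect_identical(nrow(segment_cardiac_phases(rep(0, 50))), 0L)
  sq <- rep(c(rep(0, 9), rep(1, 4)), 8)
  seg <- segment_cardiac_phases(sq)
  expect_equal(seg$onset, which(diff(c(0, sq)) == 1))
})

test_that("segmentation onsets are exact on noiseless scenes across heart rates", {
  for (hr in c(0.34, 0.7, 1.28)) {
    cfg <- scene_config("ex_vivo", height = 128, width = 128, duration = 8,
                        n_cells = 3, heart_rate = hr, seed = 5)
    sc <- render_scene(cfg)
    seg <- segment_cardiac_phases(global_frame_derivative(sc$video))
    expect_identical(nrow(seg), length(sc$truth$systole_onsets))
    expect_lte(max(abs(seg$onset - sc$truth$systole_onsets)), 1)
  }
})

test_that("segmentation intervals are disjoint and sorted on random signals", {
  set.seed(20)
  for (rep in 1:25) {
    sig <- pmin(pmax(cumsum(rnorm(120, sd = 0.3)), 0), 1)
    sig <- sig / max(max(sig), 1e-9)
    seg <- segment_cardiac_phases(sig)
    if (nrow(seg) > 0) {
      expect_true(all(seg$offset > seg$onset))
      if (nrow(seg) > 1)
        expect_true(all(seg$onset[-1] >= seg$offset[-nrow(seg)]))
      expect_true(all(seg$onset >= 1 & seg$offset <= 121))
    }
  }
})

test_that("cardioplegic and dish recordings segment as systole-free", {
  cfg <- scene_config("ex_vivo", height = 128, width = 128, duration = 6,
                      n_cells = 3, heart_rate = 0, seed = 7)
  ex <- simulate_experiment(cfg)
  expect_identical(nrow(segment_cardiac_phases(
    global_frame_derivative(ex$video))), 0L)
})

test_that("event-rate estimation recovers simulated frequencies", {
  expect_equal(estimate_event_rate(rep(1, 100), 34), 0)
  # clean 1 Hz oscillator
  onsets <- round(seq(3, 330, by = 34))
  tr <- simulate_transient_train(onsets, 340, 34, amplitude = 50)
  expect_equal(estimate_event_rate(tr, 34), 1, tolerance = 0.01)
  # noisy cells at known frequency, 32 dB scene
  sc <- small_beating_scene()
  async <- which(sc$truth$cells$label == "async")
  for (i in async) {
    traj <- track_roi(sc$noisy, round(sc$truth$centers[[i]][1, ]))
    tr <- extract_trace(sc$noisy, traj)
    est <- estimate_event_rate(tr$raw, 34)
    expect_lt(abs(est - sc$truth$cells$frequency_hz[i]), 0.05)
  }
})

test_that("the longest diastole spans the recording when no systole exists", {
  seg <- segment_cardiac_phases(rep(0, 49))
  expect_equal(longest_diastole(seg), 1:50)
})
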