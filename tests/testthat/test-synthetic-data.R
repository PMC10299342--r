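test_that("transient train reduces to the baseline with no events", {
  tr <- simulate_transient_train(integer(0), 50, 34, baseline = 7)
  expect_equal(tr, rep(7, 50))
})

test_that("transient peak location and height match dense evaluation of the waveform", {
  fr <- 34; A <- 100; tr_rise <- 0.05; tr_dec <- 0.30
  series <- simulate_transient_train(1, 60, fr, amplitude = A,
                                     rise_tau = tr_rise, decay_tau = tr_dec)
  # brute-force oracle: evaluate the closed form on a fine time grid
  tfine <- seq(0, 59 / fr, by = 1e-4)
  wave <- A * (1 - exp(-tfine / tr_rise)) * exp(-tfine / tr_dec)
  peak_t <- tfine[which.max(wave)]
  expect_lt(abs((which.max(series) - 1) / fr - peak_t), 1 / fr)
  expect_lt(abs(max(series) - max(wave)), 0.02 * max(wave))
})

test_that("well-separated transients superpose without interference", {
  series <- simulate_transient_train(c(1, 101), 200, 34, amplitude = 50)
  p1 <- max(series[1:100]); p2 <- max(series[101:200])
  expect_equal(p2, p1, tolerance = 0.01 * p1)
})

test_that("transient train rejects unsorted or out-of-range onsets", {
  expect_error(simulate_transient_train(c(10, 5), 50, 34), "sorted")
  expect_error(simulate_transient_train(60, 50, 34), "within")
})

test_that("identical configuration gives bit-identical scene and ground truth", {
  cfg <- scene_config("ex_vivo", height = 96, width = 96, duration = 3,
                      n_cells = 2, seed = 42)
  a <- render_scene(cfg); b <- render_scene(cfg)
  expect_identical(a$video$data, b$video$data)
  expect_identical(a$truth$cells, b$truth$cells)
  expect_identical(a$truth$event_onsets, b$truth$event_onsets)
})

test_that("dish-control scenes are static and conserve total intensity", {
  cfg <- scene_config("dish_control", height = 96, width = 96, duration = 3,
                      n_cells = 2, seed = 5)
  sc <- render_scene(cfg)
  for (ctr in sc$truth$centers)
    expect_true(all(ctr == matrix(ctr[1, ], nrow(ctr), 2, byrow = TRUE)))
  # frame sums change only through the cells' own transients; subtracting
  # the known blob contribution, the background is constant
  sums <- apply(sc$video$data, 3, sum)
  blob <- Reduce(`+`, lapply(seq_len(2), function(i) {
    s <- sc$truth$cells$sigma_px[i]
    ev <- sc$truth$event_onsets[[i]]
    simulate_transient_train(ev, scene_n_frames(cfg), cfg$frame_rate,
                             amplitude = cfg$transient_amplitude,
                             baseline = cfg$cell_baseline_amplitude) *
      2 * pi * s^2
  }))
  resid <- sums - blob
  expect_lt(diff(range(resid)) / mean(resid), 0.01)
})

test_that("cardioplegia means no systole and no displacement", {
  cfg <- scene_config("ex_vivo", height = 96, width = 96, duration = 3,
                      n_cells = 2, heart_rate = 0, seed = 5)
  sc <- render_scene(cfg)
  expect_length(sc$truth$systole_onsets, 0)
  for (ctr in sc$truth$centers)
    expect_true(all(ctr == matrix(ctr[1, ], nrow(ctr), 2, byrow = TRUE)))
  expect_true(all(sc$truth$cells$label == "async"))
})

test_that("systole onsets are spaced frame_rate/heart_rate frames apart", {
  cfg <- scene_config("ex_vivo", heart_rate = 1.0, duration = 10, seed = 1)
  onsets <- scene_systole_onsets(cfg)
  expect_gte(length(onsets), 8)
  expect_true(all(abs(diff(onsets) - 34) <= 1))
})

test_that("sync cells have an event within one frame of every systole onset", {
  for (seed in 0:2) {
    cfg <- scene_config("ex_vivo", height = 96, width = 96, duration = 5,
                        n_cells = 4, sync_fraction = 1, seed = seed)
    sc <- render_scene(cfg)
    for (i in seq_len(cfg$n_cells)) {
      for (s in sc$truth$systole_onsets)
        expect_true(min(abs(sc$truth$event_onsets[[i]] - s)) <= 1)
    }
  }
})

test_that("true cell centers stay inside the image at all frames", {
  sc <- small_beating_scene()
  for (ctr in sc$truth$centers) {
    expect_true(all(ctr[, 1] >= 1 & ctr[, 1] <= 128))
    expect_true(all(ctr[, 2] >= 1 & ctr[, 2] <= 128))
  }
})

test_that("overcrowded scenes fail with a generation error", {
  expect_error(render_scene(scene_config("dish_control", height = 48,
                                         width = 48, duration = 1,
                                         n_cells = 60, seed = 1)),
               "place")
})

test_that("measure_snr matches its closed form", {
  clean <- c(rep(0, 90), 10, rep(0, 9))  # amplitude 10
  resid <- rep(c(1, -1), 50)
  resid <- resid / stats::sd(resid)      # residual sd exactly 1
  expect_equal(measure_snr(clean + resid, clean), 20)
  expect_equal(measure_snr(4 * clean + resid, 4 * clean), 20 * log10(40),
               tolerance = 1e-12)
  expect_identical(measure_snr(clean, clean), Inf)
})

test_that("halving the residual raises SNR by 6.02 dB", {
  clean <- c(rep(0, 90), 10, rep(0, 9))
  set.seed(1); resid <- rnorm(100)
  expect_equal(measure_snr(clean + resid / 2, clean) -
                 measure_snr(clean + resid, clean),
               20 * log10(2), tolerance = 1e-9)
})

test_that("infinite SNR target leaves the stack untouched", {
  sc <- small_beating_scene()
  out <- add_noise_to_snr(sc$clean, sc$truth, Inf, seed = 1)
  expect_identical(out$data, sc$clean$data)
})

test_that("a scene without cells cannot be noise-calibrated", {
  cfg <- scene_config("dish_control", height = 96, width = 96, duration = 2,
                      n_cells = 0, seed = 1)
  sc <- render_scene(cfg)
  expect_error(add_noise_to_snr(sc$video, sc$truth, 32, seed = 1),
               "no cells")
})

test_that("noise calibration hits the target SNR within one dB", {
  cfg <- scene_config("ex_vivo", height = 128, width = 128, duration = 6,
                      n_cells = 3, seed = 0)
  sc <- render_scene(cfg)
  for (target in c(16, 32)) {
    measured <- vapply(0:2, function(s) {
      noisy <- add_noise_to_snr(sc$video, sc$truth, target, seed = s)
      tr <- extract_trace(noisy, truth_trajectory(sc$truth, 1))
      measure_snr(tr, sc$truth$clean_traces[[1]])
    }, numeric(1))
    expect_lt(abs(mean(measured) - target), 1)
  }
})

test_that("injection dose is the rounded microcarrier-efficiency product", {
  expect_equal(compose_injection_dose(50000, 0.50), 25000)
  expect_equal(compose_injection_dose(50000, 0.45), 22500)
  expect_equal(compose_injection_dose(0, 0.7), 0)
  expect_error(compose_injection_dose(100, 1.2), "\\[0, 1\\]")
  expect_error(compose_injection_dose(-1, 0.5), ">= 0")
})
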