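#' Systole onset frames implied by a scene configuration
#'
#' Onsets are evenly spaced at `frame_rate / heart_rate` frames (rounded per
#' beat), with the first onset half a period into the recording. A zero heart
#' rate (cardioplegic arrest) or `dish_control` mode yields no onsets.
#'
#' @param config A [scene_config()].
#' @return Integer vector of 1-based onset frames (possibly empty).
#' @export
scene_systole_onsets <- function(config) {
  n_frames <- scene_n_frames(config)
  if (config$heart_rate <= 0 || config$mode == "dish_control")
    return(integer(0))
  period <- config$frame_rate / config$heart_rate
  k <- 0:ceiling(n_frames / period)
  onsets <- as.integer(round(period / 2 + k * period)) + 1L
  onsets[onsets >= 1L & onsets + config$systole_duration - 1L <= n_frames]
}

# Raised-cosine displacement activation per frame: 0 outside systole,
# 0.5*(1 - cos(2*pi*j/(L-1))) at frame onset+j within one.
systole_activation <- function(onsets, systole_duration, n_frames) {
  a <- numeric(n_frames)
  L <- systole_duration
  if (L < 2L) L <- 2L
  for (on in onsets) {
    j <- 0:(L - 1L)
    f <- on + j
    keep <- f <= n_frames
    a[f[keep]] <- pmax(a[f[keep]], 0.5 * (1 - cos(2 * pi * j[keep] / (L - 1))))
  }
  a
}

# Smooth background texture: coarse Gaussian grid, bilinearly upsampled.
make_texture <- function(h, w, level, contrast, seed, grid_px = 16) {
  gh <- ceiling(h / grid_px) + 2L
  gw <- ceiling(w / grid_px) + 2L
  coarse <- with_seed(seed, matrix(stats::rnorm(gh * gw), gh, gw))
  rows <- 1 + (seq_len(h) - 1) / grid_px
  cols <- 1 + (seq_len(w) - 1) / grid_px
  grid_r <- rep(rows, times = w)
  grid_c <- rep(cols, each = h)
  tex <- matrix(bilinear_sample(coarse, grid_r, grid_c), h, w)
  pmax(level * (1 + contrast * tex), 0)
}

# Rejection-sampled cell placement with a minimum pairwise distance and an
# edge margin wide enough for the displacement and the blob support.
place_cells <- function(config, margin, min_sep = 14) {
  n <- config$n_cells
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  lo_r <- 1 + margin; hi_r <- config$height - margin
  lo_c <- 1 + margin; hi_c <- config$width - margin
  if (hi_r <= lo_r || hi_c <= lo_c)
    fail_input("scene too small for the requested margin")
  centers <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  max_tries <- 500L * n
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      fail_input("could not place %d non-overlapping cells (placed %d)",
                 n, placed)
    cand <- c(stats::runif(1, lo_r, hi_r), stats::runif(1, lo_c, hi_c))
    if (placed > 0L) {
      d <- sqrt((centers[seq_len(placed), 1] - cand[1])^2 +
                  (centers[seq_len(placed), 2] - cand[2])^2)
      if (min(d) < min_sep) next
    }
    placed <- placed + 1L
    centers[placed, ] <- cand
  }
  centers
}

# Per-cell event trains. Sync cells fire at every systole onset plus
# spontaneous events kept clear of systole (host drive resets the local
# oscillator); async cells are free-running regular oscillators with random
# phase and frequency.
draw_cell_events <- function(config, labels, systole_onsets, n_frames) {
  fr <- config$frame_rate
  rr <- config$spontaneous_rate_range
  n <- config$n_cells
  freqs <- stats::runif(n, rr[1], rr[2])
  phases <- stats::runif(n)
  sys_excl_s <- 0.4
  events <- lapply(seq_len(n), function(i) {
    f <- freqs[i]
    t_ev <- (phases[i] + 0:ceiling(config$duration * f)) / f
    sp <- as.integer(round(t_ev * fr)) + 1L
    sp <- sp[sp >= 1L & sp <= n_frames]
    if (labels[i] == "sync" && length(systole_onsets)) {
      if (length(sp)) {
        d_min <- vapply(sp, function(s)
          min(abs(s - systole_onsets)) / fr, numeric(1))
        sp <- sp[d_min > sys_excl_s]
      }
      sort(unique(c(systole_onsets, sp)))
    } else {
      sp
    }
  })
  list(events = events, freqs = freqs)
}

#' Render a synthetic optical-mapping scene with ground truth
#'
#' Produces a noiseless video stack of a smooth fluorescent tissue texture
#' advected by a systolic displacement field (global translation plus a mild
#' radial contraction, raised-cosine in time), with graft cells rendered as
#' Gaussian blobs riding the same field, each emitting calcium transients.
#' All randomness derives from `config$seed` via independent substreams, so
#' identical configurations give bit-identical output. Use
#' [add_noise_to_snr()] to degrade the stack to a target trace SNR.
#'
#' @param config A [scene_config()].
#' @return A list with components:
#'   \describe{
#'     \item{video}{A [video_stack()] (noiseless, `height x width x T`).}
#'     \item{truth}{A `scene_truth` list: `cells` (data.frame with `cell_id`,
#'       `label`, `frequency_hz`, `sigma_px`, initial `row`/`col`),
#'       `centers` (list of `T x 2` per-cell true center paths),
#'       `event_onsets` (list of per-cell 1-based onset frames),
#'       `systole_onsets`, `clean_traces` (per-cell noiseless k x k mean-ROI
#'       series at the rounded true centers), `roi_k`, and the echoed
#'       `config`.}
#'   }
#' @export
render_scene <- function(config) {
  validate_scene_config(config)
  h <- config$height; w <- config$width
  n_frames <- scene_n_frames(config)
  fr <- config$frame_rate
  roi_k <- 3L

  texture <- make_texture(h, w, config$background_level,
                          config$texture_contrast,
                          substream_seed(config$seed, 4L))

  systole_onsets <- scene_systole_onsets(config)
  moving <- config$mode != "dish_control" && length(systole_onsets) > 0
  a_t <- if (moving)
    systole_activation(systole_onsets, config$systole_duration, n_frames)
  else numeric(n_frames)

  # cell placement and identities
  margin <- ceiling(config$displacement_amplitude +
                      4 * max(config$blob_sigma_range) + roi_k)
  centers0 <- with_seed(substream_seed(config$seed, 1L),
                        place_cells(config, margin))
  n <- config$n_cells
  n_sync <- if (length(systole_onsets)) round(config$sync_fraction * n) else 0L
  labels <- rep("async", n)
  if (n_sync > 0) labels[seq_len(n_sync)] <- "sync"

  ph <- with_seed(substream_seed(config$seed, 2L), {
    ev <- draw_cell_events(config, labels, systole_onsets, n_frames)
    ev$sigmas <- stats::runif(n, config$blob_sigma_range[1],
                              config$blob_sigma_range[2])
    ev
  })
  events <- ph$events
  sigmas <- ph$sigmas
  freqs <- ph$freqs

  # displacement unit field (translation + radial contraction toward center)
  u <- c(0.6, 0.8)
  contraction <- 0.5
  ctr <- c((h + 1) / 2, (w + 1) / 2)
  rad <- sqrt(ctr[1]^2 + ctr[2]^2)
  amp <- config$displacement_amplitude

  grid_r <- rep(seq_len(h), times = w)
  grid_c <- rep(seq_len(w), each = h)
  ur_field <- u[1] + contraction * (ctr[1] - grid_r) / rad
  uc_field <- u[2] + contraction * (ctr[2] - grid_c) / rad

  # per-cell clean amplitude series and advected centers
  amp_series <- lapply(seq_len(n), function(i)
    simulate_transient_train(events[[i]], n_frames, fr,
                             amplitude = config$transient_amplitude,
                             rise_tau = config$transient_rise_tau,
                             decay_tau = config$transient_decay_tau,
                             baseline = config$cell_baseline_amplitude))
  centers <- lapply(seq_len(n), function(i) {
    ur <- u[1] + contraction * (ctr[1] - centers0[i, 1]) / rad
    uc <- u[2] + contraction * (ctr[2] - centers0[i, 2]) / rad
    cbind(row = centers0[i, 1] + a_t * amp * ur,
          col = centers0[i, 2] + a_t * amp * uc)
  })

  drift <- if (config$mode == "in_vivo")
    config$drift_amplitude * config$background_level *
      sin(2 * pi * config$drift_frequency * (seq_len(n_frames) - 1) / fr)
  else numeric(n_frames)

  video <- array(0, dim = c(h, w, n_frames))
  for (t in seq_len(n_frames)) {
    frame <- if (a_t[t] > 0) {
      src_r <- grid_r - a_t[t] * amp * ur_field
      src_c <- grid_c - a_t[t] * amp * uc_field
      matrix(bilinear_sample(texture, src_r, src_c), h, w)
    } else texture
    if (n > 0) {
      for (i in seq_len(n)) {
        cc <- centers[[i]][t, ]
        s <- sigmas[i]
        rpx <- ceiling(4 * s)
        rs <- max(1L, floor(cc[1]) - rpx):min(h, ceiling(cc[1]) + rpx)
        cs <- max(1L, floor(cc[2]) - rpx):min(w, ceiling(cc[2]) + rpx)
        blob <- amp_series[[i]][t] *
          exp(-outer((rs - cc[1])^2, (cs - cc[2])^2, "+") / (2 * s^2))
        frame[rs, cs] <- frame[rs, cs] + blob
      }
    }
    if (drift[t] != 0) frame <- frame + drift[t]
    video[, , t] <- frame
  }

  stack <- video_stack(video, frame_rate = fr)
  clean_traces <- lapply(seq_len(n), function(i) {
    pos <- round(centers[[i]])
    vapply(seq_len(n_frames), function(t)
      roi_mean(video, pos[t, 1], pos[t, 2], t, roi_k), numeric(1))
  })

  truth <- structure(list(
    cells = data.frame(cell_id = seq_len(n),
                       label = labels,
                       frequency_hz = freqs,
                       sigma_px = sigmas,
                       row = centers0[, 1], col = centers0[, 2]),
    centers = centers,
    event_onsets = events,
    systole_onsets = systole_onsets,
    clean_traces = clean_traces,
    roi_k = roi_k,
    config = config
  ), class = "scene_truth")

  list(video = stack, truth = truth)
}

#' Mean intensity of the k x k window centered at (row, col) in one frame
#' @noRd
roi_mean <- function(data, row, col, frame, k = 3L) {
  hk <- (k - 1L) %/% 2L
  mean(data[(row - hk):(row + hk), (col - hk):(col + hk), frame])
}
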