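#' Configuration of a synthetic optical-mapping scene
#'
#' Describes one simulated recording: a fluorescent tissue background that is
#' periodically displaced by systole, plus compact graft cells (Gaussian
#' blobs) carried by that motion, each firing calcium transients. The three
#' modes emulate the study regimes: `"ex_vivo"` (Langendorff-perfused beating
#' heart, target trace SNR 32 dB), `"dish_control"` (culture dish, no tissue
#' motion) and `"in_vivo"` (closed-chest imaging, target SNR 16 dB with a slow
#' breathing-like baseline drift).
#'
#' @param mode One of `"ex_vivo"`, `"dish_control"`, `"in_vivo"`.
#' @param height,width Image size in pixels (default 512 x 512).
#' @param frame_rate Acquisition rate in Hz (default 34).
#' @param duration Recording length in seconds (default 10).
#' @param heart_rate Host beating rate in Hz. `0` means cardioplegic arrest
#'   (no systole, no displacement). Ignored (forced to 0 motion) in
#'   `dish_control` mode.
#' @param systole_duration Length of one contraction in frames (default 10);
#'   the displacement follows a raised-cosine time course over these frames.
#' @param displacement_amplitude Peak tissue displacement in pixels
#'   (default 3).
#' @param n_cells Number of graft cells to place (default 3).
#' @param sync_fraction Fraction of cells whose transients are locked to
#'   systole onset (default 0.5). With `heart_rate = 0` every cell is
#'   asynchronous regardless of this value.
#' @param spontaneous_rate_range Range (Hz) from which each cell's spontaneous
#'   firing frequency is drawn uniformly (default `c(0.5, 1.5)`).
#' @param transient_rise_tau,transient_decay_tau Calcium transient kinetics in
#'   seconds (defaults 0.05 and 0.30; fast-rise/slow-decay indicator
#'   morphology).
#' @param transient_amplitude Scale A of the double-exponential transient in
#'   intensity units (default 400). The waveform
#'   `A * (1 - exp(-t/tau_rise)) * exp(-t/tau_decay)` peaks at about `0.62 A`.
#' @param cell_baseline_amplitude Resting blob brightness above the local
#'   background (default 600), which keeps the cell visible to the tracker
#'   during diastole.
#' @param background_level Mean background intensity (default 1000).
#' @param texture_contrast Standard deviation of the smooth background texture
#'   as a fraction of `background_level` (default 0.10).
#' @param blob_sigma_range Range of per-cell Gaussian blob widths in pixels
#'   (default `c(1, 2)`).
#' @param target_snr_db Calibration target for [add_noise_to_snr()] in dB
#'   (default 32 for `ex_vivo`/`dish_control`, 16 for `in_vivo`, the midpoint
#'   of the 13--19 dB acquisition band). `Inf` disables noise.
#' @param drift_amplitude,drift_frequency In-vivo baseline drift (breathing
#'   surrogate): additive sinusoid amplitude as a fraction of
#'   `background_level` (default 0.01) and frequency in Hz (default 0.8).
#'   Applied only in `in_vivo` mode.
#' @param seed Integer seed; expands internally into independent substreams
#'   for cell placement, phases/frequencies, texture, and noise.
#'
#' @return An object of class `scene_config` (a validated list).
#' @seealso [render_scene()], [add_noise_to_snr()]
#' @export
scene_config <- function(mode = c("ex_vivo", "dish_control", "in_vivo"),
                         height = 512L, width = 512L,
                         frame_rate = 34, duration = 10,
                         heart_rate = 0.7, systole_duration = 10L,
                         displacement_amplitude = 3,
                         n_cells = 3L, sync_fraction = 0.5,
                         spontaneous_rate_range = c(0.5, 1.5),
                         transient_rise_tau = 0.05,
                         transient_decay_tau = 0.30,
                         transient_amplitude = 400,
                         cell_baseline_amplitude = 600,
                         background_level = 1000,
                         texture_contrast = 0.10,
                         blob_sigma_range = c(1, 2),
                         target_snr_db = NULL,
                         drift_amplitude = 0.01,
                         drift_frequency = 0.8,
                         seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(target_snr_db))
    target_snr_db <- if (mode == "in_vivo") 16 else 32

  cfg <- list(
    mode = mode, height = as.integer(height), width = as.integer(width),
    frame_rate = frame_rate, duration = duration, heart_rate = heart_rate,
    systole_duration = as.integer(systole_duration),
    displacement_amplitude = displacement_amplitude,
    n_cells = as.integer(n_cells), sync_fraction = sync_fraction,
    spontaneous_rate_range = spontaneous_rate_range,
    transient_rise_tau = transient_rise_tau,
    transient_decay_tau = transient_decay_tau,
    transient_amplitude = transient_amplitude,
    cell_baseline_amplitude = cell_baseline_amplitude,
    background_level = background_level,
    texture_contrast = texture_contrast,
    blob_sigma_range = blob_sigma_range,
    target_snr_db = target_snr_db,
    drift_amplitude = drift_amplitude,
    drift_frequency = drift_frequency,
    seed = as.integer(seed)
  )
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  if (cfg$height < 16 || cfg$width < 16)
    fail_input("scene too small: height/width must be >= 16 px")
  if (cfg$frame_rate <= 0) fail_input("frame_rate must be > 0")
  if (cfg$duration <= 0) fail_input("duration must be > 0")
  if (cfg$heart_rate < 0) fail_input("heart_rate must be >= 0")
  if (cfg$systole_duration <= 0) fail_input("systole_duration must be > 0")
  if (cfg$sync_fraction < 0 || cfg$sync_fraction > 1)
    fail_input("sync_fraction must lie in [0, 1]")
  rr <- cfg$spontaneous_rate_range
  if (length(rr) != 2 || rr[1] <= 0 || rr[2] < rr[1] ||
      rr[2] >= cfg$frame_rate / 2)
    fail_input("spontaneous_rate_range must lie within (0, frame_rate/2)")
  if (cfg$displacement_amplitude < 0 ||
      cfg$displacement_amplitude >= min(cfg$height, cfg$width) / 4)
    fail_input("displacement_amplitude must be in [0, min(height,width)/4)")
  if (cfg$transient_rise_tau <= 0 || cfg$transient_decay_tau <= 0)
    fail_input("transient time constants must be > 0")
  if (cfg$transient_amplitude < 0 || cfg$background_level < 0)
    fail_input("intensity parameters must be >= 0")
  if (cfg$n_cells < 0) fail_input("n_cells must be >= 0")
  invisible(cfg)
}

#' @export
print.scene_config <- function(x, ...) {
  n_frames <- max(2L, as.integer(round(x$duration * x$frame_rate)))
  cat(sprintf("scene_config [%s]: %dx%d px, %g fps, %g s (%d frames)\n",
              x$mode, x$height, x$width, x$frame_rate, x$duration, n_frames))
  cat(sprintf("  heart %g Hz, systole %d frames, displacement %g px\n",
              x$heart_rate, x$systole_duration, x$displacement_amplitude))
  cat(sprintf("  %d cells (sync fraction %g), spontaneous %g-%g Hz\n",
              x$n_cells, x$sync_fraction,
              x$spontaneous_rate_range[1], x$spontaneous_rate_range[2]))
  cat(sprintf("  target SNR %g dB, seed %d\n", x$target_snr_db, x$seed))
  invisible(x)
}

#' Number of frames implied by a scene configuration
#' @param config A [scene_config()].
#' @return Integer frame count (at least 2).
#' @export
scene_n_frames <- function(config) {
  max(2L, as.integer(round(config$duration * config$frame_rate)))
}
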