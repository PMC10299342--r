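#' Trace signal-to-noise ratio against a clean reference
#'
#' SNR (dB) is defined as `20 * log10(A / sigma)` where `A` is the
#' peak-to-baseline amplitude of the clean reference trace (maximum minus its
#' 10th percentile, the latter serving as the resting-baseline estimate) and
#' `sigma` is the standard deviation of the residual `trace - clean`.
#'
#' @param trace Numeric vector, or a [calcium_trace()] (its `raw` series is
#'   used). Must have the same length as `clean_reference`.
#' @param clean_reference Noiseless reference series containing at least one
#'   transient (its amplitude must be positive).
#' @return SNR in dB; `Inf` if the residual has zero variance.
#' @export
measure_snr <- function(trace, clean_reference) {
  if (inherits(trace, "calcium_trace")) trace <- trace$raw
  trace <- as.numeric(trace)
  clean_reference <- as.numeric(clean_reference)
  if (length(trace) != length(clean_reference))
    fail_input("trace and clean_reference must have equal length")
  a <- trace_amplitude(clean_reference)
  if (!is.finite(a) || a <= 0)
    fail_input("clean reference has no transient (zero peak-to-baseline amplitude)")
  keep <- is.finite(trace) & is.finite(clean_reference)
  s <- stats::sd(trace[keep] - clean_reference[keep])
  if (!is.finite(s) || s == 0) return(Inf)
  20 * log10(a / s)
}

# Peak-to-baseline amplitude; baseline = 10th percentile (resting level).
trace_amplitude <- function(x) {
  x <- x[is.finite(x)]
  max(x) - stats::quantile(x, 0.1, names = FALSE)
}

#' Add Gaussian pixel noise calibrated to a target trace SNR
#'
#' Adds i.i.d. zero-mean Gaussian noise to every pixel with a standard
#' deviation chosen so that [measure_snr()] on the k x k mean-ROI trace of
#' the reference cell (cell 1) equals `target_snr_db` in expectation: the ROI
#' mean of `k^2` independent pixels attenuates the pixel noise by a factor
#' `k`, so `sigma_pixel = k * A / 10^(SNR/20)`. Negative intensities are
#' clipped at zero (negligible at the default background level).
#'
#' @param video A [video_stack()] (typically the noiseless output of
#'   [render_scene()]).
#' @param truth The matching `scene_truth` (supplies the clean reference
#'   trace and ROI size).
#' @param target_snr_db Target SNR in dB; `Inf` returns the input unchanged.
#' @param seed Integer seed for the noise stream.
#' @return A [video_stack()] with noise added.
#' @export
add_noise_to_snr <- function(video, truth, target_snr_db = NULL, seed = 1L) {
  stopifnot(inherits(video, "video_stack"), inherits(truth, "scene_truth"))
  if (is.null(target_snr_db)) target_snr_db <- truth$config$target_snr_db
  if (!is.finite(target_snr_db)) return(video)
  if (length(truth$clean_traces) == 0)
    fail_input("scene has no cells: no reference trace for SNR calibration")
  a <- trace_amplitude(truth$clean_traces[[1]])
  if (a <= 0) fail_input("reference clean trace has zero amplitude")
  sigma_pixel <- truth$roi_k * a / 10^(target_snr_db / 20)
  noisy <- with_seed(substream_seed(seed, 3L), {
    video$data + array(stats::rnorm(length(video$data), sd = sigma_pixel),
                       dim = dim(video$data))
  })
  noisy[noisy < 0] <- 0
  video_stack(noisy, frame_rate = video$frame_rate)
}

#' Expected adhered cell count of an injection dose
#'
#' The injected suspension carries `n_microcarriers` fiber fragments of which
#' a fraction `seeding_efficiency` holds an adhered cardiomyocyte; the
#' expected cell dose is the rounded product.
#'
#' @param n_microcarriers Non-negative microcarrier count.
#' @param seeding_efficiency Fraction in \[0, 1\].
#' @return Expected number of adhered cells (integer-valued numeric).
#' @examples
#' compose_injection_dose(50000, 0.5)  # 25000
#' @export
compose_injection_dose <- function(n_microcarriers, seeding_efficiency) {
  if (n_microcarriers < 0) fail_input("n_microcarriers must be >= 0")
  if (seeding_efficiency < 0 || seeding_efficiency > 1)
    fail_input("seeding_efficiency must lie in [0, 1]")
  round_half_up(n_microcarriers * seeding_efficiency)
}
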