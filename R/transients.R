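#' Simulate a clean calcium-transient train
#'
#' Builds the noiseless intensity time course of one cell as a superposition
#' of double-exponential transients, one per event onset:
#' `baseline + sum_k A * (1 - exp(-t_k/tau_rise)) * exp(-t_k/tau_decay)` for
#' `t_k >= 0`, where `t_k` is the time since onset `k`. The series is clipped
#' at 0 and is fully deterministic given its inputs.
#'
#' @param onsets Sorted 1-based frame indices of event onsets (may be empty).
#' @param n_frames Length of the output series in frames.
#' @param frame_rate Frames per second.
#' @param amplitude Transient scale A in intensity units. The unnormalized
#'   waveform peaks at `A * (1 - e^{-t*/tau_r}) e^{-t*/tau_d}` with
#'   `t* = tau_r log(1 + tau_d/tau_r)`.
#' @param rise_tau,decay_tau Rise and decay time constants in seconds.
#' @param baseline Constant baseline added to the series.
#' @return Numeric vector of length `n_frames`.
#' @examples
#' tr <- simulate_transient_train(c(5, 40), 80, 34, amplitude = 100)
#' @export
simulate_transient_train <- function(onsets, n_frames, frame_rate,
                                     amplitude = 400,
                                     rise_tau = 0.05, decay_tau = 0.30,
                                     baseline = 0) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 1) fail_input("n_frames must be >= 1")
  if (frame_rate <= 0) fail_input("frame_rate must be > 0")
  onsets <- as.numeric(onsets)
  if (length(onsets)) {
    if (is.unsorted(onsets)) fail_input("onsets must be sorted")
    if (min(onsets) < 1 || max(onsets) > n_frames)
      fail_input("onsets must lie within [1, n_frames]")
  }
  out <- rep(baseline, n_frames)
  tt <- (seq_len(n_frames) - 1) / frame_rate
  for (on in onsets) {
    t0 <- (on - 1) / frame_rate
    dt <- tt - t0
    act <- dt >= 0
    out[act] <- out[act] +
      amplitude * (1 - exp(-dt[act] / rise_tau)) * exp(-dt[act] / decay_tau)
  }
  pmax(out, 0)
}

#' Peak value and delay of the unit transient waveform
#' @noRd
transient_peak <- function(amplitude, rise_tau, decay_tau) {
  tstar <- rise_tau * log(1 + decay_tau / rise_tau)
  list(time = tstar,
       value = amplitude * (1 - exp(-tstar / rise_tau)) * exp(-tstar / decay_tau))
}
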