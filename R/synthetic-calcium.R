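# Synthetic calcium line-scan traces. The emulated indicator is Fura-2 AM
# excited at a wavelength where it darkens with increasing calcium, so
# stimulus-evoked transients are negative-going dips in raw fluorescence.
# The trace model is an exponentially decaying baseline (slow bleaching /
# dye equilibration) plus one negative exponential transient per stimulus
# plus white Gaussian noise.

#' Ground truth for a synthetic calcium line-scan trace
#'
#' @param baseline_amp Amplitude of the decaying baseline component.
#' @param baseline_tau_ms Baseline decay constant (default 2000 ms: slow
#'   relative to the 900 ms scan).
#' @param baseline_asymptote Baseline asymptote (raw intensity units).
#' @param stim_times_ms Strictly increasing stimulus times (default 70 ms,
#'   the first stimulus of the scan protocol).
#' @param transient_amplitudes Per-stimulus amplitudes, negative-going
#'   (default -40 on a baseline of ~100, a 40 percent dip).
#' @param transient_tau_ms Recovery time constant of each transient
#'   (default 250 ms).
#' @param noise_sd Gaussian noise standard deviation (raw units).
#' @param t_max_ms,dt_ms Time grid: 0 to `t_max_ms` in steps of `dt_ms`.
#' @param seed Integer master seed.
#' @return An object of class `calcium_truth`.
#' @export
calcium_truth <- function(baseline_amp = 5, baseline_tau_ms = 2000,
                          baseline_asymptote = 95,
                          stim_times_ms = 70,
                          transient_amplitudes = -40,
                          transient_tau_ms = 250,
                          noise_sd = 1,
                          t_max_ms = 900, dt_ms = 2, seed = 1) {
  stopifnot(noise_sd >= 0, all(diff(stim_times_ms) > 0),
            length(transient_amplitudes) == length(stim_times_ms),
            baseline_asymptote + baseline_amp > 0)
  structure(list(baseline_amp = baseline_amp,
                 baseline_tau_ms = baseline_tau_ms,
                 baseline_asymptote = baseline_asymptote,
                 stim_times_ms = stim_times_ms,
                 transient_amplitudes = transient_amplitudes,
                 transient_tau_ms = transient_tau_ms,
                 noise_sd = noise_sd,
                 t_max_ms = t_max_ms, dt_ms = dt_ms, seed = seed),
            class = "calcium_truth")
}

#' Render a synthetic calcium trace
#'
#' @param truth A [calcium_truth()].
#' @return A tibble with columns `t_ms` and `F`; the stimulus times are
#'   attached as attribute `stim_times_ms` and the truth as attribute
#'   `truth`.
#' @export
make_calcium_trace <- function(truth) {
  stopifnot(inherits(truth, "calcium_truth"))
  t <- seq(0, truth$t_max_ms, by = truth$dt_ms)
  f <- truth$baseline_asymptote +
    truth$baseline_amp * exp(-t / truth$baseline_tau_ms)
  for (k in seq_along(truth$stim_times_ms)) {
    tk <- truth$stim_times_ms[k]
    on <- t >= tk
    f[on] <- f[on] + truth$transient_amplitudes[k] *
      exp(-(t[on] - tk) / truth$transient_tau_ms)
  }
  if (truth$noise_sd > 0) {
    f <- f + with_rng_seed(split_seed(truth$seed, "calcium"),
                           stats::rnorm(length(t), 0, truth$noise_sd))
  }
  out <- tibble::tibble(t_ms = t, F = f)
  attr(out, "stim_times_ms") <- truth$stim_times_ms
  attr(out, "truth") <- truth
  out
}
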