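# Calcium line-scan analysis. The indicator darkens with rising calcium,
# so stimulus transients are negative-going: dF/F0 dips below zero, and on
# the min-normalized scale the trace dips below the y = 1 baseline toward
# the fitted minimum at 0. The signal area integrates (baseline - trace)
# from the first stimulus to the end of the scan.

#' Fractional fluorescence change over a pre-stimulus baseline
#'
#' `F0` is the mean raw intensity over the baseline window; the output is
#' `(F - F0) / F0`, which is invariant to any positive gain on `F`.
#'
#' @param trace Tibble with columns `t_ms` and `F`.
#' @param baseline_window_ms Length-2 window (default 0-60 ms, before a
#'   first stimulus at 70 ms); must contain at least 3 samples.
#' @return Tibble with `t_ms` and `dff`; `F0` is attached as an attribute.
#' @export
compute_dff <- function(trace, baseline_window_ms = c(0, 60)) {
  stopifnot(all(c("t_ms", "F") %in% names(trace)))
  w <- trace$t_ms >= baseline_window_ms[1] & trace$t_ms <= baseline_window_ms[2]
  if (sum(w) < 3) stop("baseline window must contain at least 3 samples")
  f0 <- mean(trace$F[w])
  if (f0 <= 0) stop("non-positive baseline F0")
  out <- tibble::tibble(t_ms = trace$t_ms, dff = (trace$F - f0) / f0)
  attr(out, "F0") <- f0
  attr(out, "stim_times_ms") <- attr(trace, "stim_times_ms")
  out
}

#' Fit a single exponential with offset to a trace segment
#'
#' Fits `v(t) = A exp(-(t - t0) / tau) + C` by nonlinear least squares to
#' the samples with `t >= t_start` (`t0 = t_start`). The revealed
#' "minimum" is the fitted extreme `A + C`, the fitted value at the
#' segment start (for a negative-going recovery, the deepest point of the
#' fit). Near-constant segments return `A = 0`, `tau = NA` and the mean as
#' the minimum.
#'
#' @param trace Tibble with `t_ms` and a value column (`dff`, `value` or
#'   `F` -- the first present is used).
#' @param t_start Segment start in ms (default: start of the trace; pass
#'   the time of the post-stimulus extreme for recovery fits).
#' @return An object of class `ca_expfit`: list with `A`, `tau_ms`, `C`,
#'   `t0_ms`, `minimum`, `resid_norm`, `n`.
#' @export
fit_exponential_min <- function(trace, t_start = NULL) {
  vcol <- intersect(c("dff", "value", "F"), names(trace))[1]
  if (is.na(vcol)) stop("no value column (dff/value/F) in trace")
  if (is.null(t_start)) t_start <- min(trace$t_ms)
  seg <- trace[trace$t_ms >= t_start, ]
  if (nrow(seg) < 5) stop("need at least 5 post-stimulus samples")
  t <- seg$t_ms - t_start
  v <- seg[[vcol]]
  if (stats::sd(v) < 1e-12) {
    fit <- list(A = 0, tau_ms = NA_real_, C = mean(v), t0_ms = t_start,
                minimum = mean(v), resid_norm = 0, n = length(v))
    class(fit) <- "ca_expfit"
    return(fit)
  }
  a0 <- v[1] - v[length(v)]
  c0 <- v[length(v)]
  tau0 <- max(diff(range(t)) / 3, 1)
  m <- tryCatch(
    minpack.lm::nlsLM(v ~ A * exp(-t / tau) + C,
                      start = list(A = a0, tau = tau0, C = c0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop("exponential fit did not converge: ", conditionMessage(e))
    })
  p <- stats::coef(m)
  fit <- list(A = unname(p["A"]), tau_ms = unname(p["tau"]),
              C = unname(p["C"]), t0_ms = t_start,
              minimum = unname(p["A"] + p["C"]),
              resid_norm = sqrt(sum(stats::resid(m)^2)), n = length(v))
  class(fit) <- "ca_expfit"
  fit
}

#' @export
print.ca_expfit <- function(x, ...) {
  cat(sprintf("<ca_expfit> A = %.4g, tau = %.4g ms, C = %.4g, minimum = %.4g\n",
              x$A, x$tau_ms, x$C, x$minimum))
  invisible(x)
}

#' Normalize a trace to its fitted minimum
#'
#' Maps the trace onto a common scale across slices: the baseline maps to
#' 1 and the fitted minimum to 0, via
#' `value = 1 + (v - baseline) / |min_value - baseline|`.
#' Applying the transform to an already normalized trace (with
#' `baseline = 1`, `min_value = 0`) returns it unchanged, and two traces
#' differing only by a positive gain normalize identically (dF/F0 input
#' is already gain-free).
#'
#' @param trace Tibble with `t_ms` and a value column (`dff` or `value`).
#' @param min_value The fitted minimum on the input scale (from
#'   [fit_exponential_min()]).
#' @param baseline The baseline on the input scale (default 0, the dF/F0
#'   baseline).
#' @return Tibble with `t_ms` and `value` (class `normalized_trace`).
#' @export
normalize_to_min <- function(trace, min_value, baseline = 0) {
  if (!is.finite(min_value) || min_value == baseline) {
    stop("zero reference: fitted minimum equals the baseline")
  }
  vcol <- intersect(c("dff", "value", "F"), names(trace))[1]
  if (is.na(vcol)) stop("no value column in trace")
  out <- tibble::tibble(
    t_ms = trace$t_ms,
    value = 1 + (trace[[vcol]] - baseline) / abs(min_value - baseline))
  attr(out, "stim_times_ms") <- attr(trace, "stim_times_ms")
  class(out) <- c("normalized_trace", class(out))
  out
}

#' Area between baseline and trace over a time window
#'
#' Trapezoidal integral of `(baseline - value)` from `t_start` to `t_end`
#' on the native time grid (linear interpolation at the window edges);
#' positive when the trace dips below baseline. Defaults integrate from
#' the first stimulus at 70 ms to the end of the 900 ms scan against the
#' y = 1 baseline of a min-normalized trace.
#'
#' @param norm_trace Tibble with `t_ms` and `value`.
#' @param t_start,t_end Window in ms (defaults 70 and 900).
#' @param baseline Baseline level (default 1).
#' @return Area in ms times normalized units.
#' @export
signal_area <- function(norm_trace, t_start = 70, t_end = 900, baseline = 1) {
  t <- norm_trace$t_ms
  v <- norm_trace$value
  if (t_start < min(t) || t_end > max(t) || t_start >= t_end) {
    stop("integration window outside the trace span")
  }
  tt <- sort(unique(c(t_start, t_end, t[t > t_start & t < t_end])))
  vv <- stats::approx(t, v, xout = tt)$y
  sum(diff(tt) * (baseline - (vv[-1] + vv[-length(vv)]) / 2))
}

#' Full analysis of one calcium trace
#'
#' dF/F0 over the pre-stimulus baseline, exponential fit of the
#' post-stimulus segment, normalization to the fitted minimum, and signal
#' area over the stimulus-to-end window.
#'
#' @param trace Tibble with `t_ms`, `F`; stimulus times from the
#'   `stim_times_ms` attribute or argument.
#' @param stim_times_ms Stimulus times (default from attribute, else 70).
#' @param baseline_window_ms Baseline window (default 0 to first stimulus
#'   minus 10 ms).
#' @param t_end_ms Integration end (default end of trace).
#' @param min_reference Reference minimum (dF/F0 scale) used for
#'   normalization. The default (`NULL`) uses the trace's own fitted
#'   minimum; pass one shared value per slice when comparing stimulus
#'   conditions within a slice, so relative amplitudes are preserved.
#' @return One-row tibble: `F0`, `A`, `tau_ms`, `C`, `minimum`, `area`.
#' @export
analyze_calcium_trace <- function(trace, stim_times_ms = NULL,
                                  baseline_window_ms = NULL,
                                  t_end_ms = NULL, min_reference = NULL) {
  if (is.null(stim_times_ms)) {
    stim_times_ms <- attr(trace, "stim_times_ms")
  }
  if (is.null(stim_times_ms)) stim_times_ms <- 70
  t1 <- stim_times_ms[1]
  if (is.null(baseline_window_ms)) baseline_window_ms <- c(0, t1 - 10)
  if (is.null(t_end_ms)) t_end_ms <- max(trace$t_ms)
  dff <- compute_dff(trace, baseline_window_ms)
  # fit the recovery from the post-stimulus extreme onward
  post <- dff[dff$t_ms >= t1, ]
  t_min <- post$t_ms[which.min(post$dff)]
  fit <- fit_exponential_min(dff, t_start = t_min)
  ref <- if (is.null(min_reference)) fit$minimum else min_reference
  norm <- normalize_to_min(dff, ref, baseline = 0)
  area <- signal_area(norm, t_start = t1, t_end = t_end_ms, baseline = 1)
  tibble::tibble(F0 = attr(dff, "F0"), A = fit$A, tau_ms = fit$tau_ms,
                 C = fit$C, minimum = fit$minimum, area = area)
}
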