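#' Fit a per-trace linear baseline by least squares
#'
#' Ordinary least-squares line over the full corridor trace (including the
#' F-wave). The residuals are orthogonal to the constant and linear terms:
#' the summed distances of samples above and below the line are equal in
#' absolute value.
#'
#' @param trace Numeric amplitude vector (uV).
#' @param sampling_rate Sampling rate in Hz (only sets the slope unit).
#' @return List with `slope` (uV/ms) and `intercept` (uV, at the first
#'   sample).
#' @examples
#' fit_linear_baseline(3 * (0:99) / 50 + 7, 50000)  # slope 3 uV/ms
#' @export
fit_linear_baseline <- function(trace, sampling_rate) {
  n <- length(trace)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  t <- 1000 * (seq_len(n) - 1) / sampling_rate      # ms from corridor start
  f <- stats::lm.fit(cbind(1, t), trace)
  list(slope = unname(f$coefficients[2]),
       intercept = unname(f$coefficients[1]))
}

#' Subtract the fitted linear baseline from a trace
#'
#' The fitted line is subtracted point by point, placing the trace on the
#' zero reference line without distorting its waveform: the input is
#' recovered sample-exactly as `output + fitted line`, and correcting an
#' already-corrected trace changes nothing.
#'
#' @inheritParams fit_linear_baseline
#' @param fit Optional precomputed [fit_linear_baseline()] result.
#' @return Numeric vector: the baseline-corrected trace.
#' @export
correct_baseline <- function(trace, sampling_rate, fit = NULL) {
  if (is.null(fit)) fit <- fit_linear_baseline(trace, sampling_rate)
  t <- 1000 * (seq_along(trace) - 1) / sampling_rate
  trace - (fit$intercept + fit$slope * t)
}

# Baseline-correct every trace of a corridor TraceSet.
correct_baseline_traces <- function(traces) {
  stopifnot(inherits(traces, "trace_set"))
  out <- traces
  out$samples <- t(apply(traces$samples, 1, correct_baseline,
                         sampling_rate = traces$sampling_rate))
  out
}
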