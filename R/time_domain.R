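#' Time-domain a- and b-wave measurement
#'
#' Conventional amplitude/implicit-time measures on an analysis-ready
#' epoch. The baseline is the mean of the pre-stimulus samples
#' (t < 0 ms). The a-trough is the minimum in the a-wave search window
#' (default 5..25 ms); `a_amp = max(0, baseline - trough)` so the a-wave
#' amplitude is a baseline-to-trough magnitude. The b-peak is the
#' maximum after the a-trough up to `b_max_ms`; `b_amp` is measured
#' trough-to-peak, the convention used for the light-adapted b-wave.
#' Both amplitudes are invariant to DC shifts of the trace.
#'
#' @param recording An [erg_recording()] covering \[0, `b_max_ms`\] ms.
#' @param a_window A-trough search window (ms), default `c(5, 25)`.
#' @param b_max_ms Upper bound of the b-peak search (ms), default 60.
#' @return A list of class `time_domain_features` with `a_amp`,
#'   `a_time_ms`, `b_amp`, `b_time_ms`.
#' @export
time_domain_features <- function(recording, a_window = c(5, 25),
                                 b_max_ms = 60) {
  stopifnot(inherits(recording, "erg_recording"))
  t <- recording$time_ms
  x <- recording$amplitude_uv
  if (a_window[1] < t[1] || b_max_ms > t[length(t)])
    stop(sprintf(
      "range error: search windows [%g, %g] ms outside epoch [%g, %g] ms",
      a_window[1], b_max_ms, t[1], t[length(t)]), call. = FALSE)
  pre <- x[t < 0]
  baseline <- if (length(pre)) mean(pre) else 0
  ia <- which(t >= a_window[1] & t <= a_window[2])
  if (!length(ia)) stop("range error: empty a-wave search window", call. = FALSE)
  trough_i <- ia[which.min(x[ia])]
  a_time <- t[trough_i]
  trough <- x[trough_i]
  ib <- which(t > a_time & t <= b_max_ms)
  if (!length(ib)) stop("range error: empty b-wave search window", call. = FALSE)
  peak_i <- ib[which.max(x[ib])]
  structure(list(
    a_amp = max(0, baseline - trough),
    a_time_ms = a_time,
    b_amp = x[peak_i] - trough,
    b_time_ms = t[peak_i]
  ), class = "time_domain_features")
}
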