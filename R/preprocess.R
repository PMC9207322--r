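#' Centile-based sweep rejection
#'
#' Implements the interquartile acceptance rule used when averaging
#' repeated sweeps: each sweep's peak-to-peak amplitude is computed and
#' only sweeps whose peak-to-peak lies within the inclusive
#' \[25th, 75th\] percentile band of the sweep set are kept. Percentiles
#' use the inverse-ECDF definition (`type = 1`), so observed sweep values
#' themselves delimit the band.
#'
#' @param traces Numeric matrix with one sweep per row (equal-length
#'   sweeps on identical time grids).
#' @return The kept subset of rows, with attribute `kept` giving their
#'   original row indices. Always contains at least one sweep.
#' @export
centile_rejection <- function(traces) {
  traces <- as.matrix(traces)
  if (nrow(traces) < 4L)
    stop("centile rejection needs at least 4 sweeps", call. = FALSE)
  ptp <- apply(traces, 1L, function(x) max(x) - min(x))
  q <- stats::quantile(ptp, c(0.25, 0.75), type = 1, names = FALSE)
  keep <- which(ptp >= q[1] & ptp <= q[2])
  if (!length(keep)) keep <- which.min(abs(ptp - stats::median(ptp)))[1]
  out <- traces[keep, , drop = FALSE]
  attr(out, "kept") <- keep
  out
}

#' Average repeated sweeps into one epoch
#'
#' Pointwise mean of the (optionally centile-filtered) sweeps.
#'
#' @param traces Numeric matrix, one sweep per row, or a list of
#'   [erg_recording()]s on identical grids.
#' @param rejection Apply [centile_rejection()] before averaging?
#' @return If `traces` is a matrix: the averaged sweep (numeric vector)
#'   with attributes `n_kept` and `n_total`. If a list of recordings: an
#'   [erg_recording()] whose metadata records `n_kept`/`n_total`.
#' @export
average_traces <- function(traces, rejection = FALSE) {
  if (is.list(traces) && all(vapply(traces, inherits, logical(1), "erg_recording"))) {
    grids <- vapply(traces, function(r) paste(format(r$time_ms, digits = 15),
                                              collapse = ","), character(1))
    if (length(unique(grids)) != 1L)
      stop("recordings must share an identical time grid", call. = FALSE)
    m <- do.call(rbind, lapply(traces, function(r) r$amplitude_uv))
    avg <- average_traces(m, rejection = rejection)
    tmpl <- traces[[1]]
    md <- tmpl$metadata
    md$n_kept <- attr(avg, "n_kept"); md$n_total <- attr(avg, "n_total")
    return(erg_recording(tmpl$participant_id, tmpl$group, tmpl$eye,
                         tmpl$flash_strength, tmpl$time_ms, as.numeric(avg),
                         metadata = md))
  }
  traces <- as.matrix(traces)
  n_total <- nrow(traces)
  if (rejection) traces <- centile_rejection(traces)
  out <- colMeans(traces)
  attr(out, "n_kept") <- nrow(traces)
  attr(out, "n_total") <- n_total
  out
}

#' Quality-control filter for a recording
#'
#' Inclusion rules: the photopic a-wave amplitude must exceed 1 uV, and
#' the recording electrode must not sit more than 2 mm below the
#' reference position (height -2 is still acceptable; below -2 is not).
#' Missing metadata never fails a recording.
#'
#' @param recording Optional [erg_recording()]; used only to label the
#'   report and to read `electrode_height_mm` from metadata when the
#'   argument is not given.
#' @param a_amp Measured a-wave amplitude (uV), e.g. from
#'   [time_domain_features()].
#' @param electrode_height_mm Electrode height in mm relative to the
#'   reference level (integer in -2..+2), or `NULL`/`NA` if unknown.
#' @return A one-row tibble (class `qc_report`) with columns `key`,
#'   `passed` and `reasons` (character, semicolon-joined).
#' @export
qc_filter <- function(recording = NULL, a_amp, electrode_height_mm = NULL) {
  if (is.null(electrode_height_mm) && !is.null(recording))
    electrode_height_mm <- recording$metadata$electrode_height_mm
  reasons <- character(0)
  if (is.na(a_amp) || a_amp <= 1) reasons <- c(reasons, "a_wave_too_small")
  if (!is.null(electrode_height_mm) && !is.na(electrode_height_mm) &&
      electrode_height_mm < -2)
    reasons <- c(reasons, "electrode_too_low")
  out <- tibble::tibble(
    key = if (is.null(recording)) NA_character_ else rec_key(recording),
    passed = length(reasons) == 0L,
    reasons = paste(reasons, collapse = ";"))
  class(out) <- c("qc_report", class(out))
  out
}

#' Resample a recording onto the analysis epoch grid
#'
#' Linear interpolation onto a uniform target grid (no extrapolation).
#' The default grid is the dyadic analysis standard: 256 samples at
#' 2048 Hz from -20 ms. If the recording is already on the requested
#' grid it is returned unchanged (flagged analysis-ready).
#'
#' @param recording An [erg_recording()].
#' @param target_rate_hz Target sampling rate (Hz).
#' @param epoch Epoch as `list(start_ms=, n_samples=)`.
#' @return An [erg_recording()] with metadata flag `analysis_ready`.
#' @export
resample_epoch <- function(recording, target_rate_hz = 2048,
                           epoch = list(start_ms = -20, n_samples = 256)) {
  stopifnot(inherits(recording, "erg_recording"))
  tt <- epoch$start_ms + (seq_len(epoch$n_samples) - 1) * 1000 / target_rate_hz
  t0 <- recording$time_ms
  eps <- 1e-9 * max(1, 1000 / target_rate_hz)
  if (tt[1] < t0[1] - eps || tt[length(tt)] > t0[length(t0)] + eps)
    stop(sprintf(
      "range error: requested epoch [%g, %g] ms outside recorded range [%g, %g] ms",
      tt[1], tt[length(tt)], t0[1], t0[length(t0)]), call. = FALSE)
  same_grid <- length(tt) == length(t0) && all(abs(tt - t0) <= eps)
  amp <- if (same_grid) recording$amplitude_uv else
    stats::approx(t0, recording$amplitude_uv, xout = tt, rule = 1)$y
  md <- recording$metadata
  md$analysis_ready <- TRUE
  erg_recording(recording$participant_id, recording$group, recording$eye,
                recording$flash_strength, time_ms = tt, amplitude_uv = amp,
                sampling_rate_hz = target_rate_hz, metadata = md)
}

#' Export a set of QC reports as TSV
#'
#' @param reports A tibble of rows from [qc_filter()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(reports, path) {
  readr::write_tsv(reports, path, progress = FALSE)
  invisible(path)
}
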