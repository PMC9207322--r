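#' @title Canonical flash-ERG epoch container
#'
#' @description
#' `erg_recording()` constructs one epoch of amplitude-versus-time for a
#' single participant, eye and flash strength. Time is in milliseconds with
#' flash onset at 0 ms (pre-stimulus samples are negative), amplitude in
#' microvolts. The time grid must be strictly increasing and uniform; the
#' sampling rate is derived from (and checked against) the grid spacing.
#'
#' @param participant_id Character scalar identifying the participant.
#' @param group One of `"ASD"`, `"ADHD"`, `"control"`, `"other"`.
#' @param eye `"right"` or `"left"`.
#' @param flash_strength Flash strength in log photopic cd.s.m-2.
#' @param time_ms Numeric vector of sample times (ms), strictly increasing
#'   and uniformly spaced.
#' @param amplitude_uv Numeric vector of amplitudes (uV), same length as
#'   `time_ms`, all finite.
#' @param sampling_rate_hz Optional sampling rate; when supplied it must be
#'   consistent with the grid spacing to within 1e-6 relative.
#' @param metadata Named list of per-recording metadata. Recognised keys
#'   include `iris_color_index`, `electrode_height_mm` (integer in -2..+2),
#'   `age_years`, `sex`, `rep` (repeat index, default 0).
#'
#' @return An object of class `erg_recording`.
#' @export
erg_recording <- function(participant_id, group, eye, flash_strength,
                          time_ms, amplitude_uv,
                          sampling_rate_hz = NULL, metadata = list()) {
  group <- match.arg(as.character(group), c("ASD", "ADHD", "control", "other"))
  eye <- match.arg(as.character(eye), c("right", "left"))
  stopifnot(is.numeric(time_ms), is.numeric(amplitude_uv))
  n <- length(time_ms)
  if (n < 2L) stop("an ERG recording needs at least two samples", call. = FALSE)
  if (length(amplitude_uv) != n)
    stop("amplitude_uv and time_ms must have the same length", call. = FALSE)
  if (!all(is.finite(amplitude_uv)))
    stop("amplitude_uv must be finite everywhere", call. = FALSE)
  dt <- diff(time_ms)
  if (any(dt <= 0))
    stop("time_ms must be strictly increasing", call. = FALSE)
  dt0 <- (time_ms[n] - time_ms[1]) / (n - 1)
  if (any(abs(dt - dt0) > 1e-9 * max(abs(dt0), 1)))
    stop("time_ms must be uniformly spaced (non-uniform grid)", call. = FALSE)
  fs <- 1000 / dt0
  if (!is.null(sampling_rate_hz)) {
    if (abs(sampling_rate_hz - fs) > 1e-6 * fs)
      stop(sprintf(
        "sampling_rate_hz (%g) inconsistent with time spacing (implies %g Hz)",
        sampling_rate_hz, fs), call. = FALSE)
    fs <- sampling_rate_hz
  }
  structure(
    list(
      participant_id = as.character(participant_id),
      group = group,
      eye = eye,
      flash_strength = as.numeric(flash_strength),
      time_ms = as.numeric(time_ms),
      amplitude_uv = as.numeric(amplitude_uv),
      sampling_rate_hz = fs,
      metadata = metadata
    ),
    class = "erg_recording"
  )
}

#' @export
print.erg_recording <- function(x, ...) {
  cat(sprintf(
    "<erg_recording> %s / %s eye / %s / flash %.3f log phot cd.s.m-2\n",
    x$participant_id, x$eye, x$group, x$flash_strength))
  cat(sprintf("  %d samples, %.6g ms to %.6g ms @ %.6g Hz\n",
              length(x$time_ms), x$time_ms[1],
              x$time_ms[length(x$time_ms)], x$sampling_rate_hz))
  invisible(x)
}

rec_repeat <- function(rec) {
  r <- rec$metadata$rep
  if (is.null(r)) 0L else as.integer(r)
}

rec_key <- function(rec) {
  sprintf("%s|%s|%.9g|%d", rec$participant_id, rec$eye,
          rec$flash_strength, rec_repeat(rec))
}

#' Collection of ERG recordings
#'
#' An `erg_study` bundles a list of [erg_recording()] objects with
#' provenance information (source path, filters applied). Keys
#' (participant, eye, flash, repeat) must be unique.
#'
#' @param recordings List of `erg_recording` objects.
#' @param provenance Named list describing where the data came from.
#' @return An object of class `erg_study`.
#' @export
erg_study <- function(recordings, provenance = list()) {
  if (!is.list(recordings) ||
      !all(vapply(recordings, inherits, logical(1), "erg_recording")))
    stop("recordings must be a list of erg_recording objects", call. = FALSE)
  keys <- vapply(recordings, rec_key, character(1))
  if (anyDuplicated(keys))
    stop("duplicate (participant, eye, flash, repeat) keys in study",
         call. = FALSE)
  structure(list(recordings = recordings, provenance = provenance),
            class = "erg_study")
}

#' @export
print.erg_study <- function(x, ...) {
  groups <- table(vapply(x$recordings, function(r) r$group, character(1)))
  cat(sprintf("<erg_study> %d recordings (%s)\n", length(x$recordings),
              paste(sprintf("%s: %d", names(groups), groups), collapse = ", ")))
  invisible(x)
}

#' @export
length.erg_study <- function(x) length(x$recordings)

waveform_columns <- c("participant", "group", "eye", "flash",
                      "time_ms", "microvolts")

#' Read waveforms from a long-format CSV
#'
#' The canonical dialect is one sample per row with columns
#' `participant,group,eye,flash,repeat,time_ms,microvolts` (the `repeat`
#' column is optional and defaults to 0). One recording is produced per
#' (participant, eye, flash, repeat); rows within a recording are sorted by
#' time.
#'
#' @param path Path to a CSV file.
#' @param dialect Input dialect; only `"long_csv"` is supported.
#' @return An [erg_study()].
#' @export
read_waveforms <- function(path, dialect = "long_csv") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  missing <- setdiff(waveform_columns, names(df))
  if (length(missing))
    stop(sprintf("schema error: missing column(s) %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (!"repeat" %in% names(df)) df[["repeat"]] <- "0"
  for (col in c("flash", "time_ms", "microvolts")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("parse error: non-numeric %s at data row %d (value '%s')",
                   col, bad[1], df[[col]][bad[1]]), call. = FALSE)
    if (anyNA(v))
      stop(sprintf("parse error: missing %s at data row %d", col,
                   which(is.na(v))[1]), call. = FALSE)
    df[[col]] <- v
  }
  key <- paste(df$participant, df$eye, format(df$flash, digits = 12),
               df[["repeat"]], sep = "|")
  if (anyDuplicated(paste(key, format(df$time_ms, digits = 15), sep = "|")))
    stop("structural error: duplicated (participant, eye, flash, repeat, time) row",
         call. = FALSE)
  recs <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    sub <- df[idx, , drop = FALSE]
    sub <- sub[order(sub$time_ms), , drop = FALSE]
    md <- list(rep = as.integer(sub[["repeat"]][1]))
    tryCatch(
      erg_recording(sub$participant[1], sub$group[1], sub$eye[1],
                    sub$flash[1], sub$time_ms, sub$microvolts,
                    metadata = md),
      error = function(e) stop(sprintf(
        "structural error in recording %s/%s/flash %g: %s",
        sub$participant[1], sub$eye[1], sub$flash[1], conditionMessage(e)),
        call. = FALSE))
  })
  names(recs) <- NULL
  recs <- recs[order(vapply(recs, rec_key, character(1)), method = "radix")]
  erg_study(recs, provenance = list(source = path, dialect = dialect))
}

#' Write a study to a long-format CSV
#'
#' Writes one sample per row in the canonical dialect of
#' [read_waveforms()]. Numeric values are serialized at full
#' (round-trippable) precision, so write/read reproduces amplitudes
#' bit-identically and write/read/write is byte-stable.
#'
#' @param study An [erg_study()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_waveforms <- function(study, path) {
  stopifnot(inherits(study, "erg_study"))
  if (!length(study$recordings))
    stop("refusing to write an empty study", call. = FALSE)
  # canonical key order makes write -> read -> write byte-stable
  recs <- study$recordings[order(vapply(study$recordings, rec_key,
                                        character(1)), method = "radix")]
  tabs <- lapply(recs, function(r) {
    tibble::tibble(
      participant = r$participant_id, group = r$group, eye = r$eye,
      flash = r$flash_strength, `repeat` = rec_repeat(r),
      time_ms = r$time_ms, microvolts = r$amplitude_uv)
  })
  df <- dplyr::bind_rows(tabs)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
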