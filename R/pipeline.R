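#' Distribution-free confidence interval for the median
#'
#' Median with a conservative two-sided confidence interval from
#' binomial order statistics: the widest symmetric pair of order
#' statistics `(x_(l), x_(n+1-l))` whose coverage is at least `level`.
#' Endpoints are always observed sample values. For n < 6 no
#' order-statistic interval reaches 95% coverage; the full range is
#' returned with a warning.
#'
#' @param sample Numeric vector.
#' @param level Confidence level, default 0.95.
#' @return List with `median`, `lower`, `upper`, `coverage`,
#'   `degenerate` (TRUE when n < 2).
#' @export
median_ci <- function(sample, level = 0.95) {
  x <- sort(sample[is.finite(sample)])
  n <- length(x)
  if (n < 2L)
    return(list(median = if (n) x else NA_real_, lower = NA_real_,
                upper = NA_real_, coverage = NA_real_, degenerate = TRUE))
  m <- stats::median(x)
  alpha <- 1 - level
  # largest l with P(Bin(n, 1/2) < l) <= alpha/2
  l <- stats::qbinom(alpha / 2, n, 0.5)
  if (stats::pbinom(l - 1, n, 0.5) > alpha / 2) l <- l - 1L
  if (l < 1L) {
    l <- 1L
    if (1 - 2 * stats::pbinom(0, n, 0.5) < level)
      warning(sprintf(
        "n = %d: order-statistic CI cannot reach %.0f%% coverage", n,
        100 * level), call. = FALSE)
  }
  u <- n + 1L - l
  list(median = m, lower = x[l], upper = x[u],
       coverage = 1 - 2 * stats::pbinom(l - 1, n, 0.5), degenerate = FALSE)
}

#' Study configuration
#'
#' Validated configuration for [run_study()]. Exactly one of `cohort`
#' (a [cohort_spec()] to simulate) or `waveforms` (path to a long CSV for
#' [read_waveforms()]) must be supplied. Unknown fields are rejected.
#'
#' @param cohort Optional [cohort_spec()].
#' @param waveforms Optional path to a waveform CSV.
#' @param grid Analysis grid, an [epoch_grid()].
#' @param windows Descriptor windows as from [descriptor_windows()].
#' @param mode Descriptor aggregation mode (see [extract_descriptors()]).
#' @param flashes Flash strengths to analyze (`NULL` = all present).
#' @param eye_rule How the two eyes are combined per participant:
#'   `"mean"` (mean of the eyes' feature values, default),
#'   `"right_only"`, `"left_only"`, or `"both_as_units"` (each eye is an
#'   analysis unit; inflates n and is flagged non-default).
#' @param alpha Simultaneous significance level.
#' @param stringent_p Fixed stringent cut-off reported alongside.
#' @param outdir Optional output directory for TSV artifacts.
#' @param seed Integer seed driving all randomness.
#' @return A list of class `study_config`.
#' @export
study_config <- function(cohort = NULL, waveforms = NULL,
                         grid = epoch_grid(),
                         windows = descriptor_windows(),
                         mode = c("rss", "max_abs", "sum_abs"),
                         flashes = NULL,
                         eye_rule = c("mean", "right_only", "left_only",
                                      "both_as_units"),
                         alpha = 0.05, stringent_p = 0.005,
                         outdir = NULL, seed = 1L) {
  mode <- match.arg(mode)
  eye_rule <- match.arg(eye_rule)
  if (is.null(cohort) == is.null(waveforms))
    stop("supply exactly one of cohort or waveforms", call. = FALSE)
  if (!is.null(cohort)) stopifnot(inherits(cohort, "cohort_spec"))
  if (!is.null(waveforms) && !file.exists(waveforms))
    stop(sprintf("waveform file not found: %s", waveforms), call. = FALSE)
  stopifnot(alpha > 0, alpha < 1, stringent_p > 0, stringent_p < 1)
  structure(list(cohort = cohort, waveforms = waveforms, grid = grid,
                 windows = windows, mode = mode, flashes = flashes,
                 eye_rule = eye_rule, alpha = alpha,
                 stringent_p = stringent_p, outdir = outdir,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Validate a configuration given as a plain list (e.g. parsed JSON)
#'
#' Unknown keys are rejected; known keys are passed to [study_config()].
#'
#' @param x Named list.
#' @return A `study_config`.
#' @export
as_study_config <- function(x) {
  if (inherits(x, "study_config")) return(x)
  known <- setdiff(names(formals(study_config)), "...")
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop(sprintf("unknown config field(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  do.call(study_config, x)
}

study_parameters <- c("b_amp", "a20", "a40", "b20", "b40",
                      "op80", "op160", "pct_ops")

#' Per-recording feature extraction
#'
#' Resamples each recording onto the analysis grid, measures time-domain
#' a-/b-wave features, runs QC, and extracts the six DWT descriptors and
#' %OPs.
#'
#' @param study An [erg_study()].
#' @param config A [study_config()].
#' @return List with `features` (tibble, one row per recording that
#'   passed QC), `qc` (tibble, one row per recording), `excluded`
#'   (character keys of QC failures).
#' @export
extract_study_features <- function(study, config) {
  stopifnot(inherits(study, "erg_study"))
  n <- length(study$recordings)
  num_cols <- c("b_amp", "a_amp", "a20", "a40", "b20", "b40",
                "op80", "op160", "pct_ops")
  feat <- c(list(participant = character(n), group = character(n),
                 eye = character(n), flash = numeric(n)),
            stats::setNames(rep(list(numeric(n)), length(num_cols)),
                            num_cols))
  qc_key <- character(n); qc_pass <- logical(n); qc_reason <- character(n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    rec <- resample_epoch(study$recordings[[i]],
                          target_rate_hz = config$grid$sampling_rate_hz,
                          epoch = config$grid)
    td <- time_domain_features(rec)
    qc <- qc_filter(rec, a_amp = td$a_amp)
    qc_key[i] <- qc$key; qc_pass[i] <- qc$passed; qc_reason[i] <- qc$reasons
    if (!qc$passed) next
    keep[i] <- TRUE
    desc <- descriptors_from_pyramid(haar_dwt(rec),
                                     windows = config$windows,
                                     mode = config$mode)
    feat$participant[i] <- rec$participant_id
    feat$group[i] <- rec$group
    feat$eye[i] <- rec$eye
    feat$flash[i] <- rec$flash_strength
    feat$b_amp[i] <- td$b_amp; feat$a_amp[i] <- td$a_amp
    for (dcol in names(desc)) feat[[dcol]][i] <- desc[[dcol]]
  }
  feats <- tibble::as_tibble(lapply(feat, function(v) v[keep]))
  qc <- tibble::tibble(key = qc_key, passed = qc_pass, reasons = qc_reason)
  list(features = feats, qc = qc, excluded = qc$key[!qc$passed])
}

aggregate_eyes <- function(features, eye_rule) {
  if (eye_rule == "right_only") features <- features[features$eye == "right", ]
  if (eye_rule == "left_only") features <- features[features$eye == "left", ]
  if (eye_rule %in% c("right_only", "left_only", "both_as_units")) {
    if (eye_rule == "both_as_units")
      features$participant <- paste(features$participant, features$eye,
                                    sep = ":")
    return(features)
  }
  # mean of the two eyes' feature values per participant x flash
  dplyr::summarise(
    dplyr::group_by(features, .data$participant, .data$group, .data$flash),
    dplyr::across(dplyr::all_of(c("b_amp", "a_amp", study_parameters[-1])),
                  ~ mean(.x, na.rm = TRUE)),
    .groups = "drop")
}

#' Run the full simulate/extract/compare pipeline
#'
#' Generates (or reads) the cohort, extracts features with QC, aggregates
#' eyes per the configured rule, and for every flash x parameter computes
#' per-group medians with distribution-free 95% CIs and the Tukey-type
#' nonparametric contrasts. All randomness derives from `config$seed`.
#'
#' @param config A [study_config()].
#' @return List of class `erg_study_results` with `results` (tibble:
#'   flash, parameter, per-group `<g>_median`/`_lower`/`_upper`, one
#'   `p_<j>_v_<i>` column per contrast), `contrasts` (long tibble of all
#'   [mctp_tukey()] rows), `features`, `qc`, `excluded`, `config`.
#'   When `config$outdir` is set, writes `results.tsv`,
#'   `descriptors.tsv`, `qc.tsv` and `config.json` there.
#' @export
run_study <- function(config) {
  config <- as_study_config(config)
  study <- if (!is.null(config$cohort)) {
    spec <- config$cohort
    spec$seed <- config$seed
    generate_cohort(spec)
  } else {
    read_waveforms(config$waveforms)
  }
  ex <- extract_study_features(study, config)
  feats <- aggregate_eyes(ex$features, config$eye_rule)

  groups_present <- sort(unique(feats$group))
  if (length(groups_present) < 2L) {
    empty <- setdiff(unique(vapply(study$recordings, function(r) r$group,
                                   character(1))), groups_present)
    stop(sprintf(
      "group(s) %s emptied by QC filter (a-wave/electrode rules)",
      paste(empty, collapse = ", ")), call. = FALSE)
  }
  flashes <- config$flashes
  if (is.null(flashes)) flashes <- sort(unique(feats$flash))

  res_rows <- list()
  contrast_rows <- list()
  for (fl in flashes) {
    sub <- feats[abs(feats$flash - fl) < 1e-9, ]
    for (par in study_parameters) {
      vals <- split(sub[[par]][is.finite(sub[[par]])],
                    sub$group[is.finite(sub[[par]])])
      vals <- vals[lengths(vals) > 0]
      if (length(vals) < 2L) next
      mc <- suppressWarnings(
        mctp_tukey(vals, alpha = config$alpha,
                   stringent_p = config$stringent_p,
                   qmc_seed = config$seed + 20104L))
      row <- tibble::tibble(flash = fl, parameter = par)
      for (g in names(vals)) {
        ci <- suppressWarnings(median_ci(vals[[g]]))
        row[[paste0(g, "_median")]] <- ci$median
        row[[paste0(g, "_lower")]] <- ci$lower
        row[[paste0(g, "_upper")]] <- ci$upper
        row[[paste0(g, "_n")]] <- length(vals[[g]])
      }
      for (k in seq_len(nrow(mc))) {
        row[[sprintf("p_%s_v_%s", mc$group_j[k], mc$group_i[k])]] <-
          mc$p_adjusted[k]
      }
      res_rows[[length(res_rows) + 1L]] <- row
      mc2 <- tibble::as_tibble(mc)
      mc2$flash <- fl
      mc2$parameter <- par
      contrast_rows[[length(contrast_rows) + 1L]] <- mc2
    }
  }
  results <- dplyr::bind_rows(res_rows)
  contrasts <- dplyr::bind_rows(contrast_rows)
  out <- structure(list(results = results, contrasts = contrasts,
                        features = feats, qc = ex$qc,
                        excluded = ex$excluded, config = config),
                   class = "erg_study_results")
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(results, file.path(config$outdir, "results.tsv"),
                     progress = FALSE)
    readr::write_tsv(feats, file.path(config$outdir, "descriptors.tsv"),
                     progress = FALSE)
    write_qc_report(ex$qc, file.path(config$outdir, "qc.tsv"))
    cfg <- config[c("mode", "eye_rule", "alpha", "stringent_p", "seed")]
    jsonlite::write_json(cfg, file.path(config$outdir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.erg_study_results <- function(x, ...) {
  cat(sprintf("<erg_study_results> %d flash x parameter rows, %d features, %d excluded by QC\n",
              nrow(x$results), nrow(x$features), length(x$excluded)))
  invisible(x)
}

format_pval <- function(p) {
  ifelse(p < 1e-16, "<1e-16", formatC(p, format = "g", digits = 2))
}

#' Render a results table as TSV or markdown
#'
#' The markdown layout mirrors the study's summary table: one row per
#' flash x parameter, group median (95% CI) column blocks, contrast
#' p-value columns trailing. Adjusted p-values below 1e-16 are rendered
#' as `<1e-16`. TSV and markdown contain the same numeric values.
#'
#' @param results The `results` tibble of an `erg_study_results` (or the
#'   object itself).
#' @param format `"tsv"` or `"markdown"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
render_report <- function(results, format = c("tsv", "markdown"), path) {
  format <- match.arg(format)
  if (inherits(results, "erg_study_results")) results <- results$results
  if (!nrow(results)) stop("empty results table", call. = FALSE)
  if (format == "tsv") {
    readr::write_tsv(results, path, progress = FALSE)
    return(invisible(path))
  }
  pcols <- grep("^p_", names(results), value = TRUE)
  groups <- unique(sub("_median$", "", grep("_median$", names(results),
                                            value = TRUE)))
  header <- c("FS", "Parameter",
              unlist(lapply(groups, function(g)
                c(paste0(g, " Mdn"), "L", "U"))),
              sub("^p_", "", pcols))
  lines <- c(paste0("| ", paste(header, collapse = " | "), " |"),
             paste0("|", paste(rep("---", length(header)), collapse = "|"),
                    "|"))
  for (k in seq_len(nrow(results))) {
    row <- results[k, ]
    cells <- c(format(row$flash, digits = 4), row$parameter)
    for (g in groups) {
      cells <- c(cells,
                 formatC(row[[paste0(g, "_median")]], format = "g", digits = 4),
                 formatC(row[[paste0(g, "_lower")]], format = "g", digits = 4),
                 formatC(row[[paste0(g, "_upper")]], format = "g", digits = 4))
    }
    cells <- c(cells, vapply(pcols, function(pc) format_pval(row[[pc]]),
                             character(1)))
    lines <- c(lines, paste0("| ", paste(cells, collapse = " | "), " |"))
  }
  writeLines(lines, path)
  invisible(path)
}
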