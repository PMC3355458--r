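#' Read a sensor recording from CSV
#'
#' The interchange format is a plain seven-column CSV with header
#' `time_s, fwd_a_g, side_a_g, up_a_g, roll_dps, pitch_dps, yaw_dps`.
#' The sampling rate is inferred from the median time step; the time
#' column must be strictly increasing and uniform to within 1% of the
#' median step (downstream processing assumes uniform sampling and no
#' resampling is attempted).
#'
#' @param path Path to a CSV file.
#' @return A [signal_series()]; `meta$source` records the path.
#' @export
read_signal_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  expected <- c("time_s", "fwd_a_g", "side_a_g", "up_a_g",
                "roll_dps", "pitch_dps", "yaw_dps")
  missing <- setdiff(expected, names(df))
  if (length(missing))
    stop("signal CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(df), expected)
  if (length(extra))
    stop("signal CSV has unexpected column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  tt <- df$time_s
  if (length(tt) < 1L) stop("signal CSV has no data rows", call. = FALSE)
  if (length(tt) > 1L) {
    dt <- diff(tt)
    if (any(dt <= 0)) stop("time_s must be strictly increasing", call. = FALSE)
    med <- stats::median(dt)
    if (any(abs(dt - med) > 0.01 * med))
      stop("non-uniform time step (tolerance 1% of median step)", call. = FALSE)
    rate <- 1 / med
  } else {
    rate <- 100
  }
  signal_series(
    fwd_a = df$fwd_a_g, side_a = df$side_a_g, up_a = df$up_a_g,
    roll = df$roll_dps, pitch = df$pitch_dps, yaw = df$yaw_dps,
    sample_rate_hz = rate,
    meta = list(source = path)
  )
}

#' Write a sensor recording to CSV
#'
#' Writes the seven-column interchange CSV (see [read_signal_csv()]).
#' Times are regenerated as `index / sample_rate_hz` and all values are
#' written with six decimal places, so a write/read round trip reproduces
#' the series to 1e-6 per sample.
#'
#' @param series A [signal_series()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_signal_csv <- function(series, path) {
  validate_signal_series(series)
  df <- as.data.frame(series)
  df[] <- lapply(df, function(v) sprintf("%.6f", v))
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write signal CSV to: ", path, call. = FALSE)
  invisible(path)
}

#' Write a classification or asymmetry report as JSON
#'
#' Serialises a [classify_series()] result or an [asymmetry_index()]
#' report to a structured JSON document with a `schema_version` field.
#' Classification reports contain the label, the full rule evidence
#' trail (rule name, measured value, threshold, comparison operator,
#' pass flag) and a segmentation summary.
#'
#' @param result A `ski_classification` or `asymmetry_report` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(result, path) {
  doc <- as_report_list(result)
  ok <- tryCatch({
    writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, null = "null"), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write report to: ", path, call. = FALSE)
  invisible(path)
}

as_report_list <- function(result) UseMethod("as_report_list")

#' @export
as_report_list.ski_classification <- function(result) {
  ev <- result$evidence
  list(
    schema_version = 1L,
    kind = "classification",
    label = if (is.na(result$label)) "none" else result$label,
    confidence = result$confidence,
    evidence = lapply(seq_len(nrow(ev)), function(i) {
      list(rule = ev$rule[i], value = ev$value[i], threshold = ev$threshold[i],
           op = ev$op[i], passed = ev$passed[i])
    }),
    segmentation = list(
      n_cycles = result$segmentation$n_cycles,
      cycle_rate_hz = result$segmentation$cycle_rate_hz,
      anchor_channel = result$segmentation$anchor_channel,
      family = result$segmentation$family
    )
  )
}

#' @export
as_report_list.asymmetry_report <- function(result) {
  list(
    schema_version = 1L,
    kind = "asymmetry",
    channels = lapply(result$channels, function(ch) {
      list(mean_L = ch$mean_L, mean_R = ch$mean_R, index = ch$index)
    }),
    n_half_cycles = result$n_half_cycles,
    flag_threshold = result$flag_threshold,
    flagged = result$flagged
  )
}
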