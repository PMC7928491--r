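#' Read and write current traces
#'
#' Two interchange formats are supported in both directions:
#' * `"raw"` — little-endian 32-bit floats plus a JSON sidecar
#'   (`<path>.json`) carrying `sampling_rate`, `units`, optional
#'   `scale` (samples are multiplied by it on read), and filter
#'   corners. Round trips are bit-identical at float32 precision.
#' * `"csv"` — two columns `time_s, current_pA`; the sampling rate is
#'   inferred from the (required uniform) time step.
#'
#' Axon Binary Format (ABF) files are not parsed; convert to either
#' supported format upstream.
#'
#' @param path file path (for `"raw"`, the sidecar is `<path>.json`).
#' @param format `"raw"` or `"csv"` (default: by file extension).
#' @return `readTrace`: a [ChannelTrace].
#' @export
readTrace <- function(path, format = c("auto", "raw", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "raw"
  if (!file.exists(path)) stop("trace file not found: ", path)
  if (format == "csv") {
    d <- utils::read.csv(path)
    if (!all(c("time_s", "current_pA") %in% names(d)))
      stop("CSV trace must have columns time_s, current_pA")
    dt <- diff(d$time_s)
    if (length(dt) < 1) stop("CSV trace needs at least 2 samples")
    if (max(abs(dt - dt[1])) > 1e-9 * dt[1])
      stop("non-uniform timestamps in CSV trace")
    return(new("ChannelTrace", samples = d$current_pA,
               samplingRate = 1 / dt[1],
               onlineFilterHz = NA_real_, offlineFilterHz = NA_real_,
               metadata = list(source = path)))
  }
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing JSON sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$sampling_rate))
    stop("sidecar missing required field 'sampling_rate'")
  if (!is.null(meta$units) && meta$units != "pA")
    stop("unsupported units '", meta$units, "': expected pA")
  n <- file.size(path) / 4
  x <- readBin(path, "numeric", n = n, size = 4, endian = "little")
  if (!is.null(meta$scale)) x <- x * meta$scale
  new("ChannelTrace", samples = x,
      samplingRate = as.numeric(meta$sampling_rate),
      onlineFilterHz = if (is.null(meta$online_filter_hz)) NA_real_
                       else as.numeric(meta$online_filter_hz),
      offlineFilterHz = if (is.null(meta$offline_filter_hz)) NA_real_
                        else as.numeric(meta$offline_filter_hz),
      metadata = list(source = path))
}

#' @rdname readTrace
#' @param trace a [ChannelTrace] to write.
#' @export
writeTrace <- function(trace, path, format = c("auto", "raw", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "raw"
  if (format == "csv") {
    n <- length(trace@samples)
    utils::write.csv(
      data.frame(time_s = (seq_len(n) - 1) / trace@samplingRate,
                 current_pA = trace@samples),
      path, row.names = FALSE)
    return(invisible(path))
  }
  writeBin(trace@samples, path, size = 4, endian = "little")
  meta <- list(sampling_rate = trace@samplingRate, units = "pA")
  if (is.finite(trace@onlineFilterHz))
    meta$online_filter_hz <- trace@onlineFilterHz
  if (is.finite(trace@offlineFilterHz))
    meta$offline_filter_hz <- trace@offlineFilterHz
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read and write idealized event lists as CSV
#'
#' Columns: `onset_s` (seconds), `duration_ms` (ms — note the mixed
#' units, which mirror standard reporting), `kind`, `amplitude_pA`,
#' `class_label`, `censored`. Round trips are lossless to 1e-9. Legacy
#' files without `class_label` load with label `"single"` for open
#' events.
#'
#' @param path CSV file path.
#' @return `readEvents`: an [EventList].
#' @export
readEvents <- function(path) {
  if (!file.exists(path)) stop("events file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("onset_s", "duration_ms", "kind", "amplitude_pA", "censored")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("events file missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (!"class_label" %in% names(d))
    d$class_label <- ifelse(d$kind == "open", "single", "")
  bad <- which(d$duration_ms <= 0)
  if (length(bad)) stop("non-positive duration at row ", bad[1])
  if (nrow(d) > 1) {
    same <- which(d$kind[-1] == d$kind[-nrow(d)])
    if (length(same))
      stop("events do not alternate at row ", same[1] + 1L)
  }
  d$censored <- as.logical(d$censored)
  new("EventList", events = d[, .eventColumns],
      metadata = list(source = path))
}

#' @rdname readEvents
#' @param events an [EventList] to write.
#' @export
writeEvents <- function(events, path) {
  ev <- events@events
  ev$onset_s <- formatC(ev$onset_s, format = "g", digits = 15)
  ev$duration_ms <- formatC(ev$duration_ms, format = "g", digits = 15)
  ev$amplitude_pA <- formatC(ev$amplitude_pA, format = "g", digits = 15)
  utils::write.csv(ev, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
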