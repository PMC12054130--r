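#' Write a gaze trace to CSV (with JSON metadata sidecar)
#'
#' Writes the trace in the package's CSV dialect: header
#' `time_s,fixating_deg,covered_deg,missing`, one row per sample, with a
#' fixed full-precision numeric format (`%.17g`, lossless for doubles)
#' so that identical traces produce byte-identical files and reading a
#' written trace reproduces it exactly. Gaze values at missing (blink)
#' samples are written as `NA`.
#' Metadata that cannot live in the rectangular file (covered eye side,
#' sampling rate, subject id, diagnosis, APCT value, simulator ground
#' truth) goes to a JSON sidecar at `<path>.json`.
#'
#' @param trace a [gaze_trace()].
#' @param path output CSV path.
#' @param sidecar write the JSON sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, sidecar = TRUE) {
  stopifnot(inherits(trace, "gaze_trace"))
  num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  lines <- c("time_s,fixating_deg,covered_deg,missing",
             paste(num(trace$time_s), num(trace$fixating_deg),
                   num(trace$covered_deg),
                   as.integer(trace$missing), sep = ","))
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e),
         call. = FALSE)
  })
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  if (sidecar) {
    meta <- list(covered_eye_side = trace$covered_eye_side,
                 fs_hz = trace$fs_hz,
                 subject_id = trace$subject_id,
                 diagnosis = trace$diagnosis,
                 apct_pd = trace$apct_pd,
                 ground_truth = trace$ground_truth)
    meta <- meta[!vapply(meta, is.null, logical(1))]
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a gaze trace from CSV
#'
#' Parses the dialect written by [write_trace_csv()] and validates the
#' result: the header must declare exactly the four expected columns,
#' every non-missing cell must be numeric, timestamps must be unique and
#' uniformly spaced at the sampling interval, and onset (t = 0) must lie
#' strictly inside the record. Rows flagged `missing = 1` enter the
#' missing mask and their gaze values are ignored downstream. Metadata
#' is taken from the JSON sidecar when present; arguments override it.
#'
#' @param path CSV path.
#' @param covered_eye_side,fs_hz optional overrides; `fs_hz` defaults to
#'   the sidecar value or the median sampling interval.
#' @return a [gaze_trace()].
#' @export
read_trace_csv <- function(path, covered_eye_side = NULL, fs_hz = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  expected <- c("time_s", "fixating_deg", "covered_deg", "missing")
  if (!identical(names(raw), expected)) {
    stop("malformed header: expected columns ",
         paste(expected, collapse = ","), " but found ",
         paste(names(raw), collapse = ","), call. = FALSE)
  }
  parse_num <- function(col, allow_na = FALSE) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !(allow_na & raw[[col]] == "NA"))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric value '%s' in column %s at data row %d",
                   raw[[col]][bad[1L]], col, bad[1L]), call. = FALSE)
    }
    v
  }
  time_s <- parse_num("time_s")
  miss_raw <- parse_num("missing")
  if (!all(miss_raw %in% c(0, 1))) {
    stop("column `missing` must contain only 0 or 1", call. = FALSE)
  }
  missing <- miss_raw == 1
  fixating <- parse_num("fixating_deg", allow_na = TRUE)
  covered <- parse_num("covered_deg", allow_na = TRUE)
  bad_na <- which((is.na(fixating) | is.na(covered)) & !missing)
  if (length(bad_na) > 0L) {
    stop(sprintf("non-numeric gaze value at data row %d (row not flagged missing)",
                 bad_na[1L]), call. = FALSE)
  }
  dup <- which(duplicated(time_s))
  if (length(dup) > 0L) {
    stop(sprintf("duplicate timestamp %.6f s at data row %d",
                 time_s[dup[1L]], dup[1L]), call. = FALSE)
  }

  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  if (is.null(covered_eye_side)) {
    covered_eye_side <- if (!is.null(meta$covered_eye_side)) {
      meta$covered_eye_side
    } else {
      "right"
    }
  }
  if (is.null(fs_hz)) {
    fs_hz <- if (!is.null(meta$fs_hz)) meta$fs_hz else 1 / stats::median(diff(time_s))
  }
  gt <- meta$ground_truth
  if (!is.null(gt) && !is.null(gt$params)) gt$params <- as.list(gt$params)
  gaze_trace(time_s = time_s, fixating_deg = fixating, covered_deg = covered,
             covered_eye_side = covered_eye_side, fs_hz = fs_hz,
             missing = missing,
             subject_id = meta$subject_id, diagnosis = meta$diagnosis,
             apct_pd = meta$apct_pd, ground_truth = gt)
}

#' Write a per-subject metrics table to CSV
#'
#' Deterministic formatting (six decimals for numeric columns) so that
#' identical results give byte-identical files.
#'
#' @param tab data.frame from [metrics_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(tab, path) {
  stopifnot(is.data.frame(tab))
  fmt <- vapply(seq_len(ncol(tab)), function(j) {
    col <- tab[[j]]
    if (is.numeric(col)) sprintf("%.6f", col) else as.character(col)
  }, character(nrow(tab)))
  if (nrow(tab) == 1L) fmt <- matrix(fmt, nrow = 1L)
  lines <- c(paste(names(tab), collapse = ","),
             apply(fmt, 1L, paste, collapse = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read back a metrics table written by [write_metrics_csv()]
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_metrics_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
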