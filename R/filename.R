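#' Recording identity parsed from a field-recorder filename
#'
#' Field recordings follow the convention
#' `RECORDERNAME_YYYYMMDD_HHMMSS.wav`, optionally with a `_start_MM_SS`
#' suffix before the extension when a long recording has been split into
#' segments: the suffix gives the minutes/seconds into the recording at which
#' the segment starts. The effective clip start is
#' `start_datetime + offset_seconds`.
#'
#' @param recorder Recorder name: the token before the first underscore that
#'   is followed by the 8-digit date. Must be non-empty and contain no
#'   underscore.
#' @param start_datetime A `POSIXct` datetime (second resolution) in UTC or
#'   any fixed representation; only the calendar fields are used.
#' @param offset_seconds Non-negative integer offset in seconds (0 when no
#'   `_start_MM_SS` suffix); must be < 3600 so that `MM_SS` can encode it.
#' @return An object of class `"recording_identity"`.
#' @seealso [parse_filename()], [format_filename()]
#' @export
recording_identity <- function(recorder, start_datetime, offset_seconds = 0L) {
  if (!is.character(recorder) || length(recorder) != 1 ||
      !nzchar(recorder) || grepl("_", recorder, fixed = TRUE)) {
    stop("`recorder` must be a non-empty string without underscores",
         call. = FALSE)
  }
  if (!inherits(start_datetime, "POSIXct")) {
    stop("`start_datetime` must be a POSIXct datetime", call. = FALSE)
  }
  if (!is.numeric(offset_seconds) || length(offset_seconds) != 1 ||
      is.na(offset_seconds) || offset_seconds < 0 ||
      offset_seconds != as.integer(offset_seconds)) {
    stop("`offset_seconds` must be a non-negative integer", call. = FALSE)
  }
  structure(list(recorder = recorder,
                 start_datetime = start_datetime,
                 offset_seconds = as.integer(offset_seconds)),
            class = "recording_identity")
}

#' @export
print.recording_identity <- function(x, ...) {
  cat(sprintf("<recording> %s starting %s (+%d s)\n", x$recorder,
              format(x$start_datetime, "%Y-%m-%d %H:%M:%S"),
              x$offset_seconds))
  invisible(x)
}

#' Parse a recorder filename into a recording identity
#'
#' Matching is a soft operation: a filename that does not follow the
#' convention returns `NULL` with a warning rather than an error, since a
#' project folder may legitimately contain other files.
#'
#' @param name A file name (base name or full path; only the base name is
#'   examined).
#' @return A [recording_identity()], or `NULL` (with a warning) when the name
#'   does not match the convention or encodes an impossible datetime.
#' @export
#' @examples
#' parse_filename("RAHORA_20220415_063000.wav")
#' parse_filename("TEEVURCHER_20220501_220000_start_05_30.wav")$offset_seconds
parse_filename <- function(name) {
  base <- basename(name)
  pat <- "^([^_]+)_([0-9]{8})_([0-9]{6})(?:_start_([0-9]{2})_([0-9]{2}))?\\.[wW][aA][vV]$"
  m <- regmatches(base, regexec(pat, base))[[1]]
  if (length(m) == 0) {
    warning(sprintf("filename '%s' does not match RECORDERNAME_YYYYMMDD_HHMMSS[_start_MM_SS].wav",
                    base), call. = FALSE)
    return(NULL)
  }
  dt <- as.POSIXct(paste(m[3], m[4]), format = "%Y%m%d %H%M%S", tz = "UTC")
  if (is.na(dt)) {
    warning(sprintf("filename '%s' encodes an invalid date/time", base),
            call. = FALSE)
    return(NULL)
  }
  offset <- 0L
  if (nzchar(m[5])) {
    ss <- as.integer(m[6])
    if (ss >= 60) {
      warning(sprintf("filename '%s' has an invalid _start_ seconds field",
                      base), call. = FALSE)
      return(NULL)
    }
    offset <- as.integer(m[5]) * 60L + ss
  }
  recording_identity(m[2], dt, offset)
}

#' Format a recording identity as its canonical filename
#'
#' Inverse of [parse_filename()]: `parse_filename(format_filename(id))`
#' reproduces `id`. The `_start_MM_SS` suffix is omitted when
#' `offset_seconds == 0`.
#'
#' @param id A [recording_identity()].
#' @return The canonical `.wav` file name (no directory part).
#' @export
format_filename <- function(id) {
  stopifnot(inherits(id, "recording_identity"))
  if (id$offset_seconds < 0 || id$offset_seconds >= 3600) {
    stop("`offset_seconds` must be in [0, 3600) to be encodable as MM_SS",
         call. = FALSE)
  }
  stamp <- format(id$start_datetime, "%Y%m%d_%H%M%S", tz = "UTC")
  suffix <- if (id$offset_seconds > 0) {
    sprintf("_start_%02d_%02d", id$offset_seconds %/% 60L,
            id$offset_seconds %% 60L)
  } else ""
  sprintf("%s_%s%s.wav", id$recorder, stamp, suffix)
}
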