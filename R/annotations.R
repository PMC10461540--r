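# Label CSV schema: seven required columns, optional extras with defaults.
REQUIRED_LABEL_COLUMNS <- c("date_time", "file_name", "start_time",
                            "end_time", "start_freq", "end_freq",
                            "class_label")
OPTIONAL_LABEL_COLUMNS <- c(confidence = 100, labeller = "", call_type = "",
                            notes = "")
LABEL_COLUMN_ORDER <- c("date_time", "file_name", "start_time", "end_time",
                        "start_freq", "end_freq", "class_label",
                        "confidence", "labeller", "call_type", "notes")

#' An ordered set of bounding-box annotations
#'
#' Wraps a data frame with one row per saved label and a stable integer `id`
#' column assigned at load/creation time. Ids are unique and row order is
#' stable under edits, so a label keeps its identity across an editing
#' session.
#'
#' @param records A data frame with the label columns (see
#'   [load_annotations()] for the schema). May have zero rows.
#' @return An object of class `"annotation_set"`.
#' @export
annotation_set <- function(records = NULL) {
  if (is.null(records)) {
    records <- as.data.frame(
      c(list(id = integer()),
        stats::setNames(
          lapply(LABEL_COLUMN_ORDER, function(cl) {
            if (cl %in% c("start_time", "end_time", "start_freq",
                          "end_freq")) numeric()
            else if (cl == "confidence") integer()
            else character()
          }), LABEL_COLUMN_ORDER)),
      stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(records))
  if (!"id" %in% names(records)) {
    records <- cbind(id = seq_len(nrow(records)), records)
  }
  if (anyDuplicated(records$id)) {
    stop("annotation ids must be unique", call. = FALSE)
  }
  rownames(records) <- NULL
  structure(list(records = records), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation set> %d label(s)", nrow(x$records)))
  if (nrow(x$records) > 0) {
    cat(sprintf(" across %d file(s), classes: %s",
                length(unique(x$records$file_name)),
                paste(sort(unique(x$records$class_label)), collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.annotation_set <- function(x) nrow(x$records)

# ISO 8601 with numeric zone offset, e.g. 2022-04-15T06:30:00+0100
iso8601_now <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")

validate_annotation_row <- function(row, where = "annotation") {
  num <- vapply(row[c("start_time", "end_time", "start_freq", "end_freq")],
                as.numeric, numeric(1))
  if (anyNA(num) || any(!is.finite(num)) || any(num < 0)) {
    stop(sprintf("%s: box coordinates must be finite and >= 0", where),
         call. = FALSE)
  }
  if (num[["start_time"]] >= num[["end_time"]]) {
    stop(sprintf("%s: start_time must be < end_time", where), call. = FALSE)
  }
  if (num[["start_freq"]] >= num[["end_freq"]]) {
    stop(sprintf("%s: start_freq must be < end_freq", where), call. = FALSE)
  }
  conf <- row[["confidence"]]
  if (is.na(conf) || conf < 0 || conf > 100 || conf != as.integer(conf)) {
    stop(sprintf("%s: confidence must be an integer in [0, 100]", where),
         call. = FALSE)
  }
  if (!nzchar(row[["class_label"]])) {
    stop(sprintf("%s: class_label must be non-empty", where), call. = FALSE)
  }
  invisible(TRUE)
}

#' Create a single validated annotation
#'
#' Stamps the creation time (`date_time`, ISO 8601 with the local zone
#' offset) and checks that the box lies within the clip's time extent and
#' below the Nyquist frequency.
#'
#' @param box A [bounding_box()] (seconds x kHz, clip-relative).
#' @param class_label Non-empty class name (e.g. a species).
#' @param file_name Audio file the label refers to.
#' @param confidence Integer percent 0-100 (default 100).
#' @param labeller Name of the annotator (may be empty).
#' @param call_type,notes Optional free-text fields.
#' @param clip_duration Clip length in seconds; the box must fit inside.
#' @param nyquist Nyquist frequency in kHz; the box must stay below it.
#' @return A one-row data frame in the label schema (no id).
#' @export
create_annotation <- function(box, class_label, file_name,
                              confidence = 100, labeller = "",
                              call_type = "", notes = "",
                              clip_duration, nyquist) {
  stopifnot(inherits(box, "bounding_box"))
  if (box$t_end > clip_duration + 1e-9) {
    stop(sprintf("box ends at %.3f s but the clip is only %.3f s long",
                 box$t_end, clip_duration), call. = FALSE)
  }
  if (box$f_end > nyquist + 1e-9) {
    stop(sprintf("box ends at %.3f kHz but the Nyquist frequency is %.3f kHz",
                 box$f_end, nyquist), call. = FALSE)
  }
  row <- data.frame(
    date_time = iso8601_now(), file_name = as.character(file_name),
    start_time = box$t_start, end_time = box$t_end,
    start_freq = box$f_start, end_freq = box$f_end,
    class_label = as.character(class_label),
    confidence = suppressWarnings(as.integer(confidence)),
    labeller = as.character(labeller),
    call_type = as.character(call_type), notes = as.character(notes),
    stringsAsFactors = FALSE)
  if (is.na(row$confidence)) {
    stop("confidence must be an integer in [0, 100]", call. = FALSE)
  }
  validate_annotation_row(row)
  row
}

#' Append an annotation to a set
#'
#' @param set An [annotation_set()].
#' @param row A one-row data frame from [create_annotation()].
#' @return The set with the new record appended under a fresh id.
#' @export
add_annotation <- function(set, row) {
  stopifnot(inherits(set, "annotation_set"))
  new_id <- if (nrow(set$records) == 0) 1L else max(set$records$id) + 1L
  row <- cbind(id = new_id, row[LABEL_COLUMN_ORDER])
  set$records <- rbind(set$records, row)
  rownames(set$records) <- NULL
  set
}

#' Save annotations to the project labels folder
#'
#' Writes `labels/labels_<username>.csv` under `project_dir` when `username`
#' is non-empty, else the shared fallback `labels/labels_tmp.csv`. The file
#' always carries a header row and re-reading with [load_annotations()]
#' yields an equal set. Output is UTF-8 without a byte-order mark.
#'
#' @param set An [annotation_set()].
#' @param project_dir Project root; a `labels/` folder is created inside if
#'   absent.
#' @param username Annotator name used in the file name ("" for the
#'   `labels_tmp.csv` fallback).
#' @return The path written, invisibly.
#' @export
save_annotations <- function(set, project_dir, username = "") {
  stopifnot(inherits(set, "annotation_set"))
  labels_dir <- file.path(project_dir, "labels")
  dir.create(labels_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(labels_dir)) {
    stop(sprintf("cannot create labels directory '%s'", labels_dir),
         call. = FALSE)
  }
  fname <- if (nzchar(username)) sprintf("labels_%s.csv", username)
           else "labels_tmp.csv"
  path <- file.path(labels_dir, fname)
  out <- set$records[LABEL_COLUMN_ORDER]
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' Load annotations from a label CSV
#'
#' Accepts files with at least the seven required columns (`date_time`,
#' `file_name`, `start_time`, `end_time`, `start_freq`, `end_freq`,
#' `class_label`). Missing optional columns are defaulted (`confidence`
#' 100, empty `labeller`/`call_type`/`notes`). A UTF-8 byte-order mark is
#' tolerated and stripped, so files exported by spreadsheet software load
#' identically to plain UTF-8.
#'
#' @param path Path to a label CSV.
#' @return An [annotation_set()] with ids 1..n in file order.
#' @export
load_annotations <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("label file not found: '%s'", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8-BOM", check.names = FALSE,
                        colClasses = "character")
  missing <- setdiff(REQUIRED_LABEL_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop(sprintf("label file '%s' is missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (cl in names(OPTIONAL_LABEL_COLUMNS)) {
    if (!cl %in% names(df)) df[[cl]] <- OPTIONAL_LABEL_COLUMNS[[cl]]
  }
  for (cl in c("start_time", "end_time", "start_freq", "end_freq")) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & nzchar(trimws(df[[cl]])))
    bad <- union(bad, which(!nzchar(trimws(df[[cl]]))))
    if (length(bad) > 0) {
      stop(sprintf("label file '%s': column %s has unparsable value in row %d",
                   path, cl, bad[1]), call. = FALSE)
    }
    df[[cl]] <- v
  }
  conf <- suppressWarnings(as.integer(df$confidence))
  conf[!nzchar(trimws(as.character(df$confidence)))] <- 100L
  if (anyNA(conf)) {
    stop(sprintf("label file '%s': column confidence has unparsable value in row %d",
                 path, which(is.na(conf))[1]), call. = FALSE)
  }
  df$confidence <- conf
  for (cl in c("labeller", "call_type", "notes")) {
    df[[cl]][is.na(df[[cl]])] <- ""
  }
  df <- df[LABEL_COLUMN_ORDER]
  annotation_set(df)
}

EDITABLE_LABEL_FIELDS <- c("start_time", "end_time", "start_freq",
                           "end_freq", "class_label", "confidence",
                           "call_type", "notes")

#' Edit one annotation in place
#'
#' Applies `field_updates` to the record with the given id and revalidates
#' it. Only the box limits, `class_label`, `confidence`, `call_type` and
#' `notes` are editable; `date_time` and `file_name` are immutable
#' provenance. The edit is atomic: on any validation failure an error is
#' raised and the set is unchanged.
#'
#' @param set An [annotation_set()].
#' @param id Stable integer id of the record to edit.
#' @param field_updates Named list of new values for editable fields.
#' @return The updated set.
#' @export
edit_annotation <- function(set, id, field_updates) {
  stopifnot(inherits(set, "annotation_set"))
  i <- match(id, set$records$id)
  if (is.na(i)) {
    stop(sprintf("no annotation with id %s", id), call. = FALSE)
  }
  bad <- setdiff(names(field_updates), EDITABLE_LABEL_FIELDS)
  if (length(bad) > 0) {
    stop(sprintf("field(s) not editable: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  row <- set$records[i, ]
  for (f in names(field_updates)) {
    row[[f]] <- if (f == "confidence") {
      suppressWarnings(as.integer(field_updates[[f]]))
    } else if (f %in% c("start_time", "end_time", "start_freq", "end_freq")) {
      as.numeric(field_updates[[f]])
    } else as.character(field_updates[[f]])
  }
  validate_annotation_row(row, where = sprintf("annotation id %s", id))
  set$records[i, ] <- row
  set
}

#' Delete one annotation by id
#'
#' @param set An [annotation_set()].
#' @param id Stable integer id of the record to delete.
#' @return The set with the record removed; other records and their ids are
#'   untouched.
#' @export
delete_annotation <- function(set, id) {
  stopifnot(inherits(set, "annotation_set"))
  i <- match(id, set$records$id)
  if (is.na(i)) {
    stop(sprintf("no annotation with id %s", id), call. = FALSE)
  }
  set$records <- set$records[-i, ]
  rownames(set$records) <- NULL
  set
}

#' Filter annotations by multiple fields
#'
#' Supplied criteria are combined by conjunction; an empty criteria list
#' returns the full set. `min_confidence` is boundary-inclusive.
#' `time_window = c(t0, t1)` keeps labels whose `[start_time, end_time]`
#' interval overlaps the window.
#'
#' @param set An [annotation_set()].
#' @param file_name,class_label,labeller Exact-match filters (character).
#' @param min_confidence Keep labels with `confidence >= min_confidence`.
#' @param time_window Numeric `c(t0, t1)` in seconds.
#' @return A filtered [annotation_set()] (ids preserved).
#' @export
filter_annotations <- function(set, file_name = NULL, class_label = NULL,
                               labeller = NULL, min_confidence = NULL,
                               time_window = NULL) {
  stopifnot(inherits(set, "annotation_set"))
  keep <- rep(TRUE, nrow(set$records))
  r <- set$records
  if (!is.null(file_name)) keep <- keep & r$file_name %in% file_name
  if (!is.null(class_label)) keep <- keep & r$class_label %in% class_label
  if (!is.null(labeller)) keep <- keep & r$labeller %in% labeller
  if (!is.null(min_confidence)) keep <- keep & r$confidence >= min_confidence
  if (!is.null(time_window)) {
    stopifnot(is.numeric(time_window), length(time_window) == 2)
    keep <- keep & r$start_time <= time_window[2] &
      r$end_time >= time_window[1]
  }
  set$records <- r[keep, ]
  rownames(set$records) <- NULL
  set
}

#' Summarize label counts per workflow file
#'
#' One row per workflow file - including files with zero labels - with the
#' total label count and one count column per class present in the set. Row
#' totals always equal the sum of the class columns.
#'
#' @param set An [annotation_set()].
#' @param workflow_files Character vector of audio file names in the
#'   project (order preserved in the output).
#' @return A data frame with columns `file_name`, `n_labels`, then one
#'   column per class (alphabetical).
#' @export
summarize_annotations <- function(set, workflow_files) {
  stopifnot(inherits(set, "annotation_set"))
  classes <- sort(unique(set$records$class_label))
  out <- data.frame(file_name = as.character(workflow_files),
                    n_labels = 0L, stringsAsFactors = FALSE)
  for (cl in classes) out[[cl]] <- 0L
  if (nrow(set$records) > 0) {
    tab <- table(factor(set$records$file_name, levels = workflow_files),
                 set$records$class_label)
    for (cl in classes) out[[cl]] <- as.integer(tab[, cl])
    out$n_labels <- as.integer(rowSums(tab))
  }
  out
}
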