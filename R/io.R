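# File formats and the offline telemetry message schema.
#
# Beat CSV dialect: headerless comma-separated rows, one beat per row,
# n_value_columns amplitude values followed by an integer class label 0-4.
# The public heartbeat CSV uses 187 value columns; the classifier input is
# 186, and the documented bridge rule drops the final value column.

#' Beat CSV dialect description
#'
#' @param n_value_columns Number of amplitude columns per row (186 native,
#'   187 for the public heartbeat CSV).
#' @return An object of class `beat_csv_dialect` (delimiter comma, label in
#'   the last column, no header).
#' @export
beat_csv_dialect <- function(n_value_columns = 186L) {
  check_count(n_value_columns, "n_value_columns", lower = 32L)
  structure(list(n_value_columns = as.integer(n_value_columns),
                 delimiter = ",", header = FALSE, label_column = "last"),
            class = "beat_csv_dialect")
}

#' Write a beat dataset as headerless CSV
#'
#' @param dataset A `beat_dataset`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_beat_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "beat_dataset"))
  dt <- data.table::as.data.table(cbind(dataset$beats, dataset$labels))
  data.table::fwrite(dt, path, col.names = FALSE)
  invisible(path)
}

#' Read a beat dataset from CSV
#'
#' Malformed rows (wrong arity handled by the reader; labels that are not
#' integers in 0..4) are collected into an error report attached as
#' attribute `"error_report"` (data.frame of `row`, `reason`) and excluded
#' from the returned dataset with a warning — never silently skipped. When
#' the dialect carries 187 value columns and `model_length` is 186, the
#' final value column is dropped, with a loud message.
#'
#' @param path CSV file.
#' @param dialect A [beat_csv_dialect()].
#' @param model_length Beat length expected by the classifier (default 186).
#' @param fs Nominal sampling rate to attach (Hz).
#' @return A `beat_dataset`; check `attr(x, "error_report")`.
#' @export
read_beat_csv <- function(path, dialect = beat_csv_dialect(),
                          model_length = 186L, fs = 125) {
  if (!file.exists(path)) abort_invalid(sprintf("file not found: %s", path))
  dt <- data.table::fread(path, header = FALSE, sep = dialect$delimiter)
  want <- dialect$n_value_columns + 1L
  if (ncol(dt) != want) {
    abort_invalid(sprintf(
      "%s: expected %d columns (%d values + label) but found %d; check the dialect",
      path, want, dialect$n_value_columns, ncol(dt)),
      class = "ecgtriage_format_error")
  }
  values <- as.matrix(dt[, seq_len(dialect$n_value_columns), with = FALSE])
  labels_raw <- dt[[want]]
  bad <- which(!is.finite(labels_raw) | labels_raw != floor(labels_raw) |
                 labels_raw < 0 | labels_raw > 4)
  errors <- data.frame(row = integer(), reason = character())
  if (length(bad)) {
    errors <- data.frame(
      row = bad,
      reason = sprintf("label %s not an integer in 0..4",
                       format(labels_raw[bad])))
    warning(sprintf("%d malformed row(s) in %s excluded; see attr(, 'error_report')",
                    length(bad), path))
    values <- values[-bad, , drop = FALSE]
    labels_raw <- labels_raw[-bad]
  }
  if (dialect$n_value_columns == 187L && model_length == 186L) {
    message("dialect has 187 value columns; dropping the final value column to match the 186-sample model input")
    values <- values[, seq_len(186L), drop = FALSE]
  }
  ds <- structure(
    list(beats = values, labels = as.integer(labels_raw), fs = fs,
         split = rep(NA_character_, length(labels_raw)),
         class_names = beat_class_names()),
    class = "beat_dataset"
  )
  attr(ds, "error_report") <- errors
  ds
}

#' Write a vitals stream as JSON lines
#'
#' @param stream Vitals data.frame (see [generate_vitals_stream()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_vitals_jsonl <- function(stream, path) {
  lines <- vapply(seq_len(nrow(stream)), function(i) {
    jsonlite::toJSON(as.list(stream[i, , drop = FALSE]), auto_unbox = TRUE,
                     digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a JSON-lines vitals stream
#'
#' @param path File written by [write_vitals_jsonl()].
#' @return Vitals data.frame.
#' @export
read_vitals_jsonl <- function(path) {
  if (!file.exists(path)) abort_invalid(sprintf("file not found: %s", path))
  rows <- lapply(readLines(path), function(l) {
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# schema checks shared by parse_telemetry_message
.require_field <- function(obj, name, jpath, numeric = TRUE) {
  if (is.null(obj[[name]])) {
    abort_invalid(sprintf("telemetry schema violation at %s.%s: missing field",
                          jpath, name),
                  class = "ecgtriage_schema_error")
  }
  if (numeric && !is.numeric(obj[[name]])) {
    abort_invalid(sprintf("telemetry schema violation at %s.%s: not numeric",
                          jpath, name),
                  class = "ecgtriage_schema_error")
  }
  obj[[name]]
}

#' Parse an offline telemetry message
#'
#' Messages follow the published topic/payload convention of the monitoring
#' pipeline: topic `vitals/<patient_id>/<signal>` with exactly three
#' segments, signal one of `ecg` or `vitals`; the JSON payload carries
#' `schema_version`, `timestamp`, and either an ECG chunk
#' (`ecg_chunk.samples` + `ecg_chunk.fs`) or a vitals reading
#' (`vitals.temp_f`, `vitals.hr_bpm`, `vitals.spo2_pct`, plus
#' `age.years`/`age.months`). Transport (the actual MQTT broker) is out of
#' scope; this validates and types stored messages.
#'
#' @param topic Topic string.
#' @param payload_text JSON payload text.
#' @return For `ecg` topics a [raw_ecg()]; for `vitals` topics a one-row
#'   vitals data.frame. Both carry attributes `patient_id` and `timestamp`.
#' @export
parse_telemetry_message <- function(topic, payload_text) {
  seg <- strsplit(topic, "/", fixed = TRUE)[[1]]
  if (length(seg) != 3L || seg[1] != "vitals" || any(!nzchar(seg))) {
    abort_invalid(sprintf(
      "topic '%s' must have the form vitals/<patient_id>/<signal>", topic),
      class = "ecgtriage_topic_error")
  }
  signal_kind <- seg[3]
  if (!signal_kind %in% c("ecg", "vitals")) {
    abort_invalid(sprintf("unknown signal segment '%s' (want ecg|vitals)",
                          signal_kind),
                  class = "ecgtriage_topic_error")
  }
  payload <- tryCatch(jsonlite::fromJSON(payload_text),
                      error = function(e) {
                        abort_invalid(sprintf("payload is not valid JSON: %s",
                                              conditionMessage(e)),
                                      class = "ecgtriage_schema_error")
                      })
  .require_field(payload, "schema_version", "$", numeric = FALSE)
  ts <- .require_field(payload, "timestamp", "$")
  if (signal_kind == "ecg") {
    chunk <- .require_field(payload, "ecg_chunk", "$", numeric = FALSE)
    samples <- .require_field(chunk, "samples", "$.ecg_chunk")
    fs <- .require_field(chunk, "fs", "$.ecg_chunk")
    out <- raw_ecg(samples, fs)
  } else {
    v <- .require_field(payload, "vitals", "$", numeric = FALSE)
    age <- payload$age %||% list(years = 0, months = 0)
    out <- data.frame(
      timestamp = ts,
      temp_f = .require_field(v, "temp_f", "$.vitals"),
      hr_bpm = .require_field(v, "hr_bpm", "$.vitals"),
      spo2_pct = .require_field(v, "spo2_pct", "$.vitals"),
      age_years = as.integer(age$years %||% 0),
      age_months = as.integer(age$months %||% 0)
    )
  }
  attr(out, "patient_id") <- seg[2]
  attr(out, "timestamp") <- ts
  out
}

#' Write an evaluation or triage report as JSON
#'
#' Serializes with stable key order and attaches provenance: the package
#' version and a hash of the report content. [read_report()] restores the
#' report so that a write/read round trip is exact.
#'
#' @param report An `evaluation_report` or `triage_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  kind <- if (inherits(report, "evaluation_report")) {
    "evaluation"
  } else if (inherits(report, "triage_report")) {
    "triage"
  } else {
    abort_invalid("`report` must be an evaluation_report or triage_report")
  }
  body <- unclass(report)
  if (kind == "evaluation") body$confusion <- unname(body$confusion)
  obj <- list(report_kind = kind,
              package_version = as.character(utils::packageVersion("ecgtriage")),
              content_hash = rlang::hash(body),
              body = body)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a report written by [write_report()]
#'
#' @param path JSON report file.
#' @return The restored `evaluation_report` or `triage_report`.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) abort_invalid(sprintf("file not found: %s", path))
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  body <- obj$body
  if (obj$report_kind == "evaluation") {
    structure(
      list(accuracy = body$accuracy,
           per_class = as.data.frame(body$per_class),
           macro = unlist(body$macro),
           weighted = unlist(body$weighted),
           total = as.integer(body$total),
           confusion = {
             cm <- as.matrix(body$confusion)
             storage.mode(cm) <- "integer"
             dimnames(cm) <- list(true = as.character(seq_len(nrow(cm)) - 1L),
                                  pred = as.character(seq_len(nrow(cm)) - 1L))
             cm
           }),
      class = "evaluation_report")
  } else {
    structure(
      list(flags = if (is.null(body$flags)) NULL else as.data.frame(body$flags),
           beat_class_histogram = as.integer(body$beat_class_histogram),
           abnormal_beat_fraction = body$abnormal_beat_fraction,
           alarm = body$alarm,
           reasons = as.character(unlist(body$reasons))),
      class = "triage_report")
  }
}
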