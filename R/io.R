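#' Read a cohort of patient records
#'
#' Reads a cohort from disk in either of two layouts:
#'
#' * **csv** — a records table plus a companion events table at
#'   `<records-stem>_events.csv`. Empty cells decode to *unknown*; the
#'   literal token `"NA!"` decodes to *not applicable*, keeping the two
#'   kinds of missingness distinct on disk.
#' * **json** — one object per record with a nested `events` array and
#'   explicit `{state, value}` encoding for every three-valued field.
#'
#' Records whose cells cannot be parsed (malformed dates, unknown event
#' types, invalid vital status) are skipped and counted in the load report
#' attached to the result (`attr(x, "load_report")`: rows read, rows
#' rejected, per-row notes). A missing `record_id` aborts the load.
#'
#' The relapse-date field and relapse events describe one clinical fact, so
#' the loader synchronises them: a present relapse date with no relapse
#' event materialises the event, and a relapse event with an unknown
#' relapse date fills the field from the earliest relapse event. Both
#' repairs are noted in the load report.
#'
#' @param path path to the records file.
#' @param format `"csv"` or `"json"`.
#' @return A list of [patient_record()] objects with a `load_report`
#'   attribute.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  rows <- if (format == "csv") cohort_rows_csv(path) else cohort_rows_json(path)
  records <- list()
  notes <- character()
  rejected <- 0L
  for (i in seq_along(rows)) {
    row <- rows[[i]]
    rid <- row$record_id
    if (is.null(rid) || is.na(rid) || !nzchar(rid)) {
      stop("record without record_id at position ", i, call. = FALSE)
    }
    rec <- tryCatch(row_to_record(row), error = function(e) {
      notes[[length(notes) + 1L]] <<- paste0("rejected ", rid, ": ", conditionMessage(e))
      rejected <<- rejected + 1L
      NULL
    })
    if (is.null(rec)) next
    sync <- sync_relapse(rec)
    if (nzchar(sync$note)) notes[[length(notes) + 1L]] <- sync$note
    records[[length(records) + 1L]] <- sync$record
  }
  ids <- vapply(records, function(r) r$record_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate record_id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  attr(records, "load_report") <- list(
    rows_read = length(rows), rows_rejected = rejected, notes = notes
  )
  records
}

events_companion_path <- function(path) {
  sub("\\.csv$", "_events.csv", path)
}

cohort_rows_csv <- function(path) {
  rec <- read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = NULL)
  epath <- events_companion_path(path)
  ev <- if (file.exists(epath)) {
    read.csv(epath, colClasses = "character", check.names = FALSE,
             na.strings = NULL)
  } else {
    data.frame(record_id = character(), event_type = character(),
               date = character(), procedure_code = character(),
               planned_duration_days = character(), source_form = character())
  }
  lapply(seq_len(nrow(rec)), function(i) {
    row <- as.list(rec[i, , drop = FALSE])
    erows <- ev[ev$record_id == row$record_id, , drop = FALSE]
    row$events <- lapply(seq_len(nrow(erows)), function(j) as.list(erows[j, , drop = FALSE]))
    row
  })
}

cohort_rows_json <- function(path) {
  objs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(objs, function(o) {
    flat <- list(record_id = o$record_id,
                 vital_status = o$vital_status,
                 remission_documented = as.character(isTRUE(o$remission_documented)),
                 is_new = as.character(isTRUE(o$is_new)))
    for (f in RECORD_FV_FIELDS) {
      st <- o[[f]]$state
      flat[[f]] <- if (identical(st, "present")) as.character(o[[f]]$value)
                   else if (identical(st, "not_applicable")) NA_SENTINEL
                   else ""
    }
    flat$events <- lapply(o$events, function(e) {
      list(event_type = e$event_type, date = e$date,
           procedure_code = if (is.null(e$procedure_code)) "" else as.character(e$procedure_code),
           planned_duration_days = if (is.null(e$planned_duration_days)) "" else as.character(e$planned_duration_days),
           source_form = if (is.null(e$source_form)) "" else as.character(e$source_form))
    })
    flat
  })
}

row_to_record <- function(row) {
  fvs <- list()
  for (f in RECORD_FV_FIELDS) {
    type <- if (f %in% RECORD_DATE_FIELDS) "date" else "text"
    fvs[[f]] <- fv_decode(row[[f]], type)
  }
  evs <- empty_events()
  for (e in row$events) {
    code <- e$procedure_code
    plan <- suppressWarnings(as.numeric(e$planned_duration_days))
    evs <- dplyr::bind_rows(evs, clinical_event(
      event_type = e$event_type, date = e$date,
      procedure_code = if (is.null(code) || !nzchar(code)) NA_character_ else code,
      planned_duration_days = if (length(plan) == 0L || is.na(plan)) NA_real_ else plan,
      source_form = if (is.null(e$source_form) || !nzchar(e$source_form)) NA_character_ else e$source_form
    ))
  }
  patient_record(
    record_id = row$record_id,
    gender = fvs$gender, dob = fvs$dob, cancer_site = fvs$cancer_site,
    diagnosis_date = fvs$diagnosis_date, tumor_grade = fvs$tumor_grade,
    t_stage = fvs$t_stage,
    vital_status = row$vital_status,
    relapse_date = fvs$relapse_date,
    remission_documented = parse_flag(row$remission_documented, "remission_documented"),
    events = evs,
    is_new = parse_flag(row$is_new, "is_new")
  )
}

parse_flag <- function(x, what) {
  v <- toupper(trimws(as.character(x)))
  if (v %in% c("TRUE", "1")) return(TRUE)
  if (v %in% c("FALSE", "0", "")) return(FALSE)
  stop("invalid logical for ", what, ": '", x, "'", call. = FALSE)
}

# Keep the relapse_date field and relapse events describing the same fact.
sync_relapse <- function(record) {
  note <- ""
  has_event <- any(record$events$event_type == "relapse")
  if (fv_is_present(record$relapse_date) && !has_event) {
    record$events <- dplyr::bind_rows(
      record$events,
      clinical_event("relapse", fv_value(record$relapse_date), source_form = "sync")
    )
    note <- paste0(record$record_id, ": relapse event materialized from relapse_date")
  } else if (!fv_is_present(record$relapse_date) && has_event &&
             fv_state(record$relapse_date) == "unknown") {
    d <- min(record$events$date[record$events$event_type == "relapse"])
    record$relapse_date <- fv_present(d)
    note <- paste0(record$record_id, ": relapse_date filled from earliest relapse event")
  }
  list(record = record, note = note)
}

#' Write a cohort of patient records
#'
#' Inverse of [read_cohort()]: encodes all fields losslessly, including the
#' three missingness states (empty cell = unknown, `"NA!"` = not
#' applicable). The csv layout writes the records table to `path` and the
#' events to `<stem>_events.csv`.
#'
#' @param records list of [patient_record()] objects.
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @return The number of records written (invisibly).
#' @export
write_cohort <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") write_cohort_csv(records, path) else write_cohort_json(records, path)
  invisible(length(records))
}

write_cohort_csv <- function(records, path) {
  rec_df <- do.call(rbind, c(list(
    data.frame(record_id = character(), gender = character(), dob = character(),
               cancer_site = character(), diagnosis_date = character(),
               tumor_grade = character(), t_stage = character(),
               vital_status = character(), relapse_date = character(),
               remission_documented = character(), is_new = character(),
               stringsAsFactors = FALSE)),
    lapply(records, function(r) {
      data.frame(
        record_id = r$record_id,
        gender = fv_encode(r$gender), dob = fv_encode(r$dob),
        cancer_site = fv_encode(r$cancer_site),
        diagnosis_date = fv_encode(r$diagnosis_date),
        tumor_grade = fv_encode(r$tumor_grade), t_stage = fv_encode(r$t_stage),
        vital_status = r$vital_status,
        relapse_date = fv_encode(r$relapse_date),
        remission_documented = as.character(r$remission_documented),
        is_new = as.character(r$is_new),
        stringsAsFactors = FALSE
      )
    })))
  ev_df <- do.call(rbind, c(list(
    data.frame(record_id = character(), event_type = character(), date = character(),
               procedure_code = character(), planned_duration_days = character(),
               source_form = character(), stringsAsFactors = FALSE)),
    lapply(records, function(r) {
      ev <- r$events
      if (!nrow(ev)) return(NULL)
      data.frame(
        record_id = r$record_id, event_type = ev$event_type,
        date = format(ev$date, "%Y-%m-%d"),
        procedure_code = ifelse(is.na(ev$procedure_code), "", ev$procedure_code),
        planned_duration_days = ifelse(is.na(ev$planned_duration_days), "",
                                       format(ev$planned_duration_days, trim = TRUE, scientific = FALSE)),
        source_form = ifelse(is.na(ev$source_form), "", ev$source_form),
        stringsAsFactors = FALSE
      )
    })))
  write.csv(rec_df, path, row.names = FALSE, quote = TRUE, na = "")
  write.csv(ev_df, events_companion_path(path), row.names = FALSE, quote = TRUE, na = "")
}

record_to_json_obj <- function(r) {
  o <- list(record_id = r$record_id)
  for (f in RECORD_FV_FIELDS) {
    fv <- r[[f]]
    o[[f]] <- if (fv_is_present(fv)) list(state = "present", value = fv_canonical(fv))
              else list(state = fv_state(fv))
  }
  o$vital_status <- r$vital_status
  o$remission_documented <- r$remission_documented
  o$is_new <- r$is_new
  ev <- r$events
  o$events <- lapply(seq_len(nrow(ev)), function(j) {
    e <- list(event_type = ev$event_type[j], date = format(ev$date[j], "%Y-%m-%d"))
    if (!is.na(ev$procedure_code[j])) e$procedure_code <- ev$procedure_code[j]
    if (!is.na(ev$planned_duration_days[j])) e$planned_duration_days <- ev$planned_duration_days[j]
    if (!is.na(ev$source_form[j])) e$source_form <- ev$source_form[j]
    e
  })
  o
}

write_cohort_json <- function(records, path) {
  jsonlite::write_json(lapply(records, record_to_json_obj), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Read and write access/edit traces
#'
#' Traces record every summary-page access (`kind = "summary_access"`) and
#' every field edit (`kind = "field_edit"`, with field name and before and
#' after values using the cohort missingness encoding: empty = unknown,
#' `"NA!"` = not applicable). Timestamps are ISO-8601 date-times stored in
#' UTC.
#'
#' @param path traces CSV path.
#' @return A tibble with columns `kind`, `record_id`, `user_id`,
#'   `timestamp` (`POSIXct`, UTC), `field`, `before`, `after`.
#' @export
read_traces <- function(path) {
  df <- read.csv(path, colClasses = "character", na.strings = NULL)
  need <- c("kind", "record_id", "user_id", "timestamp", "field", "before", "after")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("traces file missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(df$kind), c("summary_access", "field_edit"))
  if (length(bad)) stop("unknown trace kind(s): ", paste(bad, collapse = ", "), call. = FALSE)
  ts <- as.POSIXct(df$timestamp, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  if (anyNA(ts)) stop("unparseable trace timestamp(s)", call. = FALSE)
  tibble(kind = df$kind, record_id = df$record_id, user_id = df$user_id,
         timestamp = ts, field = df$field, before = df$before, after = df$after)
}

#' @rdname read_traces
#' @param traces a traces tibble (as returned by [generate_cohort()] or
#'   [read_traces()]).
#' @export
write_traces <- function(traces, path) {
  df <- data.frame(
    kind = traces$kind, record_id = traces$record_id, user_id = traces$user_id,
    timestamp = format(traces$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    field = traces$field, before = traces$before, after = traces$after,
    stringsAsFactors = FALSE
  )
  write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(nrow(df))
}

empty_traces <- function() {
  tibble(kind = character(), record_id = character(), user_id = character(),
         timestamp = as.POSIXct(character(), tz = "UTC"),
         field = character(), before = character(), after = character())
}
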