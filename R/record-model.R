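#' @importFrom tibble tibble as_tibble
#' @importFrom stats rbinom rlnorm runif setNames
#' @importFrom utils read.csv write.csv head modifyList
NULL

# Recognised clinical event types and the fixed same-day ordering used to
# break date ties when building timelines (earlier rank sorts first).
EVENT_TYPES <- c(
  "surgery", "xrt_start", "xrt_end", "chemo_start", "chemo_end",
  "relapse", "remission", "follow_up", "death"
)

EVENT_TIE_PRIORITY <- c(
  diagnosis = 1, surgery = 2, xrt_start = 3, chemo_start = 4, relapse = 5,
  remission = 6, xrt_end = 7, chemo_end = 8, follow_up = 9, death = 10
)

VITAL_STATUSES <- c("alive", "died_from_disease", "died_other_cause", "unknown")

# Low-overhead tibble construction for hot paths (columns already validated
# equal-length vectors).
new_tbl <- function(lst) {
  n <- if (length(lst)) length(lst[[1L]]) else 0L
  structure(lst, class = c("tbl_df", "tbl", "data.frame"),
            row.names = c(NA_integer_, -n))
}

#' Construct a clinical event
#'
#' A dated treatment or outcome event attached to a patient record.
#' Surgery events must carry a `procedure_code`; radiation-start events may
#' carry a `planned_duration_days` attribute used by the abrupt-discontinuation
#' rule.
#'
#' @param event_type one of `surgery`, `xrt_start`, `xrt_end`, `chemo_start`,
#'   `chemo_end`, `relapse`, `remission`, `follow_up`, `death`.
#' @param date event date (`Date` or ISO-8601 string).
#' @param procedure_code surgical procedure code (surgery events only).
#' @param planned_duration_days planned course length in days
#'   (`xrt_start` events).
#' @param source_form identifier of the data-entry form the event came from.
#' @return A one-row tibble with the events schema.
#' @export
clinical_event <- function(event_type, date, procedure_code = NA_character_,
                           planned_duration_days = NA_real_,
                           source_form = NA_character_) {
  if (!event_type %in% EVENT_TYPES) {
    stop("unknown event_type '", event_type, "'", call. = FALSE)
  }
  if (is.character(date)) date <- parse_iso_date(date)
  stopifnot(inherits(date, "Date"), !is.na(date))
  if (event_type == "surgery" && (is.na(procedure_code) || !nzchar(procedure_code))) {
    stop("a surgery event requires a procedure_code", call. = FALSE)
  }
  new_tbl(list(
    event_type = event_type, date = date,
    procedure_code = as.character(procedure_code),
    planned_duration_days = as.numeric(planned_duration_days),
    source_form = as.character(source_form)
  ))
}

#' @rdname clinical_event
#' @export
empty_events <- function() {
  tibble(
    event_type = character(), date = as.Date(character()),
    procedure_code = character(), planned_duration_days = numeric(),
    source_form = character()
  )
}

#' Construct a patient record
#'
#' One research-database record: identifiers, demographics, diagnosis,
#' outcome status and the list of dated clinical events. Demographic and
#' date fields are [field_value] objects so that *unknown* and
#' *not applicable* stay distinct from recorded values.
#'
#' @param record_id unique record identifier (non-empty string).
#' @param gender,dob,cancer_site,diagnosis_date,tumor_grade,t_stage,relapse_date
#'   [field_value] objects (dates for `dob`, `diagnosis_date`,
#'   `relapse_date`).
#' @param vital_status one of `alive`, `died_from_disease`,
#'   `died_other_cause`, `unknown`.
#' @param remission_documented logical: is a remission documented anywhere
#'   in the record?
#' @param events tibble of clinical events (see [clinical_event()]).
#' @param is_new logical: newly entered record (vs an update of an existing
#'   one). Supplied by the data-entry context, never inferred.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(record_id,
                           gender = fv_unknown(), dob = fv_unknown(),
                           cancer_site = fv_unknown(),
                           diagnosis_date = fv_unknown(),
                           tumor_grade = fv_unknown(), t_stage = fv_unknown(),
                           vital_status = "unknown",
                           relapse_date = fv_unknown(),
                           remission_documented = FALSE,
                           events = empty_events(), is_new = FALSE) {
  if (!is.character(record_id) || length(record_id) != 1L || !nzchar(record_id) || is.na(record_id)) {
    stop("record_id must be a non-empty string", call. = FALSE)
  }
  if (!vital_status %in% VITAL_STATUSES) {
    stop("invalid vital_status '", vital_status, "'", call. = FALSE)
  }
  fvs <- list(gender = gender, dob = dob, cancer_site = cancer_site,
              diagnosis_date = diagnosis_date, tumor_grade = tumor_grade,
              t_stage = t_stage, relapse_date = relapse_date)
  for (nm in names(fvs)) {
    if (!inherits(fvs[[nm]], "field_value")) {
      stop(nm, " must be a field_value", call. = FALSE)
    }
  }
  for (nm in c("dob", "diagnosis_date", "relapse_date")) {
    if (fv_is_present(fvs[[nm]]) && !inherits(fv_value(fvs[[nm]]), "Date")) {
      stop(nm, " must hold a Date when present", call. = FALSE)
    }
  }
  stopifnot(is.logical(remission_documented), length(remission_documented) == 1L,
            is.logical(is_new), length(is_new) == 1L)
  if (!inherits(events, "tbl_df")) events <- as_tibble(events)
  bad <- setdiff(events$event_type, EVENT_TYPES)
  if (length(bad)) stop("unknown event_type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  surg <- events$event_type == "surgery"
  if (any(surg & (is.na(events$procedure_code) | !nzchar(events$procedure_code)))) {
    stop("surgery events require a procedure_code", call. = FALSE)
  }
  structure(
    list(record_id = record_id, gender = gender, dob = dob,
         cancer_site = cancer_site, diagnosis_date = diagnosis_date,
         tumor_grade = tumor_grade, t_stage = t_stage,
         vital_status = vital_status, relapse_date = relapse_date,
         remission_documented = remission_documented,
         events = events, is_new = is_new),
    class = "patient_record"
  )
}

# field_value slots of a patient_record, in display order.
RECORD_FV_FIELDS <- c("gender", "dob", "cancer_site", "diagnosis_date",
                      "tumor_grade", "t_stage", "relapse_date")
RECORD_DATE_FIELDS <- c("dob", "diagnosis_date", "relapse_date")

#' @export
print.patient_record <- function(x, ...) {
  cat("<patient_record> ", x$record_id,
      if (x$is_new) " (new)" else " (update)", "\n", sep = "")
  for (f in RECORD_FV_FIELDS) cat("  ", f, ": ", format(x[[f]]), "\n", sep = "")
  cat("  vital_status: ", x$vital_status,
      "  remission_documented: ", x$remission_documented, "\n", sep = "")
  cat("  events: ", nrow(x$events), "\n", sep = "")
  invisible(x)
}

#' Build the chronological timeline of a record
#'
#' Collects the record's clinical events plus a diagnosis entry (when a
#' diagnosis date is recorded) into a chronologically ordered timeline, and
#' reports every inter-entry span longer than `gap_threshold_days` as a
#' gap. Same-day ties are broken by a fixed clinically plausible event
#' ordering (diagnosis before surgery before treatment starts, deaths
#' last), so the timeline is a pure function of the record: shuffling the
#' stored event order never changes it.
#'
#' @param record a [patient_record()].
#' @param gap_threshold_days positive number of days above which an
#'   inter-event span is reported as a gap (default 365).
#' @return An object of class `timeline` with elements `entries`
#'   (tibble: `date`, `event_type`, `label`) and `gaps` (tibble: `start`,
#'   `end`, `span_days`).
#' @export
build_timeline <- function(record, gap_threshold_days = 365) {
  stopifnot(inherits(record, "patient_record"),
            is.numeric(gap_threshold_days), gap_threshold_days > 0)
  ev <- record$events
  entries <- tibble(
    date = ev$date, event_type = ev$event_type,
    label = event_label(ev)
  )
  if (fv_is_present(record$diagnosis_date)) {
    entries <- dplyr::bind_rows(
      tibble(date = fv_value(record$diagnosis_date),
             event_type = "diagnosis", label = "DIAGNOSIS"),
      entries
    )
  }
  if (nrow(entries)) {
    ord <- order(entries$date, EVENT_TIE_PRIORITY[entries$event_type])
    entries <- entries[ord, ]
  }
  gaps <- tibble(start = as.Date(character()), end = as.Date(character()),
                 span_days = numeric())
  if (nrow(entries) > 1L) {
    span <- as.numeric(diff(entries$date))
    keep <- which(span > gap_threshold_days)
    gaps <- tibble(start = entries$date[keep], end = entries$date[keep + 1L],
                   span_days = span[keep])
  }
  structure(list(entries = entries, gaps = gaps,
                 gap_threshold_days = gap_threshold_days),
            class = "timeline")
}

event_label <- function(ev) {
  lbl <- toupper(ev$event_type)
  has_code <- ev$event_type == "surgery" & !is.na(ev$procedure_code)
  lbl[has_code] <- paste0("SURGERY (", ev$procedure_code[has_code], ")")
  has_plan <- ev$event_type == "xrt_start" & !is.na(ev$planned_duration_days)
  lbl[has_plan] <- paste0("XRT_START (planned ", ev$planned_duration_days[has_plan], "d)")
  lbl
}

#' @export
print.timeline <- function(x, ...) {
  cat("<timeline> ", nrow(x$entries), " entries, ", nrow(x$gaps),
      " gap(s) > ", x$gap_threshold_days, " days\n", sep = "")
  invisible(x)
}

# Does the record lack a value for `field`? For event-backed fields
# ("xrt_start") this means no such event; for field_value slots it means
# state == "unknown" (not_applicable is a recorded answer, not an omission).
field_is_missing <- function(record, field) {
  if (field == "xrt_start") {
    return(!any(record$events$event_type == "xrt_start"))
  }
  if (!field %in% RECORD_FV_FIELDS) stop("unknown field '", field, "'", call. = FALSE)
  fv_state(record[[field]]) == "unknown"
}

# Dates on which a relapse is documented (events plus the relapse_date field).
relapse_dates <- function(record) {
  d <- record$events$date[record$events$event_type == "relapse"]
  if (fv_is_present(record$relapse_date)) d <- c(d, fv_value(record$relapse_date))
  unique(as.Date(d, origin = "1970-01-01"))
}
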