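#' Possible-error rules
#'
#' The rule engine scans one record at a time for cross-field
#' inconsistencies that usually indicate an omission error. Each firing is
#' a *possible* error: likely but not certain, so firings are reported
#' non-interruptively and never block anything. Built-in rules:
#'
#' * **R1 escalated surgery** — a more radical surgical procedure follows a
#'   less radical one with no relapse documented in between; the relapse
#'   date was probably omitted.
#' * **R2 death from disease without relapse** — a documented remission and
#'   vital status "died from disease" imply a relapse occurred, but no
#'   relapse date is recorded.
#' * **R3 unexpected treatment activity** — a new treatment starts long
#'   after the previous treatment episode ended, with no relapse in
#'   between.
#' * **R4 abrupt radiation discontinuation** — a radiation course ends well
#'   short of its planned duration; toxicity information was probably
#'   omitted.
#' * **R5 missing key fields** — a key demographic/clinical field is in the
#'   *unknown* state (a *not applicable* value never fires).
#'
#' @name possible_error_rules
NULL

possible_error <- function(rule_id, record_id, implicated_fields, message,
                           date = as.Date(NA)) {
  stopifnot(length(implicated_fields) >= 1L, nzchar(message))
  new_tbl(list(rule_id = rule_id, record_id = record_id,
               implicated_fields = list(implicated_fields),
               message = message, certainty = "possible", date = as.Date(date)))
}

empty_errors <- function() {
  new_tbl(list(rule_id = character(), record_id = character(),
               implicated_fields = list(), message = character(),
               certainty = character(), date = as.Date(character())))
}

#' Default surgery radicality table
#'
#' Total order of surgical radicality used by the escalated-surgery rule
#' (breast-surgery defaults; override per database via the rule
#' configuration). Procedure codes absent from the table are incomparable
#' and the rule skips them.
#'
#' @return Named integer vector mapping procedure code to radicality rank
#'   (higher = more radical).
#' @export
default_radicality <- function() {
  c(biopsy = 1L, lumpectomy = 2L, simple_mastectomy = 3L,
    modified_radical_mastectomy = 4L, radical_mastectomy = 5L)
}

event_ref <- function(ev_row) {
  paste0("event:", ev_row$event_type, "@", format(ev_row$date, "%Y-%m-%d"))
}

#' @rdname possible_error_rules
#' @param record a [patient_record()].
#' @param radicality named integer vector ranking procedure codes (see
#'   [default_radicality()]).
#' @param params named list of rule parameters.
#' @return A tibble of firings with columns `rule_id`, `record_id`,
#'   `implicated_fields` (list column), `message`, `certainty`, `date`.
#' @export
rule_R1_escalated_surgery <- function(record, radicality = default_radicality(),
                                      params = list(min_gap_days = 30)) {
  min_gap <- params$min_gap_days %||% 30
  ev <- record$events
  surg <- ev[ev$event_type == "surgery" & ev$procedure_code %in% names(radicality), , drop = FALSE]
  if (nrow(surg) < 2L) return(empty_errors())
  surg <- surg[order(surg$date), , drop = FALSE]
  rel <- relapse_dates(record)
  out <- empty_errors()
  for (j in seq_len(nrow(surg))[-1]) {
    s2 <- surg[j, ]
    fired <- FALSE
    for (i in seq_len(j - 1L)) {
      s1 <- surg[i, ]
      if (radicality[[s1$procedure_code]] >= radicality[[s2$procedure_code]]) next
      if (as.numeric(s2$date - s1$date) < min_gap) next
      # a relapse explains the escalation only if it falls strictly after
      # the earlier surgery and no later than the new one
      if (any(rel > s1$date & rel <= s2$date)) next
      fired <- TRUE
      break
    }
    if (fired) {
      out <- dplyr::bind_rows(out, possible_error(
        "R1", record$record_id,
        c(event_ref(s2), "relapse_date"),
        paste0("more radical surgery (", s2$procedure_code, " on ",
               format(s2$date, "%Y-%m-%d"),
               ") after earlier less radical surgery with no documented relapse in between; ",
               "relapse date possibly omitted"),
        s2$date
      ))
    }
  }
  out
}

#' @rdname possible_error_rules
#' @export
rule_R2_death_without_relapse <- function(record, params = list()) {
  if (isTRUE(record$remission_documented) &&
      record$vital_status == "died_from_disease" &&
      !fv_is_present(record$relapse_date)) {
    return(possible_error(
      "R2", record$record_id,
      c("relapse_date", "vital_status", "remission_documented"),
      paste0("documented remission with vital status 'died from disease' implies ",
             "a relapse occurred, but no relapse date is recorded")
    ))
  }
  empty_errors()
}

# Treatment episodes of a record: start date plus the episode end (matching
# end event when one exists, otherwise the start date itself).
treatment_episodes <- function(record) {
  ev <- record$events
  starts <- ev[ev$event_type %in% c("surgery", "xrt_start", "chemo_start"), , drop = FALSE]
  if (!nrow(starts)) {
    return(tibble(event_type = character(), start = as.Date(character()),
                  end = as.Date(character())))
  }
  end_of <- c(xrt_start = "xrt_end", chemo_start = "chemo_end")
  end <- starts$date
  for (k in seq_len(nrow(starts))) {
    et <- starts$event_type[k]
    if (et %in% names(end_of)) {
      cand <- ev$date[ev$event_type == end_of[[et]] & ev$date >= starts$date[k]]
      if (length(cand)) end[k] <- min(cand)
    }
  }
  tibble(event_type = starts$event_type, start = starts$date, end = end)
}

#' @rdname possible_error_rules
#' @export
rule_R3_unexpected_treatment <- function(record, params = list(quiescence_days = 180)) {
  quiescence <- params$quiescence_days %||% 180
  epi <- treatment_episodes(record)
  if (nrow(epi) < 2L) return(empty_errors())
  rel <- relapse_dates(record)
  out <- empty_errors()
  for (k in seq_len(nrow(epi))) {
    prior_end <- epi$end[epi$start < epi$start[k]]
    if (!length(prior_end)) next
    last_end <- max(prior_end)
    gap <- as.numeric(epi$start[k] - last_end)
    if (gap < quiescence) next
    if (any(rel > last_end & rel <= epi$start[k])) next
    out <- dplyr::bind_rows(out, possible_error(
      "R3", record$record_id,
      c(paste0("event:", epi$event_type[k], "@", format(epi$start[k], "%Y-%m-%d")),
        "relapse_date"),
      paste0("treatment activity (", epi$event_type[k], ") resumed ", gap,
             " days after the previous treatment episode with no documented relapse; ",
             "relapse information possibly omitted"),
      epi$start[k]
    ))
  }
  out
}

#' @rdname possible_error_rules
#' @export
rule_R4_abrupt_xrt_stop <- function(record, params = list(min_completion_fraction = 0.8)) {
  frac <- params$min_completion_fraction %||% 0.8
  ev <- record$events
  starts <- ev[ev$event_type == "xrt_start" & !is.na(ev$planned_duration_days), , drop = FALSE]
  if (!nrow(starts)) return(empty_errors())
  ends <- ev[ev$event_type == "xrt_end", , drop = FALSE]
  out <- empty_errors()
  for (k in seq_len(nrow(starts))) {
    cand <- ends$date[ends$date >= starts$date[k]]
    if (!length(cand)) next
    end_date <- min(cand)
    actual <- as.numeric(end_date - starts$date[k])
    planned <- starts$planned_duration_days[k]
    if (actual < frac * planned) {
      out <- dplyr::bind_rows(out, possible_error(
        "R4", record$record_id,
        c(event_ref(starts[k, ]),
          paste0("event:xrt_end@", format(end_date, "%Y-%m-%d")),
          "toxicity_record"),
        paste0("radiation course ended after ", actual, " of ", planned,
               " planned days; toxicity information possibly omitted"),
        end_date
      ))
    }
  }
  out
}

R5_ALLOWED_FIELDS <- c("gender", "dob", "cancer_site", "diagnosis_date", "xrt_start")

#' @rdname possible_error_rules
#' @export
rule_R5_missing_key_fields <- function(record,
                                       params = list(key_fields = c("gender", "dob", "cancer_site", "xrt_start"))) {
  key_fields <- params$key_fields %||% c("gender", "dob", "cancer_site", "xrt_start")
  bad <- setdiff(key_fields, R5_ALLOWED_FIELDS)
  if (length(bad)) stop("R5 key_fields not supported: ", paste(bad, collapse = ", "), call. = FALSE)
  out <- empty_errors()
  for (f in key_fields) {
    if (field_is_missing(record, f)) {
      msg <- if (f == "xrt_start") {
        "no radiation start event recorded; possibly omitted"
      } else {
        paste0("key field '", f, "' has no recorded value; possibly omitted")
      }
      out <- dplyr::bind_rows(out, possible_error("R5", record$record_id, f, msg))
    }
  }
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Built-in rule registry: evaluation function, default parameters, and a
# parameter validator (returns invisibly or stops naming the bad key).
rule_registry <- function() {
  list(
    R1 = list(
      fn = function(record, params, radicality) rule_R1_escalated_surgery(record, radicality, params),
      defaults = list(min_gap_days = 30),
      validate = function(p) {
        check_positive_number(p$min_gap_days, "R1.min_gap_days")
      }
    ),
    R2 = list(
      fn = function(record, params, radicality) rule_R2_death_without_relapse(record, params),
      defaults = list(),
      validate = function(p) invisible(TRUE)
    ),
    R3 = list(
      fn = function(record, params, radicality) rule_R3_unexpected_treatment(record, params),
      defaults = list(quiescence_days = 180),
      validate = function(p) {
        check_positive_number(p$quiescence_days, "R3.quiescence_days")
      }
    ),
    R4 = list(
      fn = function(record, params, radicality) rule_R4_abrupt_xrt_stop(record, params),
      defaults = list(min_completion_fraction = 0.8),
      validate = function(p) {
        f <- p$min_completion_fraction
        if (!is.numeric(f) || length(f) != 1L || is.na(f) || f <= 0 || f > 1) {
          stop("invalid parameter R4.min_completion_fraction: must be in (0, 1]", call. = FALSE)
        }
        invisible(TRUE)
      }
    ),
    R5 = list(
      fn = function(record, params, radicality) rule_R5_missing_key_fields(record, params),
      defaults = list(key_fields = c("gender", "dob", "cancer_site", "xrt_start")),
      validate = function(p) {
        kf <- p$key_fields
        if (!is.character(kf) || !length(kf) || !all(kf %in% R5_ALLOWED_FIELDS)) {
          stop("invalid parameter R5.key_fields: must be a subset of {",
               paste(R5_ALLOWED_FIELDS, collapse = ", "), "}", call. = FALSE)
        }
        invisible(TRUE)
      }
    )
  )
}

check_positive_number <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop("invalid parameter ", what, ": must be a positive number", call. = FALSE)
  }
  invisible(TRUE)
}

#' Default rule configuration
#'
#' All built-in rules enabled with their documented default parameters.
#'
#' @return A list of rule configs, each `list(rule_id, enabled, params)`.
#' @export
default_rule_configs <- function() {
  reg <- rule_registry()
  lapply(setNames(names(reg), names(reg)), function(id) {
    list(rule_id = id, enabled = TRUE, params = reg[[id]]$defaults)
  })
}

#' Load a rule configuration file
#'
#' Reads a YAML or JSON configuration with optional `rules` (list of
#' `{id, enabled, params}`) and `radicality` (map procedure code to rank)
#' sections. Absent rules and parameters keep their built-in defaults; an
#' empty file yields the full default configuration. Unknown rule ids and
#' malformed parameters raise a configuration error naming the offending
#' key.
#'
#' @param path path to the configuration file (extension `.json` is parsed
#'   as JSON, anything else as YAML).
#' @return `list(configs = <rule configs>, radicality = <named ranks>)`.
#' @export
load_rule_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  reg <- rule_registry()
  configs <- default_rule_configs()
  for (entry in raw$rules %||% list()) {
    id <- entry$id %||% entry$rule_id
    if (is.null(id) || !id %in% names(reg)) {
      stop("unknown rule id in config: '", id %||% "<missing>", "'", call. = FALSE)
    }
    params <- configs[[id]]$params
    for (k in names(entry$params %||% list())) {
      if (!k %in% names(reg[[id]]$defaults)) {
        stop("unknown parameter '", k, "' for rule ", id, call. = FALSE)
      }
      params[[k]] <- simplify_param(entry$params[[k]])
    }
    reg[[id]]$validate(params)
    configs[[id]] <- list(rule_id = id,
                          enabled = if (is.null(entry$enabled)) TRUE else isTRUE(entry$enabled),
                          params = params)
  }
  radicality <- default_radicality()
  if (!is.null(raw$radicality)) {
    ranks <- vapply(raw$radicality, function(v) as.integer(v), integer(1))
    if (anyNA(ranks) || anyDuplicated(ranks)) {
      stop("invalid radicality table: ranks must be distinct integers", call. = FALSE)
    }
    radicality <- ranks
  }
  list(configs = configs, radicality = radicality)
}

simplify_param <- function(x) {
  if (is.list(x)) unlist(x) else x
}

#' Apply all enabled possible-error rules to a record
#'
#' Pure function: the same record, configuration and radicality table
#' always yield the same firings, ordered by rule id and then by the date
#' of the implicated event. Rules silently skip records lacking the fields
#' they inspect.
#'
#' @param record a [patient_record()].
#' @param configs rule configurations (see [default_rule_configs()] and
#'   [load_rule_config()]).
#' @param radicality surgery radicality table (see [default_radicality()]).
#' @return A tibble of possible errors (zero rows when nothing fires).
#' @examples
#' rec <- patient_record(
#'   "B-0001",
#'   gender = fv_present("F"),
#'   diagnosis_date = fv_present(as.Date("2001-01-10")),
#'   events = rbind(
#'     clinical_event("surgery", "2001-02-01", procedure_code = "lumpectomy"),
#'     clinical_event("surgery", "2002-08-01",
#'                    procedure_code = "modified_radical_mastectomy")
#'   )
#' )
#' apply_rules(rec)
#' @export
apply_rules <- function(record, configs = default_rule_configs(),
                        radicality = default_radicality()) {
  stopifnot(inherits(record, "patient_record"))
  reg <- rule_registry()
  out <- empty_errors()
  for (cfg in configs) {
    if (!isTRUE(cfg$enabled)) next
    fn <- reg[[cfg$rule_id]]$fn
    if (is.null(fn)) stop("unknown rule id '", cfg$rule_id, "'", call. = FALSE)
    out <- dplyr::bind_rows(out, fn(record, cfg$params, radicality))
  }
  if (nrow(out)) out <- out[order(out$rule_id, out$date), ]
  out
}

#' Audit a whole cohort
#'
#' Runs [apply_rules()] over every record and binds the firings.
#'
#' @inheritParams apply_rules
#' @param records list of [patient_record()] objects.
#' @return A tibble of possible errors across the cohort.
#' @export
audit_cohort <- function(records, configs = default_rule_configs(),
                         radicality = default_radicality()) {
  dplyr::bind_rows(lapply(records, apply_rules, configs = configs,
                          radicality = radicality))
}
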