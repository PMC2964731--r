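# Shared fixtures, built in code.

# Breast-cancer course: lumpectomy, adjuvant radiation, then a modified
# radical mastectomy ~18 months later with no relapse documented.
escalation_record <- function(id = "B-0001") {
  patient_record(
    id,
    gender = fv_present("F"),
    dob = fv_present(as.Date("1950-05-01")),
    cancer_site = fv_present("breast"),
    diagnosis_date = fv_present(as.Date("2001-01-10")),
    tumor_grade = fv_present("moderate"),
    t_stage = fv_present("T1"),
    vital_status = "alive",
    relapse_date = fv_unknown(),
    events = dplyr::bind_rows(
      clinical_event("surgery", "2001-02-01", procedure_code = "lumpectomy"),
      clinical_event("xrt_start", "2001-03-01", planned_duration_days = 42),
      clinical_event("xrt_end", "2001-04-12"),
      clinical_event("surgery", "2002-10-01",
                     procedure_code = "modified_radical_mastectomy")
    )
  )
}

# Complete, internally consistent record that fires no rule.
clean_record <- function(id = "B-0002") {
  patient_record(
    id,
    gender = fv_present("F"),
    dob = fv_present(as.Date("1948-03-15")),
    cancer_site = fv_present("breast"),
    diagnosis_date = fv_present(as.Date("2003-06-01")),
    tumor_grade = fv_present("well"),
    t_stage = fv_present("T1"),
    vital_status = "alive",
    relapse_date = fv_na(),
    events = dplyr::bind_rows(
      clinical_event("surgery", "2003-06-20", procedure_code = "lumpectomy"),
      clinical_event("xrt_start", "2003-07-15", planned_duration_days = 42),
      clinical_event("xrt_end", "2003-08-26"),
      clinical_event("follow_up", "2003-12-01"),
      clinical_event("follow_up", "2004-05-20")
    )
  )
}

# Bare record with only the slots a statistics test needs.
bare_record <- function(id, gender = fv_present("F"),
                        dob = fv_present(as.Date("1950-01-01")),
                        cancer_site = fv_present("sarcoma_extremity"),
                        has_xrt = TRUE, is_new = FALSE) {
  ev <- if (has_xrt) {
    clinical_event("xrt_start", as.Date("2001-03-01"), planned_duration_days = 42)
  } else {
    empty_events()
  }
  patient_record(id, gender = gender, dob = dob, cancer_site = cancer_site,
                 events = ev, is_new = is_new)
}

ts_utc <- function(x) as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")

access_trace <- function(record_id, user_id = "u1", timestamp = "2008-07-04 10:00:00") {
  tibble::tibble(kind = "summary_access", record_id = record_id, user_id = user_id,
                 timestamp = ts_utc(timestamp), field = "", before = "", after = "")
}

edit_trace <- function(record_id, field = "relapse_date", before = "",
                       after = "2005-01-01", user_id = "u1",
                       timestamp = "2008-07-04 10:05:00") {
  tibble::tibble(kind = "field_edit", record_id = record_id, user_id = user_id,
                 timestamp = ts_utc(timestamp), field = field,
                 before = before, after = after)
}

# all permutations of seq_len(n) (n small)
combinat_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in combinat_permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}
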