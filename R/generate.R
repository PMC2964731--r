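#' Specification for the synthetic cohort generator
#'
#' Collects every knob of [generate_cohort()] with defaults chosen to
#' emulate the study conditions the analyses were designed for: a
#' radiation-oncology registry of 1,356 records of which 200 are newly
#' entered, three data-entry users with very different summary-access
#' propensities (84.6%, 47.1%, 11.8%), probe-field omission rates of a few
#' percent that cluster within careless records, and an index-field (XRT
#' start date) split between true missingness and recoverable omission
#' errors at roughly a 2:1 ratio.
#'
#' @param n_records number of records.
#' @param seed integer seed fixing all randomness.
#' @param missingness named baseline per-field omission probabilities for
#'   `gender`, `dob`, `cancer_site`, `tumor_grade`, `t_stage`.
#' @param careless_fraction fraction of records entered "carelessly".
#' @param careless_multiplier multiplier applied to all omission
#'   probabilities in careless records (two-point clustering model).
#' @param index_error_rate baseline probability that a record's XRT start
#'   date exists but was omitted (an omission error; multiplied for
#'   careless records).
#' @param index_truly_missing_rate probability that no XRT start date is
#'   recoverable at all (true missingness, not an error).
#' @param relapse_prevalence probability a record's disease relapses.
#' @param omitted_relapse_rate probability that a relapsed record's relapse
#'   date is omitted at entry (eligible for later correction).
#' @param scenario_counts named counts of records rewritten into scenarios
#'   that exactly satisfy each possible-error rule (`R1`..`R5`).
#' @param user_profiles tibble: `user_id`, `workload_share`,
#'   `access_probability`, `correction_probability_given_access`,
#'   `correction_probability_without_access`,
#'   `edit_latency_median_minutes`, `edit_latency_sdlog`.
#' @param new_record_fraction fraction of newly entered (vs updated)
#'   records.
#' @return A `generator_spec` list, validated.
#' @export
generator_spec <- function(n_records = 1356,
                           seed = 1,
                           missingness = c(gender = 0.05, dob = 0.04,
                                           cancer_site = 0.05,
                                           tumor_grade = 0.10, t_stage = 0.10),
                           careless_fraction = 0.2,
                           careless_multiplier = 2.5,
                           index_error_rate = 0.04,
                           index_truly_missing_rate = 0.10,
                           relapse_prevalence = 0.25,
                           omitted_relapse_rate = 0.30,
                           scenario_counts = c(R1 = 0, R2 = 0, R3 = 0, R4 = 0, R5 = 0),
                           user_profiles = default_user_profiles(),
                           new_record_fraction = 200 / 1356) {
  probs <- c(missingness, careless_fraction,
             index_error_rate, index_truly_missing_rate,
             relapse_prevalence, omitted_relapse_rate, new_record_fraction,
             user_profiles$access_probability,
             user_profiles$correction_probability_given_access,
             user_profiles$correction_probability_without_access)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (n_records < 1) stop("n_records must be positive", call. = FALSE)
  if (careless_multiplier < 1) stop("careless_multiplier must be >= 1", call. = FALSE)
  if (any(scenario_counts < 0) || sum(scenario_counts) > n_records) {
    stop("scenario_counts must be non-negative and sum to at most n_records", call. = FALSE)
  }
  if (abs(sum(user_profiles$workload_share) - 1) > 1e-8) {
    stop("user workload shares must sum to 1", call. = FALSE)
  }
  structure(list(
    n_records = as.integer(n_records), seed = as.integer(seed),
    missingness = missingness, careless_fraction = careless_fraction,
    careless_multiplier = careless_multiplier,
    index_error_rate = index_error_rate,
    index_truly_missing_rate = index_truly_missing_rate,
    relapse_prevalence = relapse_prevalence,
    omitted_relapse_rate = omitted_relapse_rate,
    scenario_counts = scenario_counts,
    user_profiles = user_profiles,
    new_record_fraction = new_record_fraction
  ), class = "generator_spec")
}

#' @rdname generator_spec
#' @export
default_user_profiles <- function() {
  tibble(
    user_id = c("tech_A", "tech_B", "tech_C"),
    workload_share = c(0.2, 0.6, 0.2),
    access_probability = c(0.846, 0.471, 0.118),
    correction_probability_given_access = 0.30,
    correction_probability_without_access = 0.05,
    edit_latency_median_minutes = 5,
    edit_latency_sdlog = 0.8
  )
}

CANCER_SITES <- c("breast", "sarcoma_extremity", "sarcoma_trunk")
GENDERS <- c("F", "M")
T_STAGES <- c("T1", "T2", "T3", "T4")
GRADES <- c("well", "moderate", "poor")

#' Generate a synthetic cohort with ground truth
#'
#' Builds a full synthetic registry: patient records with a clinically
#' plausible event scaffold (diagnosis, surgery, optional radiation course
#' with planned duration, optional chemotherapy, optional relapse and
#' salvage treatment, death or censoring), per-field omissions that cluster
#' within careless records, rule-matching injected scenarios (verified
#' against the rule predicates before emission), user access/edit traces,
#' and an exhaustive ground-truth log that downstream tests use as an
#' oracle. Deterministic: the same spec (including its seed) always
#' produces identical output.
#'
#' @param spec a [generator_spec()].
#' @return `list(records, traces, ground_truth)` where `ground_truth` has
#'   `injections` (record id, rule id, target, true value), `review_results`
#'   (named logical: was the omitted index value recoverable), `categories`,
#'   and `outcomes` (per-record user, access, eligibility, correction and
#'   latency).
#' @export
generate_cohort <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  n <- spec$n_records
  ids <- sprintf("S%05d", seq_len(n))
  careless <- runif(n) < spec$careless_fraction
  mult <- ifelse(careless, spec$careless_multiplier, 1)
  cap <- function(p) pmin(p, 1)

  # index-field structure: truly missing vs omitted-by-error XRT start
  truly_missing <- runif(n) < spec$index_truly_missing_rate
  index_omitted <- !truly_missing & runif(n) < cap(spec$index_error_rate * mult)
  has_xrt <- !truly_missing & !index_omitted

  relapsed <- runif(n) < spec$relapse_prevalence
  relapse_omitted <- relapsed & runif(n) < spec$omitted_relapse_rate

  # records destined to be rewritten into rule scenarios carry no other
  # injected errors (they would be overwritten anyway)
  n_scenarios <- sum(spec$scenario_counts)
  if (n_scenarios > 0L) {
    scenario_slots <- seq_len(n_scenarios)
    index_omitted[scenario_slots] <- FALSE
    relapse_omitted[scenario_slots] <- FALSE
  }

  field_omitted <- vapply(names(spec$missingness), function(f)
    runif(n) < cap(spec$missingness[[f]] * mult), logical(n))
  field_omitted <- matrix(field_omitted, nrow = n,
                          dimnames = list(NULL, names(spec$missingness)))

  is_new <- runif(n) < spec$new_record_fraction

  base_dates <- as.Date("2000-01-01") + sample.int(2500, n, replace = TRUE)
  inj_id <- character(); inj_rule <- character()
  inj_target <- character(); inj_truth <- character()
  add_injection <- function(rid, rule, target, truth) {
    inj_id <<- c(inj_id, rid); inj_rule <<- c(inj_rule, rule)
    inj_target <<- c(inj_target, target); inj_truth <<- c(inj_truth, truth)
  }

  records <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- scaffold_record(
      id = ids[i], diagnosis = base_dates[i], has_xrt = has_xrt[i],
      relapsed = relapsed[i], is_new = is_new[i]
    )
    # apply clustered probe/auxiliary field omissions
    for (f in colnames(field_omitted)) {
      if (field_omitted[i, f] && fv_is_present(rec[[f]])) {
        rec[[f]] <- fv_unknown()
      }
    }
    if (index_omitted[i]) {
      # the XRT course happened; its start date was omitted at entry
      add_injection(ids[i], "index", "xrt_start",
                    format(base_dates[i] + 60, "%Y-%m-%d"))
    }
    if (relapse_omitted[i] && fv_is_present(rec$relapse_date)) {
      true_rel <- fv_canonical(rec$relapse_date)
      rec$relapse_date <- fv_unknown()
      rec$events <- rec$events[rec$events$event_type != "relapse", , drop = FALSE]
      add_injection(ids[i], "omitted_relapse", "relapse_date", true_rel)
    }
    records[[i]] <- rec
  }

  # rewrite dedicated records into rule-matching scenarios
  sc <- spec$scenario_counts
  sc <- sc[sc > 0]
  slot <- 1L
  for (rule in names(sc)) {
    for (k in seq_len(sc[[rule]])) {
      i <- slot; slot <- slot + 1L
      built <- build_scenario(rule, ids[i], base_dates[i], is_new[i])
      records[[i]] <- built$record
      if (nrow(built$log)) {
        add_injection(built$log$record_id, built$log$rule_id,
                      built$log$target, built$log$true_value)
      }
    }
  }

  injections <- tibble(record_id = inj_id, rule_id = inj_rule,
                       target = inj_target, true_value = inj_truth)

  index_missing <- vapply(records, field_is_missing, logical(1), field = "xrt_start")
  found <- setNames(ids %in% injections$record_id[injections$rule_id == "index"], ids)
  review_results <- found[index_missing]
  categories <- ifelse(!index_missing, "no_missing_index",
                       ifelse(found, "missing_found", "missing_not_found"))
  names(categories) <- ids

  tr <- generate_traces(spec, records, injections)

  list(
    records = records,
    traces = tr$traces,
    ground_truth = list(
      injections = injections,
      review_results = review_results,
      categories = categories,
      outcomes = tr$outcomes,
      careless = setNames(careless, ids)
    )
  )
}

# Fast internal events builder (one tibble, no per-event binding).
events_tibble <- function(event_type, date, procedure_code = NA_character_,
                          planned_duration_days = NA_real_,
                          source_form = NA_character_) {
  k <- length(event_type)
  new_tbl(list(
    event_type = event_type, date = as.Date(date, origin = "1970-01-01"),
    procedure_code = rep_len(as.character(procedure_code), k),
    planned_duration_days = rep_len(as.numeric(planned_duration_days), k),
    source_form = rep_len(as.character(source_form), k)
  ))
}

# Minimal clinically plausible event scaffold for one record.
scaffold_record <- function(id, diagnosis, has_xrt, relapsed, is_new) {
  surgery_date <- diagnosis + sample.int(45, 1L)
  types <- "surgery"; dates <- surgery_date
  codes <- sample(c("biopsy", "lumpectomy", "simple_mastectomy"), 1L)
  plans <- NA_real_; forms <- "treatment"
  last_treatment <- surgery_date
  if (has_xrt) {
    xrt_start <- surgery_date + sample(20:60, 1L)
    planned <- sample(c(35, 42, 49), 1L)
    xrt_end <- xrt_start + planned
    types <- c(types, "xrt_start", "xrt_end")
    dates <- c(dates, xrt_start, xrt_end)
    codes <- c(codes, NA, NA)
    plans <- c(plans, planned, NA)
    forms <- c(forms, "radiation", "radiation")
    last_treatment <- xrt_end
  }
  relapse_date <- fv_na()
  vital <- "alive"
  if (relapsed) {
    rel <- last_treatment + sample(200:900, 1L)
    relapse_date <- fv_present(rel)
    salvage <- rel + sample.int(30, 1L)
    types <- c(types, "relapse", "chemo_start", "chemo_end")
    dates <- c(dates, rel, salvage, salvage + 120)
    codes <- c(codes, NA, NA, NA)
    plans <- c(plans, NA, NA, NA)
    forms <- c(forms, "outcome", "treatment", "treatment")
    if (runif(1) < 0.4) {
      vital <- "died_from_disease"
      types <- c(types, "death")
      dates <- c(dates, salvage + 120 + sample.int(400, 1L))
      codes <- c(codes, NA); plans <- c(plans, NA); forms <- c(forms, "outcome")
    }
  } else {
    types <- c(types, "follow_up")
    dates <- c(dates, last_treatment + 180)
    codes <- c(codes, NA); plans <- c(plans, NA); forms <- c(forms, "follow_up")
  }
  patient_record(
    record_id = id,
    gender = fv_present(sample(GENDERS, 1L)),
    dob = fv_present(diagnosis - sample(8000:30000, 1L)),
    cancer_site = fv_present(sample(CANCER_SITES, 1L)),
    diagnosis_date = fv_present(diagnosis),
    tumor_grade = fv_present(sample(GRADES, 1L)),
    t_stage = fv_present(sample(T_STAGES, 1L)),
    vital_status = vital,
    relapse_date = relapse_date,
    remission_documented = !relapsed && runif(1) < 0.5,
    events = events_tibble(types, dates, codes, plans, forms),
    is_new = is_new
  )
}

# Construct a record that exactly satisfies one rule predicate; verified by
# evaluating the rule before emission.
build_scenario <- function(rule, id, base_date, is_new) {
  log <- tibble(record_id = character(), rule_id = character(),
                target = character(), true_value = character())
  common <- list(
    record_id = id,
    gender = fv_present("F"), dob = fv_present(base_date - 15000),
    cancer_site = fv_present("breast"),
    diagnosis_date = fv_present(base_date),
    tumor_grade = fv_present("moderate"), t_stage = fv_present("T2"),
    is_new = is_new
  )
  rec <- switch(rule,
    R1 = {
      log <- tibble(record_id = id, rule_id = "R1", target = "relapse_date",
                    true_value = format(base_date + 300, "%Y-%m-%d"))
      do.call(patient_record, c(common, list(
        relapse_date = fv_unknown(),
        events = dplyr::bind_rows(
          clinical_event("surgery", base_date + 20, procedure_code = "lumpectomy"),
          clinical_event("xrt_start", base_date + 50, planned_duration_days = 42),
          clinical_event("xrt_end", base_date + 92),
          clinical_event("surgery", base_date + 560,
                         procedure_code = "modified_radical_mastectomy")
        ))))
    },
    R2 = {
      log <- tibble(record_id = id, rule_id = "R2", target = "relapse_date",
                    true_value = format(base_date + 700, "%Y-%m-%d"))
      do.call(patient_record, c(common, list(
        vital_status = "died_from_disease",
        remission_documented = TRUE,
        relapse_date = fv_unknown(),
        events = dplyr::bind_rows(
          clinical_event("surgery", base_date + 20, procedure_code = "simple_mastectomy"),
          clinical_event("remission", base_date + 200),
          clinical_event("death", base_date + 900)
        ))))
    },
    R3 = {
      log <- tibble(record_id = id, rule_id = "R3", target = "relapse_date",
                    true_value = format(base_date + 1000, "%Y-%m-%d"))
      do.call(patient_record, c(common, list(
        relapse_date = fv_unknown(),
        events = dplyr::bind_rows(
          clinical_event("surgery", base_date + 20, procedure_code = "simple_mastectomy"),
          clinical_event("chemo_start", base_date + 1120),
          clinical_event("chemo_end", base_date + 1240)
        ))))
    },
    R4 = {
      log <- tibble(record_id = id, rule_id = "R4", target = "toxicity_record",
                    true_value = "radiation_toxicity")
      do.call(patient_record, c(common, list(
        relapse_date = fv_na(),
        events = dplyr::bind_rows(
          clinical_event("surgery", base_date + 20, procedure_code = "lumpectomy"),
          clinical_event("xrt_start", base_date + 50, planned_duration_days = 42),
          clinical_event("xrt_end", base_date + 60)
        ))))
    },
    R5 = {
      log <- dplyr::bind_rows(
        tibble(record_id = id, rule_id = "R5", target = "gender", true_value = "F"),
        tibble(record_id = id, rule_id = "R5", target = "dob",
               true_value = format(base_date - 15000, "%Y-%m-%d"))
      )
      mods <- common
      mods$gender <- fv_unknown()
      mods$dob <- fv_unknown()
      do.call(patient_record, c(mods, list(
        relapse_date = fv_na(),
        events = dplyr::bind_rows(
          clinical_event("surgery", base_date + 20, procedure_code = "lumpectomy"),
          clinical_event("xrt_start", base_date + 50, planned_duration_days = 42),
          clinical_event("xrt_end", base_date + 92)
        ))))
    },
    stop("no scenario builder for rule '", rule, "'", call. = FALSE)
  )
  fired <- apply_rules(rec)
  if (!rule %in% fired$rule_id) {
    stop("internal error: constructed scenario does not satisfy rule ", rule, call. = FALSE)
  }
  list(record = rec, log = log)
}

# Simulate data-entry sessions: user assignment, summary accesses,
# a bookkeeping edit per session, and corrections of omitted relapse dates.
generate_traces <- function(spec, records, injections) {
  n <- length(records)
  ids <- vapply(records, function(r) r$record_id, character(1))
  up <- spec$user_profiles
  user_idx <- sample.int(nrow(up), n, replace = TRUE, prob = up$workload_share)
  session_start <- as.POSIXct("2008-07-04 09:00:00", tz = "UTC") +
    (seq_len(n) - 1L) * 3600

  omitted_rel <- injections[injections$rule_id == "omitted_relapse", , drop = FALSE]
  eligible <- setNames(ids %in% omitted_rel$record_id, ids)
  true_rel <- setNames(omitted_rel$true_value, omitted_rel$record_id)

  tr_kind <- character(); tr_rid <- character(); tr_uid <- character()
  tr_ts <- numeric(); tr_field <- character(); tr_before <- character()
  tr_after <- character()
  add_trace <- function(kind, rid, uid, ts, field = "", before = "", after = "") {
    tr_kind[[length(tr_kind) + 1L]] <<- kind
    tr_rid[[length(tr_rid) + 1L]] <<- rid
    tr_uid[[length(tr_uid) + 1L]] <<- uid
    tr_ts[[length(tr_ts) + 1L]] <<- as.numeric(ts)
    tr_field[[length(tr_field) + 1L]] <<- field
    tr_before[[length(tr_before) + 1L]] <<- before
    tr_after[[length(tr_after) + 1L]] <<- after
  }
  out_accessed <- logical(n); out_nacc <- integer(n)
  out_corr <- logical(n); out_lat <- rep(NA_real_, n)
  out_uid <- character(n)

  for (i in seq_len(n)) {
    u <- up[user_idx[i], ]
    out_uid[i] <- u$user_id
    t0 <- session_start[i]
    # every session edits something: workload attribution anchor
    add_trace("field_edit", ids[i], u$user_id, t0, "t_stage", "",
              render_field_value(records[[i]], "t_stage"))
    accessed <- runif(1) < u$access_probability
    n_acc <- 0L
    last_access <- NA_real_
    if (accessed) {
      n_acc <- sample(c(1L, 2L, 3L), 1L, prob = c(0.80, 0.146, 0.054))
      at <- as.numeric(t0) + sort(sample.int(1800, n_acc))
      for (a in seq_len(n_acc)) {
        add_trace("summary_access", ids[i], u$user_id, at[a])
      }
      last_access <- at[n_acc]
    }
    out_accessed[i] <- accessed; out_nacc[i] <- n_acc
    if (eligible[[ids[i]]]) {
      p_corr <- if (accessed) u$correction_probability_given_access
                else u$correction_probability_without_access
      if (runif(1) < p_corr) {
        out_corr[i] <- TRUE
        latency <- rlnorm(1, meanlog = log(u$edit_latency_median_minutes),
                          sdlog = u$edit_latency_sdlog)
        out_lat[i] <- latency
        ts <- if (accessed) last_access + latency * 60 else as.numeric(t0) + 1200 + latency * 60
        add_trace("field_edit", ids[i], u$user_id, ts, "relapse_date", "",
                  true_rel[[ids[i]]])
      }
    }
  }
  traces <- tibble(
    kind = tr_kind, record_id = tr_rid, user_id = tr_uid,
    timestamp = as.POSIXct(tr_ts, origin = "1970-01-01", tz = "UTC"),
    field = tr_field, before = tr_before, after = tr_after
  )
  traces <- traces[order(traces$timestamp, traces$record_id, traces$kind), , drop = FALSE]
  outcomes <- tibble(
    record_id = ids, user_id = out_uid, accessed = out_accessed,
    n_accesses = out_nacc, eligible_correction = unname(eligible[ids]),
    corrected = out_corr, latency_minutes = out_lat
  )
  list(traces = traces, outcomes = outcomes)
}

#' Inject an omission error into a record
#'
#' Sets a currently present field to the *unknown* state and appends the
#' true value to the ground-truth log, so that downstream detection can be
#' scored against what was removed. Injecting into an already missing field
#' is a warning no-op (the log is not extended twice).
#'
#' @param record a [patient_record()].
#' @param field name of a three-valued record field that is currently
#'   present.
#' @param log an injections tibble to extend (or `NULL` to start one).
#' @param quiet suppress the no-op warning.
#' @return `list(record, log)`.
#' @export
inject_omission <- function(record, field, log = NULL, quiet = FALSE) {
  if (is.null(log)) {
    log <- tibble(record_id = character(), rule_id = character(),
                  target = character(), true_value = character())
  }
  if (!field %in% RECORD_FV_FIELDS) stop("unknown field '", field, "'", call. = FALSE)
  if (!fv_is_present(record[[field]])) {
    if (!quiet) warning("field '", field, "' already missing; injection skipped")
    return(list(record = record, log = log))
  }
  truth <- fv_canonical(record[[field]])
  record[[field]] <- fv_unknown()
  log <- dplyr::bind_rows(log, tibble(
    record_id = record$record_id, rule_id = "omission", target = field,
    true_value = truth
  ))
  list(record = record, log = log)
}

#' @rdname inject_omission
#' @details `restore_omission()` is the inverse: it re-materialises the
#'   logged true value into the field and drops the log entry.
#' @export
restore_omission <- function(record, field, log) {
  hit <- which(log$record_id == record$record_id & log$target == field)
  if (!length(hit)) stop("no logged injection for ", record$record_id, "/", field, call. = FALSE)
  truth <- log$true_value[hit[1L]]
  record[[field]] <- if (field %in% RECORD_DATE_FIELDS) {
    fv_present(parse_iso_date(truth))
  } else {
    fv_present(truth)
  }
  list(record = record, log = log[-hit[1L], , drop = FALSE])
}

#' Build a cohort with prescribed missingness marginals
#'
#' Deterministically constructs a minimal cohort whose category sizes and
#' per-field missing counts match given marginal totals — the shape needed
#' to reproduce a published prevalence/co-occurrence table whose
#' record-level data are unavailable. Within each category the missing
#' flags for each field are assigned to the leading records; the overlap
#' structure between fields is therefore arbitrary (marginals do not
#' determine it) but fixed.
#'
#' @param n named integer vector: records per category
#'   (`no_missing_index`, `missing_not_found`, `missing_found`).
#' @param missing named list: for each of `missing_not_found` /
#'   `missing_found` (and optionally `no_missing_index`), a named vector of
#'   missing counts per probe field.
#' @param probe_fields the probed fields.
#' @return `list(records, review_results)` ready for
#'   [cooccurrence_analysis()].
#' @export
cohort_from_marginals <- function(n, missing,
                                  probe_fields = c("gender", "dob", "cancer_site")) {
  stopifnot(all(names(n) %in% RECORD_CATEGORIES))
  records <- list()
  review <- logical(0)
  idx <- 0L
  for (cat in names(n)) {
    counts <- missing[[cat]] %||% setNames(rep(0L, length(probe_fields)), probe_fields)
    if (any(counts > n[[cat]])) stop("missing count exceeds category size", call. = FALSE)
    for (k in seq_len(n[[cat]])) {
      idx <- idx + 1L
      rid <- sprintf("M%05d", idx)
      args <- list(
        record_id = rid,
        gender = fv_present("F"),
        dob = fv_present(as.Date("1950-01-01")),
        cancer_site = fv_present("sarcoma_extremity"),
        diagnosis_date = fv_present(as.Date("2001-01-01"))
      )
      for (f in probe_fields) {
        cnt <- if (f %in% names(counts)) counts[[f]] else 0L
        if (k <= cnt) args[[f]] <- fv_unknown()
      }
      if (cat == "no_missing_index") {
        args$events <- clinical_event("xrt_start", as.Date("2001-03-01"),
                                      planned_duration_days = 42)
      } else {
        review[[rid]] <- (cat == "missing_found")
      }
      records[[idx]] <- do.call(patient_record, args)
    }
  }
  list(records = records, review_results = review)
}
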