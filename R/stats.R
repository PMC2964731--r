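#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Two-sided exact interval for a binomial proportion, obtained by
#' inverting the binomial tail probabilities, returned in percent. The
#' lower bound is exactly 0 when `x = 0` and the upper bound exactly 100
#' when `x = n`.
#'
#' @param x number of successes (0..n).
#' @param n number of trials (>= 1).
#' @param alpha two-sided error level in (0, 1); default 0.05 for a 95%
#'   interval.
#' @return Named numeric vector `c(low, high)` in percent.
#' @examples
#' clopper_pearson_ci(18, 226) # 4.8-12.3 after 1-decimal rounding
#' @export
clopper_pearson_ci <- function(x, n, alpha = 0.05) {
  if (!is.numeric(x) || !is.numeric(n) || length(x) != 1L || length(n) != 1L ||
      is.na(x) || is.na(n) || n < 1 || x < 0 || x > n ||
      x != round(x) || n != round(n)) {
    stop("require integer counts with 0 <= x <= n and n >= 1", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  ci <- stats::binom.test(x, n, conf.level = 1 - alpha)$conf.int
  c(low = 100 * ci[1L], high = 100 * ci[2L])
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the probability-mass method: the sum of
#' hypergeometric probabilities, over all tables with the observed margins,
#' that do not exceed the observed table's probability (inclusion judged
#' with a small relative tolerance). A table with a zero margin carries no
#' information about association; by convention it returns `p = 1` with a
#' warning.
#'
#' @param table a 2x2 matrix (or something coercible to one) of
#'   non-negative integer counts.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(0, 86, 5, 73), 2, 2, byrow = TRUE)) # ~0.023
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L)) || any(is.na(m)) || any(m < 0) ||
      any(m != round(m))) {
    stop("require a 2x2 matrix of non-negative integer counts", call. = FALSE)
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warning("zero margin in 2x2 table; returning p = 1 by convention")
    return(1.0)
  }
  stats::fisher.test(m)$p.value
}

#' Hochberg step-up multiple-testing adjustment
#'
#' Step-up adjusted p-values (Simes-Hochberg): with raw p-values sorted in
#' decreasing order, the i-th largest is multiplied by i and running minima
#' are taken from the largest down, clipped at 1, then mapped back to the
#' input order. Controls the family-wise error rate under non-negative
#' dependence.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
hochberg_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must be numbers in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "hochberg")
}

# Half-up decimal rounding (R's round() is half-even); display convention
# for percents.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

RECORD_CATEGORIES <- c("no_missing_index", "missing_not_found", "missing_found")

#' Classify records by index-field missingness and manual review
#'
#' Partitions a cohort into the three categories used in the omission
#' analysis: records with the index field recorded
#' (`no_missing_index`); records missing it for which manual review could
#' not recover a value (`missing_not_found` — truly missing, not a data
#' error); and records missing it for which review found the value
#' (`missing_found` — an omission error).
#'
#' @param records list of [patient_record()] objects.
#' @param index_field the probed field; `"xrt_start"` (the default) means
#'   absence of any radiation-start event, other names refer to
#'   three-valued record fields (missing = unknown).
#' @param review_results named logical vector (or list), record id ->
#'   whether manual review found a value. Must cover exactly the records
#'   with the index field missing.
#' @return Named character vector record id -> category.
#' @export
classify_records <- function(records, index_field = "xrt_start", review_results) {
  ids <- vapply(records, function(r) r$record_id, character(1))
  missing <- vapply(records, field_is_missing, logical(1), field = index_field)
  review <- unlist(review_results)
  extra <- setdiff(names(review), ids[missing])
  if (length(extra)) {
    stop("review result supplied for record(s) whose index field is present: ",
         paste(head(extra, 5L), collapse = ", "), call. = FALSE)
  }
  uncovered <- setdiff(ids[missing], names(review))
  if (length(uncovered)) {
    stop("missing review result for record(s): ",
         paste(head(uncovered, 5L), collapse = ", "), call. = FALSE)
  }
  cat <- ifelse(!missing, "no_missing_index",
                ifelse(review[ids], "missing_found", "missing_not_found"))
  setNames(cat, ids)
}

#' Omission prevalence and co-occurrence analysis
#'
#' For each record category (see [classify_records()]) and each probe
#' field, tabulates how many records are missing the probe field, the
#' percent missing with its exact binomial confidence interval, and — per
#' probe field — the two-sided Fisher p-value comparing the truly-missing
#' (`missing_not_found`) against the omission-error (`missing_found`)
#' category, with Hochberg-adjusted companions. Also reports, per category,
#' the rate at which *any* probe field is missing (omissions cluster within
#' records, so this composite exceeds every single-field rate).
#'
#' @inheritParams classify_records
#' @param probe_fields fields probed for co-occurring omissions.
#' @param alpha confidence level complement for the intervals.
#' @param digits decimals for the display-rounded percent columns (raw
#'   percents are retained).
#' @return An object of class `cooccurrence_table`: list with `table`
#'   (category x field tibble), `pvalues`, `any_missing`, `alpha`.
#' @export
cooccurrence_analysis <- function(records, index_field = "xrt_start",
                                  review_results,
                                  probe_fields = c("gender", "dob", "cancer_site"),
                                  alpha = 0.05, digits = 1) {
  categories <- classify_records(records, index_field, review_results)
  ids <- names(categories)
  miss <- vapply(probe_fields, function(f)
    vapply(records, field_is_missing, logical(1), field = f),
    logical(length(records)))
  miss <- matrix(miss, nrow = length(records),
                 dimnames = list(ids, probe_fields))

  cell <- function(x, n) {
    if (n == 0L) {
      return(tibble(missing = 0L, percent_raw = NA_real_, percent = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_))
    }
    pct <- 100 * x / n
    ci <- clopper_pearson_ci(x, n, alpha)
    tibble(missing = x, percent_raw = pct,
           percent = round_half_up(pct, digits),
           ci_low = round_half_up(ci[["low"]], digits),
           ci_high = round_half_up(ci[["high"]], digits))
  }

  tab <- dplyr::bind_rows(lapply(RECORD_CATEGORIES, function(cat) {
    in_cat <- categories == cat
    n <- sum(in_cat)
    dplyr::bind_rows(lapply(probe_fields, function(f) {
      dplyr::bind_cols(tibble(category = cat, n = n, field = f),
                       cell(sum(miss[in_cat, f]), n))
    }))
  }))

  pv <- vapply(probe_fields, function(f) {
    b <- categories == "missing_not_found"
    c_ <- categories == "missing_found"
    m <- matrix(c(sum(miss[b, f]), sum(b) - sum(miss[b, f]),
                  sum(miss[c_, f]), sum(c_) - sum(miss[c_, f])),
                2L, 2L, byrow = TRUE)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) NA_real_ else fisher_exact_2x2(m)
  }, numeric(1))
  p_adj <- rep(NA_real_, length(pv))
  ok <- !is.na(pv)
  if (any(ok)) p_adj[ok] <- hochberg_adjust(pv[ok])
  pvalues <- tibble(field = probe_fields, p = unname(pv), p_adj = p_adj)

  any_missing <- dplyr::bind_rows(lapply(RECORD_CATEGORIES, function(cat) {
    in_cat <- categories == cat
    n <- sum(in_cat)
    x <- if (n) sum(apply(miss[in_cat, , drop = FALSE], 1L, any)) else 0L
    dplyr::bind_cols(tibble(category = cat, n = n), cell(x, n))
  }))

  structure(list(table = tab, pvalues = pvalues, any_missing = any_missing,
                 alpha = alpha, index_field = index_field),
            class = "cooccurrence_table")
}

#' @export
print.cooccurrence_table <- function(x, ...) {
  cat("Omission co-occurrence by ", x$index_field, "-missingness category (",
      100 * (1 - x$alpha), "% exact CIs)\n", sep = "")
  print(x$table, n = Inf)
  cat("\nFisher p (missing_not_found vs missing_found):\n")
  print(x$pvalues)
  invisible(x)
}

# A before/after trace value is a missing state iff it is the empty string
# (unknown) or the not-applicable sentinel.
trace_value_state <- function(v) {
  ifelse(!nzchar(v), "unknown", ifelse(v == NA_SENTINEL, "not_applicable", "present"))
}

#' Summary-access effectiveness analysis
#'
#' Evaluates whether records whose summary page was accessed had omissions
#' in `target_field` corrected more often. A record counts as *accessed* if
#' at least one summary-access trace exists for it, and as *corrected* if a
#' field edit changed `target_field` from the *unknown* state to a present
#' value (overwrites of an already-present value are counted separately as
#' revisions). `window_attributed` counts the corrected-and-accessed
#' records whose earliest qualifying edit falls within `window_minutes`
#' after the latest preceding access.
#'
#' @param records list of [patient_record()] objects (defines the analysis
#'   population).
#' @param traces traces tibble (see [read_traces()]).
#' @param target_field the field whose omission corrections are the
#'   outcome.
#' @param window_minutes attribution window after an access (default 10).
#' @param alpha level for the exact binomial CIs.
#' @return An object of class `effectiveness_result`: 2x2 `contingency`
#'   (accessed x corrected), per-group `proportions` with CIs, `fisher_p`,
#'   `window_attributed`, `revisions`.
#' @export
effectiveness_analysis <- function(records, traces, target_field = "relapse_date",
                                   window_minutes = 10, alpha = 0.05) {
  stopifnot(window_minutes > 0)
  ids <- vapply(records, function(r) r$record_id, character(1))
  unknown_ids <- setdiff(unique(traces$record_id), ids)
  if (length(unknown_ids)) {
    stop("traces reference unknown record id(s): ",
         paste(head(unknown_ids, 5L), collapse = ", "), call. = FALSE)
  }
  accesses <- traces[traces$kind == "summary_access", , drop = FALSE]
  edits <- traces[traces$kind == "field_edit" & traces$field == target_field, , drop = FALSE]
  noop <- edits$before == edits$after
  if (any(noop)) {
    warning(sum(noop), " edit(s) with identical before and after values ignored")
    edits <- edits[!noop, , drop = FALSE]
  }
  qualifying <- trace_value_state(edits$before) == "unknown" &
    trace_value_state(edits$after) == "present"
  revisions <- sum(trace_value_state(edits$before) == "present" &
                     trace_value_state(edits$after) == "present")
  edits <- edits[qualifying, , drop = FALSE]

  accessed <- ids %in% accesses$record_id
  corrected <- ids %in% edits$record_id

  contingency <- matrix(
    c(sum(accessed & corrected), sum(accessed & !corrected),
      sum(!accessed & corrected), sum(!accessed & !corrected)),
    2L, 2L, byrow = TRUE,
    dimnames = list(accessed = c("yes", "no"), corrected = c("yes", "no"))
  )

  prop_row <- function(label, x, n) {
    if (n == 0L) {
      return(tibble(group = label, corrected = x, n = n, percent_raw = NA_real_,
                    percent = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
    }
    ci <- clopper_pearson_ci(x, n, alpha)
    pct <- 100 * x / n
    tibble(group = label, corrected = x, n = n, percent_raw = pct,
           percent = round_half_up(pct, 1),
           ci_low = round_half_up(ci[["low"]], 1),
           ci_high = round_half_up(ci[["high"]], 1))
  }
  proportions <- dplyr::bind_rows(
    prop_row("accessed", contingency["yes", "yes"], sum(accessed)),
    prop_row("not_accessed", contingency["no", "yes"], sum(!accessed))
  )

  fisher_p <- if (any(rowSums(contingency) == 0) || any(colSums(contingency) == 0)) {
    warning("zero margin in effectiveness contingency table; p = 1 by convention")
    1.0
  } else {
    fisher_exact_2x2(contingency)
  }

  window_attributed <- 0L
  for (rid in ids[accessed & corrected]) {
    e_times <- sort(edits$timestamp[edits$record_id == rid])
    a_times <- accesses$timestamp[accesses$record_id == rid]
    first_edit <- e_times[1L]
    prior <- a_times[a_times <= first_edit]
    if (!length(prior)) next
    latency <- as.numeric(difftime(first_edit, max(prior), units = "mins"))
    if (latency <= window_minutes) window_attributed <- window_attributed + 1L
  }

  structure(list(contingency = contingency, proportions = proportions,
                 fisher_p = fisher_p, window_attributed = window_attributed,
                 revisions = revisions, target_field = target_field,
                 window_minutes = window_minutes),
            class = "effectiveness_result")
}

#' @export
print.effectiveness_result <- function(x, ...) {
  cat("Effectiveness of summary access on correction of omitted '",
      x$target_field, "'\n", sep = "")
  print(x$contingency)
  print(x$proportions)
  cat("Fisher two-sided p = ", format(x$fisher_p, digits = 4),
      "; corrections within ", x$window_minutes, " min of an access: ",
      x$window_attributed, "\n", sep = "")
  invisible(x)
}

#' Summary-access utilization
#'
#' Tabulates how often the summary page was accessed: a per-record access
#' count histogram (0, 1, 2, 3+), the overall percent of records with at
#' least one access, the split between newly entered records and updates,
#' and per-user access rates (a user's workload being the records carrying
#' any trace by that user).
#'
#' @inheritParams effectiveness_analysis
#' @return An object of class `utilization_summary` with elements
#'   `histogram`, `overall`, `by_entry_type`, `per_user`.
#' @export
utilization_summary <- function(records, traces) {
  ids <- vapply(records, function(r) r$record_id, character(1))
  is_new <- vapply(records, function(r) r$is_new, logical(1))
  acc <- traces[traces$kind == "summary_access", , drop = FALSE]
  counts <- setNames(integer(length(ids)), ids)
  if (nrow(acc)) {
    t <- table(acc$record_id)
    common <- intersect(names(t), ids)
    counts[common] <- as.integer(t[common])
  }
  bucket <- cut(counts, breaks = c(-0.5, 0.5, 1.5, 2.5, Inf),
                labels = c("0", "1", "2", "3+"))
  histogram <- tibble(accesses = c("0", "1", "2", "3+"),
                      records = as.integer(table(bucket)))
  rate <- function(x, n) if (n == 0L) 0 else round_half_up(100 * x / n, 1)
  accessed <- counts > 0L
  n_accessed <- sum(accessed)
  overall <- tibble(n = length(ids), accessed = n_accessed,
                    rate_percent = rate(n_accessed, length(ids)))
  n_new <- sum(is_new); n_upd <- sum(!is_new)
  acc_new <- sum(accessed & is_new); acc_upd <- sum(accessed & !is_new)
  by_entry_type <- tibble(
    entry_type = c("new", "update"),
    n = c(n_new, n_upd),
    accessed = c(acc_new, acc_upd),
    rate_percent = c(rate(acc_new, n_new), rate(acc_upd, n_upd))
  )
  users <- sort(unique(traces$user_id))
  per_user <- dplyr::bind_rows(lapply(users, function(u) {
    n_work <- length(unique(traces$record_id[traces$user_id == u]))
    n_hits <- length(unique(acc$record_id[acc$user_id == u]))
    tibble(user_id = u, workload = n_work, accessed = n_hits,
           rate_percent = rate(n_hits, n_work))
  }))
  if (!length(users)) {
    per_user <- tibble(user_id = character(), workload = integer(),
                       accessed = integer(), rate_percent = numeric())
  }
  structure(list(histogram = histogram, overall = overall,
                 by_entry_type = by_entry_type, per_user = per_user),
            class = "utilization_summary")
}

#' @export
print.utilization_summary <- function(x, ...) {
  cat("Summary-access utilization: ", x$overall$accessed, "/", x$overall$n,
      " records (", x$overall$rate_percent, "%)\n", sep = "")
  print(x$histogram)
  print(x$by_entry_type)
  if (nrow(x$per_user)) print(x$per_user)
  invisible(x)
}
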