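#' Default key fields for the record summary
#'
#' The demographic and clinical fields listed verbatim in the first section
#' of the record summary, in display order.
#'
#' @return Character vector of field names.
#' @export
default_key_fields <- function() {
  c("record_id", "gender", "dob", "cancer_site", "diagnosis_date",
    "tumor_grade", "t_stage", "vital_status", "relapse_date")
}

SECTION_HEADERS <- c(
  key_fields = "== KEY FIELDS ==",
  timeline   = "== TIMELINE ==",
  errors     = "== POSSIBLE ERRORS =="
)

render_field_value <- function(record, field) {
  if (field == "record_id") return(record$record_id)
  if (field == "vital_status") return(record$vital_status)
  if (field == "remission_documented") return(as.character(record$remission_documented))
  if (field %in% RECORD_FV_FIELDS) return(format(record[[field]]))
  stop("unknown key field '", field, "'", call. = FALSE)
}

#' Render a timeline as monospace text
#'
#' One line per timeline entry (`YYYY-MM-DD  LABEL`) under a header line,
#' with each qualifying inter-event gap rendered as an interstitial
#' annotation line. An empty timeline renders a single placeholder line.
#'
#' @param timeline a [build_timeline()] result.
#' @param width line width, at least 40; longer lines are truncated.
#' @return Character vector of lines.
#' @export
render_timeline_text <- function(timeline, width = 80) {
  stopifnot(inherits(timeline, "timeline"), is.numeric(width), width >= 40)
  en <- timeline$entries
  if (!nrow(en)) return("(no events recorded)")
  lines <- "DATE        EVENT"
  gaps <- timeline$gaps
  for (i in seq_len(nrow(en))) {
    lines <- c(lines, substr(paste0(format(en$date[i], "%Y-%m-%d"), "  ", en$label[i]), 1L, width))
    if (i < nrow(en)) {
      g <- which(gaps$start == en$date[i] & gaps$end == en$date[i + 1L])
      if (length(g)) {
        lines <- c(lines, paste0("── gap: ", gaps$span_days[g[1L]], " days ──"))
      }
    }
  }
  lines
}

render_errors_text <- function(errors) {
  if (!nrow(errors)) return("(no possible errors)")
  vapply(seq_len(nrow(errors)), function(i) {
    paste0("[", errors$rule_id[i], "] ", errors$message[i],
           " {", paste(errors$implicated_fields[[i]], collapse = "; "), "}")
  }, character(1))
}

#' Render the three-section record summary
#'
#' Produces the read-only summary document for one record: a verbatim
#' listing of key fields (with explicit `UNKNOWN` / `N/A` missingness
#' markers), the clinical timeline with long inter-event gaps annotated,
#' and the list of possible errors flagged by the rule engine. All three
#' sections are always present; an empty section renders a placeholder
#' line. Output is deterministic: the same inputs give identical bytes.
#'
#' @param record a [patient_record()].
#' @param errors possible errors for this record (from [apply_rules()]);
#'   a firing for a different record id is a hard error.
#' @param format `"text"` or `"html"` (static, no scripting).
#' @param key_field_spec ordered field names for the first section.
#' @param gap_threshold_days gap threshold passed to [build_timeline()].
#' @param width text line width (minimum 40).
#' @return A single string: the serialized document.
#' @export
render_summary <- function(record, errors = empty_errors(),
                           format = c("text", "html"),
                           key_field_spec = default_key_fields(),
                           gap_threshold_days = 365, width = 80) {
  format <- match.arg(format)
  stopifnot(inherits(record, "patient_record"))
  if (nrow(errors) && any(errors$record_id != record$record_id)) {
    stop("possible errors refer to a different record than the one being rendered",
         call. = FALSE)
  }
  kf <- vapply(key_field_spec, function(f)
    paste0(f, ": ", render_field_value(record, f)), character(1))
  if (!length(kf)) kf <- "(no key fields configured)"
  tl <- render_timeline_text(build_timeline(record, gap_threshold_days), width)
  er <- render_errors_text(errors)
  if (format == "text") {
    paste(c(SECTION_HEADERS[["key_fields"]], kf, "",
            SECTION_HEADERS[["timeline"]], tl, "",
            SECTION_HEADERS[["errors"]], er, ""),
          collapse = "\n")
  } else {
    render_summary_html(record$record_id, kf, tl, er)
  }
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

render_summary_html <- function(record_id, key_lines, timeline_lines, error_lines) {
  section <- function(id, title, lines) {
    paste0("<section id=\"", id, "\">\n<h2>", title, "</h2>\n<pre>\n",
           paste(html_escape(lines), collapse = "\n"), "\n</pre>\n</section>")
  }
  paste0(
    "<!DOCTYPE html>\n<html>\n<head>\n<meta charset=\"utf-8\"/>\n<title>Record summary ",
    html_escape(record_id), "</title>\n</head>\n<body>\n",
    "<h1>Record summary: ", html_escape(record_id), "</h1>\n",
    section("key-fields", "Key fields", key_lines), "\n",
    section("timeline", "Timeline", timeline_lines), "\n",
    section("possible-errors", "Possible errors", error_lines),
    "\n</body>\n</html>\n"
  )
}
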