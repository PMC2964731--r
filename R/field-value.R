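#' Three-valued field semantics
#'
#' Registry fields distinguish a recorded value from two kinds of
#' missingness: *unknown* (the value exists or may exist but was not
#' recorded — the state an omission error produces) and *not applicable*
#' (the concept does not apply to this patient, e.g. a relapse date for a
#' patient whose cancer never relapsed). Collapsing the two onto a single
#' NULL is a known source of interpretation errors in clinical registries,
#' so the model keeps them apart end to end: in memory, on disk, and in
#' rendered output.
#'
#' @param value the payload (a `Date`, character code, number or text);
#'   required when `state = "present"` and forbidden otherwise.
#' @param state one of `"present"`, `"unknown"`, `"not_applicable"`.
#' @return An object of class `field_value`.
#' @examples
#' fv_present(as.Date("2008-07-04"))
#' fv_unknown()
#' fv_na()
#' @export
field_value <- function(value = NULL, state = c("present", "unknown", "not_applicable")) {
  state <- match.arg(state)
  if (state == "present") {
    if (is.null(value) || length(value) != 1L || is.na(value)) {
      stop("a present field_value requires a non-missing scalar value", call. = FALSE)
    }
  } else if (!is.null(value)) {
    stop("value must be NULL unless state is 'present'", call. = FALSE)
  }
  structure(list(state = state, value = value), class = "field_value")
}

#' @rdname field_value
#' @export
fv_present <- function(value) field_value(value, "present")

#' @rdname field_value
#' @export
fv_unknown <- function() field_value(NULL, "unknown")

#' @rdname field_value
#' @export
fv_na <- function() field_value(NULL, "not_applicable")

#' Query a field_value
#'
#' @param x a [field_value].
#' @return `fv_state()` returns the state string; `fv_value()` the payload
#'   (`NULL` unless present); `fv_is_present()` a logical.
#' @export
fv_state <- function(x) {
  stopifnot(inherits(x, "field_value"))
  x$state
}

#' @rdname fv_state
#' @export
fv_value <- function(x) {
  stopifnot(inherits(x, "field_value"))
  x$value
}

#' @rdname fv_state
#' @export
fv_is_present <- function(x) fv_state(x) == "present"

#' @export
format.field_value <- function(x, ...) {
  switch(x$state,
    present        = fv_canonical(x),
    unknown        = "UNKNOWN",
    not_applicable = "N/A"
  )
}

#' @export
print.field_value <- function(x, ...) {
  cat("<field_value> ", format(x), "\n", sep = "")
  invisible(x)
}

# Sentinel used on disk for not_applicable; an empty cell means unknown.
NA_SENTINEL <- "NA!"

# Canonical string for a present value (ISO dates, plain text otherwise).
fv_canonical <- function(x) {
  v <- x$value
  if (inherits(v, "Date")) format(v, "%Y-%m-%d") else as.character(v)
}

# Disk encoding of any field_value (CSV cell / JSON scalar).
fv_encode <- function(x) {
  switch(fv_state(x), present = fv_canonical(x), unknown = "", not_applicable = NA_SENTINEL)
}

# Inverse of fv_encode. `type` controls payload parsing for present cells.
fv_decode <- function(cell, type = c("text", "date")) {
  type <- match.arg(type)
  if (is.null(cell) || length(cell) == 0L || is.na(cell) || !nzchar(cell)) {
    return(fv_unknown())
  }
  if (identical(cell, NA_SENTINEL)) {
    return(fv_na())
  }
  if (type == "date") fv_present(parse_iso_date(cell)) else fv_present(cell)
}

# Strict ISO-8601 day parsing; stops on malformed input.
parse_iso_date <- function(x) {
  if (!grepl("^\\d{4}-\\d{2}-\\d{2}$", x)) {
    stop("invalid date '", x, "' (expected YYYY-MM-DD)", call. = FALSE)
  }
  d <- as.Date(x, format = "%Y-%m-%d")
  if (is.na(d)) stop("invalid calendar date '", x, "'", call. = FALSE)
  d
}
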