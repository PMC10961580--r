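#' Read a registry event table from CSV
#'
#' Parses a registry export with one row per operation into a clean event
#' table of (provider, unit, date) triples. Rows with a missing provider or
#' unit, or an unparseable date, are dropped; the drop counts are recorded in
#' the table's audit attribute so that event conservation can be checked
#' downstream.
#'
#' @param path path to a CSV file.
#' @param column_map named character vector mapping the roles `provider`,
#'   `unit` and `date` to column names in the file. Defaults match a common
#'   registry export: consultant in charge, unit, procedure completed date.
#' @param date_format `"iso"` (`YYYY-MM-DD`, the default) or `"dayfirst"`
#'   (`DD/MM/YYYY`), for registries exporting UK-style dates.
#' @return a tibble of class `case_event_table` with columns `provider_id`,
#'   `unit_id`, `event_date`, carrying an `audit` attribute (see
#'   [event_audit()]).
#' @seealso [filter_window()], [monthly_caseloads()]
#' @export
parse_registry <- function(path,
                           column_map = c(
                             provider = "consultant_in_charge",
                             unit = "unit",
                             date = "procedure_completed_date"
                           ),
                           date_format = c("iso", "dayfirst")) {
  date_format <- match.arg(date_format)
  if (!file.exists(path)) {
    stop("registry file not found: ", path, call. = FALSE)
  }
  needed <- c("provider", "unit", "date")
  if (!all(needed %in% names(column_map))) {
    stop("column_map must name 'provider', 'unit' and 'date'", call. = FALSE)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  missing_cols <- setdiff(unname(column_map[needed]), names(raw))
  if (length(missing_cols) > 0) {
    stop("mapped column(s) absent from file: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n_raw <- nrow(raw)
  provider <- trimws(raw[[column_map[["provider"]]]])
  unit <- trimws(raw[[column_map[["unit"]]]])
  date_str <- trimws(raw[[column_map[["date"]]]])

  fmt <- if (date_format == "iso") "%Y-%m-%d" else "%d/%m/%Y"
  event_date <- as.Date(date_str, format = fmt)

  missing_field <- is.na(provider) | provider == "" | is.na(unit) | unit == ""
  bad_date <- !missing_field & (is.na(date_str) | date_str == "" | is.na(event_date))
  keep <- !missing_field & !bad_date

  events <- tibble::tibble(
    provider_id = provider[keep],
    unit_id = unit[keep],
    event_date = event_date[keep]
  )
  new_case_event_table(events, audit = list(
    n_raw = n_raw,
    n_dropped_missing_field = sum(missing_field),
    n_dropped_bad_date = sum(bad_date),
    n_kept = sum(keep)
  ))
}

new_case_event_table <- function(df, audit = list()) {
  out <- tibble::as_tibble(df)
  class(out) <- c("case_event_table", class(out))
  attr(out, "audit") <- audit
  out
}

#' Construct an event table directly from vectors
#'
#' Convenience constructor used by the synthetic generator and in tests;
#' performs the same validity checks as [parse_registry()] but takes already
#' typed columns.
#'
#' @param provider_id,unit_id character vectors of identifiers.
#' @param event_date a `Date` vector.
#' @return a `case_event_table` tibble.
#' @export
case_event_table <- function(provider_id, unit_id, event_date) {
  stopifnot(inherits(event_date, "Date"))
  df <- tibble::tibble(
    provider_id = as.character(provider_id),
    unit_id = as.character(unit_id),
    event_date = event_date
  )
  bad <- is.na(df$provider_id) | df$provider_id == "" |
    is.na(df$unit_id) | df$unit_id == "" | is.na(df$event_date)
  if (any(bad)) stop("invalid events: missing identifier or date", call. = FALSE)
  new_case_event_table(df, audit = list(
    n_raw = nrow(df), n_dropped_missing_field = 0L,
    n_dropped_bad_date = 0L, n_kept = nrow(df)
  ))
}

#' Retrieve the audit record of an event table or caseload matrix
#'
#' The audit record tracks every row excluded at each stage (unparseable
#' rows at ingest, out-of-window or inactive-provider events at aggregation)
#' so that total event counts are conserved end to end.
#'
#' @param x a `case_event_table` or `caseload_matrix`.
#' @return a named list of counts.
#' @export
event_audit <- function(x) {
  attr(x, "audit")
}

#' Define a study window
#'
#' An inclusive date interval; events outside it are excluded from analysis.
#'
#' @param start,end `Date`s or strings coercible by `as.Date()`.
#' @return a `study_window` object.
#' @examples
#' study_window("2016-05-01", "2021-02-27")
#' @export
study_window <- function(start, end) {
  start <- as.Date(start)
  end <- as.Date(end)
  if (is.na(start) || is.na(end)) stop("invalid window date", call. = FALSE)
  if (start > end) stop("window start is after end", call. = FALSE)
  structure(list(start = start, end = end), class = "study_window")
}

#' Define an activity rule for providers
#'
#' A provider counts as active when it has at least `min_events` events dated
#' on or after `activity_cutoff`. Registries usually carry no roster of who
#' is in practice; this rule lets zero-operation months be counted for
#' providers known to be active.
#'
#' @param activity_cutoff a `Date` or string.
#' @param min_events minimum number of qualifying events (default 1).
#' @return an `activity_rule` object.
#' @examples
#' activity_rule("2019-04-01")
#' @export
activity_rule <- function(activity_cutoff, min_events = 1L) {
  activity_cutoff <- as.Date(activity_cutoff)
  if (is.na(activity_cutoff)) stop("invalid cutoff date", call. = FALSE)
  min_events <- as.integer(min_events)
  if (min_events < 1L) stop("min_events must be >= 1", call. = FALSE)
  structure(list(activity_cutoff = activity_cutoff, min_events = min_events),
            class = "activity_rule")
}

#' Restrict an event table to a study window
#'
#' @param events a `case_event_table`.
#' @param window a [study_window()].
#' @return the events with `start <= event_date <= end`, original order
#'   preserved; the audit records how many fell outside.
#' @export
filter_window <- function(events, window) {
  stopifnot(inherits(window, "study_window"))
  keep <- events$event_date >= window$start & events$event_date <= window$end
  audit <- attr(events, "audit")
  audit$n_outside_window <- sum(!keep)
  new_case_event_table(events[keep, , drop = FALSE], audit = audit)
}

#' Identify active providers
#'
#' @param events a `case_event_table`.
#' @param rule an [activity_rule()].
#' @return character vector of provider ids with at least `min_events`
#'   events on/after the cutoff, sorted.
#' @export
active_providers <- function(events, rule) {
  stopifnot(inherits(rule, "activity_rule"))
  recent <- events$provider_id[events$event_date >= rule$activity_cutoff]
  tab <- table(recent)
  sort(names(tab)[tab >= rule$min_events])
}

#' Build a month-by-entity caseload matrix
#'
#' Aggregates events into a months x entities count matrix covering every
#' calendar month intersecting the window, with explicit zeros for active
#' entities that performed no operations in a month. This matrix is the basis
#' of every downstream statistic: frequency tables, concentration curves,
#' and volume bands.
#'
#' @param events a `case_event_table` (already window-filtered or not; events
#'   outside `window` are excluded here and audited).
#' @param actives character vector of active entity ids (required for
#'   `entity_kind = "provider"`). For units, defaults to all units observed.
#' @param window a [study_window()]; its calendar months define the rows.
#' @param entity_kind `"provider"` or `"unit"` — which identifier column to
#'   aggregate over. The same machinery serves both analyses.
#' @return a `caseload_matrix`: an integer matrix with `"YYYY-MM"` rownames
#'   and entity-id colnames, plus attributes `entity_kind` and `audit`
#'   (counts of events excluded as out-of-window or by inactive entities).
#' @export
monthly_caseloads <- function(events, actives = NULL, window,
                              entity_kind = c("provider", "unit")) {
  entity_kind <- match.arg(entity_kind)
  stopifnot(inherits(window, "study_window"))
  id <- if (entity_kind == "provider") events$provider_id else events$unit_id
  if (is.null(actives)) {
    if (entity_kind == "provider") {
      stop("`actives` must be supplied for provider-level matrices", call. = FALSE)
    }
    actives <- sort(unique(id))
  }
  if (entity_kind == "provider" && length(actives) == 0) {
    stop("`actives` is empty", call. = FALSE)
  }
  in_window <- events$event_date >= window$start & events$event_date <= window$end
  months <- month_seq(window$start, window$end)
  id_w <- id[in_window]
  is_active <- id_w %in% actives
  mk <- month_key(events$event_date[in_window][is_active])
  counts <- table(
    factor(mk, levels = months),
    factor(id_w[is_active], levels = actives)
  )
  mat <- matrix(as.integer(counts), nrow = length(months),
                dimnames = list(months, actives))
  structure(mat,
            class = c("caseload_matrix", "matrix", "array"),
            entity_kind = entity_kind,
            audit = list(
              n_events_in = nrow(events),
              n_outside_window = sum(!in_window),
              n_excluded_inactive = sum(!is_active),
              n_counted = sum(is_active)
            ))
}

#' @export
print.caseload_matrix <- function(x, ...) {
  cat(sprintf("<caseload_matrix: %d months x %d %ss, %d operations>\n",
              nrow(x), ncol(x), attr(x, "entity_kind"), sum(x)))
  invisible(x)
}

#' Tidy a caseload matrix
#'
#' @param matrix a `caseload_matrix`.
#' @return tibble with columns `year`, `month`, `entity_id`, `count` — the
#'   serialization format for caseload matrices.
#' @export
caseload_long <- function(matrix) {
  stopifnot(inherits(matrix, "caseload_matrix"))
  keys <- rep(rownames(matrix), times = ncol(matrix))
  dplyr::bind_cols(
    month_parts(keys),
    tibble::tibble(
      entity_id = rep(colnames(matrix), each = nrow(matrix)),
      count = as.integer(matrix)
    )
  )
}

#' Summarize a registry
#'
#' Headline descriptive statistics: total events, monthly event volumes,
#' distinct providers/units, monthly operating-provider counts (entities with
#' at least one operation in the month) and multi-unit working. Quartiles use
#' linear interpolation (type 7), so IQR bounds may be fractional.
#'
#' @param matrix a provider-level `caseload_matrix`.
#' @param events the `case_event_table` the matrix was built from (used for
#'   event totals and unit-level facts).
#' @return a list of class `registry_summary`.
#' @export
registry_summary <- function(matrix, events) {
  stopifnot(inherits(matrix, "caseload_matrix"))
  monthly_events <- as.numeric(table(factor(month_key(events$event_date),
                                            levels = rownames(matrix))))
  operating <- rowSums(matrix >= 1)
  units_per_provider <- tapply(events$unit_id, events$provider_id,
                               function(u) length(unique(u)))
  q_ev <- stats::quantile(monthly_events, c(.25, .5, .75), type = 7, names = FALSE)
  q_op <- stats::quantile(operating, c(.25, .5, .75), type = 7, names = FALSE)
  structure(list(
    total_events = nrow(events),
    monthly_event_median = q_ev[2],
    monthly_event_iqr = c(q_ev[1], q_ev[3]),
    distinct_providers = length(unique(events$provider_id)),
    distinct_units = length(unique(events$unit_id)),
    monthly_provider_median = q_op[2],
    monthly_provider_iqr = c(q_op[1], q_op[3]),
    multi_unit_provider_count = sum(units_per_provider >= 2),
    max_units_per_provider = if (length(units_per_provider)) max(units_per_provider) else 0L,
    n_active_providers = ncol(matrix)
  ), class = "registry_summary")
}

#' @export
print.registry_summary <- function(x, ...) {
  cat(sprintf(
    paste0("Registry summary\n",
           "  operations: %d (monthly median %.1f, IQR %.1f-%.1f)\n",
           "  providers: %d distinct, %d active (monthly operating median %.1f, IQR %.1f-%.1f)\n",
           "  units: %d distinct; %d providers at 2+ units (max %d)\n"),
    x$total_events, x$monthly_event_median, x$monthly_event_iqr[1], x$monthly_event_iqr[2],
    x$distinct_providers, x$n_active_providers, x$monthly_provider_median,
    x$monthly_provider_iqr[1], x$monthly_provider_iqr[2],
    x$distinct_units, x$multi_unit_provider_count, x$max_units_per_provider))
  invisible(x)
}
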