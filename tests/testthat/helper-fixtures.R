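# Small in-code fixtures shared across test files.

# Write a registry CSV with the default column names; rows is a data frame
# with columns unit, consultant_in_charge, procedure_completed_date.
write_registry_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  readr::write_csv(rows, path, na = "")
  path
}

registry_rows <- function(provider, unit, date) {
  tibble::tibble(
    unit = unit,
    consultant_in_charge = provider,
    procedure_completed_date = date
  )
}

# A tiny caseload matrix built through the public API.
toy_matrix <- function(counts, months, providers) {
  events <- list()
  for (i in seq_along(months)) {
    for (j in seq_along(providers)) {
      n <- counts[i, j]
      if (n > 0) {
        events[[length(events) + 1]] <- tibble::tibble(
          provider_id = providers[j], unit_id = "U1",
          event_date = rep(month_first(months[i]), n)
        )
      }
    }
  }
  if (length(events) == 0) {
    return(structure(
      matrix(0L, length(months), length(providers),
             dimnames = list(months, providers)),
      class = c("caseload_matrix", "matrix", "array"),
      entity_kind = "provider", audit = list()))
  }
  df <- dplyr::bind_rows(events)
  ev <- case_event_table(df$provider_id, df$unit_id, df$event_date)
  w <- study_window(month_first(months[1]), month_last(months[length(months)]))
  monthly_caseloads(ev, providers, w, "provider")
}

month_first <- function(key) as.Date(paste0(key, "-01"))
month_last <- function(key) {
  month_first(key) + month_days(key) - 1
}

# Dense log-spaced grid search over (a, b): the independent least-squares
# oracle for curve fits.
grid_oracle <- function(x, y, family, a_range, b_range, n_grid = 200) {
  a_grid <- exp(seq(log(a_range[1]), log(a_range[2]), length.out = n_grid))
  b_grid <- exp(seq(log(b_range[1]), log(b_range[2]), length.out = n_grid))
  best <- list(rss = Inf)
  for (a in a_grid) {
    for (b in b_grid) {
      mu <- if (family == "power") a * x^(-b) else a * exp(-b * x)
      rss <- sum((y - mu)^2)
      if (rss < best$rss) best <- list(a = a, b = b, rss = rss)
    }
  }
  best
}

# Exhaustive minimal-cardinality subset covering a share of the total:
# brute-force oracle for the greedy top-k rule.
brute_force_min_k <- function(volumes, q) {
  total <- sum(volumes)
  n <- length(volumes)
  for (k in 1:n) {
    combos <- utils::combn(n, k)
    sums <- colSums(matrix(volumes[combos], nrow = k))
    if (any(sums >= q * total - 1e-9)) return(k)
  }
  n
}
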