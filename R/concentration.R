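#' Build a concentration curve from entity volumes
#'
#' Sorts volumes in descending order and computes the cumulative share of
#' total operations covered by the top-k entities, the basis of the Pareto
#' fraction and generalized Price root. The denominator N is either the
#' entities that actually operated in the period (`"operating_only"`, the
#' default) or all active entities including those with zero volume
#' (`"all_active"`); zero-volume entities never contribute share.
#'
#' @param volumes non-negative entity volumes, optionally named by entity id.
#' @param denominator_rule `"operating_only"` or `"all_active"`.
#' @return a `concentration_curve` list: `sorted_volumes`, `cum_share`
#'   (length N, final value 1), `N`, `T`, `denominator_rule`, `month`.
#' @param month optional `"YYYY-MM"` label carried through to statistics.
#' @export
build_concentration_curve <- function(volumes,
                                      denominator_rule = c("operating_only", "all_active"),
                                      month = NA_character_) {
  denominator_rule <- match.arg(denominator_rule)
  stopifnot(all(volumes >= 0))
  if (all(volumes == 0)) stop("no operations in period", call. = FALSE)
  ids <- names(volumes)
  if (is.null(ids)) ids <- as.character(seq_along(volumes))
  # stable: volume descending, id ascending — byte-reproducible under ties
  ord <- order(-volumes, ids)
  v <- as.numeric(volumes[ord])
  ids <- ids[ord]
  if (denominator_rule == "operating_only") {
    keep <- v > 0
    v <- v[keep]
    ids <- ids[keep]
  }
  total <- sum(v)
  structure(list(
    sorted_volumes = v,
    entity_ids = ids,
    cum_share = cumsum(v) / total,
    N = length(v),
    T = total,
    denominator_rule = denominator_rule,
    month = month
  ), class = "concentration_curve")
}

#' @export
print.concentration_curve <- function(x, ...) {
  cat(sprintf("<concentration_curve: N = %d, T = %g (%s)>\n",
              x$N, x$T, x$denominator_rule))
  invisible(x)
}

# Fractional top-k covering share q: smallest k with cum_share[k] >= q,
# linearly interpolated within the k-th entity when requested.
top_k_for_share <- function(curve, q, interpolate) {
  cs <- curve$cum_share
  k <- which(cs >= q - 1e-12)[1]
  if (is.na(k)) k <- length(cs)
  if (!interpolate) return(as.numeric(k))
  prev <- if (k == 1) 0 else cs[k - 1]
  step <- cs[k] - prev
  if (step <= 0) return(as.numeric(k))
  (k - 1) + (q - prev) / step
}

#' Pareto fraction: minimal share of top entities covering share q
#'
#' Computes k_q, the (possibly fractional) number of top-ranked entities
#' whose cumulative share of operations first reaches q, and the Pareto
#' fraction k_q / N. Under the classic Pareto principle, the fraction at
#' q = 0.8 is 0.2 ("80% of work is done by 20% of people"); larger fractions
#' mean volumes are more evenly spread.
#'
#' @param curve a [build_concentration_curve()] result.
#' @param q target share of operations, in (0, 1].
#' @param interpolate interpolate k_q linearly within the marginal entity
#'   (default `TRUE`; integer k otherwise).
#' @return a `concentration_stat` list: `q`, `k_q`, `fraction_q`, `N`, `T`,
#'   `month`.
#' @examples
#' cc <- build_concentration_curve(c(5, 3, 2))
#' pareto_fraction(cc, 0.65)$fraction_q # 0.5
#' @export
pareto_fraction <- function(curve, q, interpolate = TRUE) {
  stopifnot(inherits(curve, "concentration_curve"))
  if (!(q > 0 && q <= 1)) stop("q must lie in (0, 1]", call. = FALSE)
  k_q <- top_k_for_share(curve, q, interpolate)
  structure(list(
    q = q, k_q = k_q, fraction_q = k_q / curve$N,
    N = curve$N, T = curve$T, month = curve$month
  ), class = "concentration_stat")
}

#' Generalized Price root exponent
#'
#' Price's law asserts that half of total output is produced by the square
#' root of the number of contributors. This generalizes the claim to the
#' root exponent n solving k_{0.5} = N^(1/n), i.e. n = ln(N) / ln(k_{0.5}),
#' where k_{0.5} is the (fractional) number of top entities covering half the
#' operations. n = 2 recovers Price's law; smaller n means output is less
#' concentrated.
#'
#' @inheritParams pareto_fraction
#' @return a `concentration_stat` list with fields `q = 0.5`, `k_q`,
#'   `fraction_q`, `price_root`, `N`, `T`, `month`.
#' @examples
#' cc <- build_concentration_curve(c(6, 4, 3, 2, 1))
#' price_root(cc)$price_root # log(5)/log(1.5)
#' @export
price_root <- function(curve, interpolate = TRUE) {
  stopifnot(inherits(curve, "concentration_curve"))
  if (curve$N < 2) stop("price root requires N >= 2", call. = FALSE)
  k <- top_k_for_share(curve, 0.5, interpolate)
  if (k <= 1) stop("root undefined: dominant single entity", call. = FALSE)
  structure(list(
    q = 0.5, k_q = k, fraction_q = k / curve$N,
    price_root = log(curve$N) / log(k),
    N = curve$N, T = curve$T, month = curve$month
  ), class = "concentration_stat")
}

#' @export
print.concentration_stat <- function(x, ...) {
  cat(sprintf("<concentration_stat q = %.2f: k_q = %.3f of N = %d (fraction %.4f)%s>\n",
              x$q, x$k_q, x$N, x$fraction_q,
              if (!is.null(x$price_root)) sprintf(", price root %.3f", x$price_root) else ""))
  invisible(x)
}

#' Monthly concentration statistics across a caseload matrix
#'
#' Applies [pareto_fraction()] (for each q in `q_list`) and [price_root()]
#' month by month. Months with no operations, or where the root is undefined,
#' are skipped with a notice.
#'
#' @param matrix a `caseload_matrix`.
#' @param q_list target shares (default `c(0.5, 0.8)`).
#' @param denominator_rule,interpolate passed through.
#' @return tibble with columns `year`, `month`, `statistic`
#'   (`"fraction_q"` or `"price_root"`), `q`, `value`, `N`, `T`; attribute
#'   `skipped_months` lists any months skipped and why.
#' @export
monthly_concentration_series <- function(matrix, q_list = c(0.5, 0.8),
                                         denominator_rule = "operating_only",
                                         interpolate = TRUE) {
  stopifnot(inherits(matrix, "caseload_matrix"), nrow(matrix) >= 1)
  skipped <- character(0)
  rows <- list()
  for (m in rownames(matrix)) {
    vols <- matrix[m, ]
    if (all(vols == 0)) {
      skipped <- c(skipped, paste0(m, ": no operations"))
      next
    }
    cc <- build_concentration_curve(vols, denominator_rule, month = m)
    for (q in q_list) {
      st <- pareto_fraction(cc, q, interpolate)
      rows[[length(rows) + 1]] <- tibble::tibble(
        key = m, statistic = "fraction_q", q = q,
        value = st$fraction_q, N = st$N, T = st$T)
    }
    pr <- tryCatch(price_root(cc, interpolate), error = function(e) NULL)
    if (is.null(pr)) {
      skipped <- c(skipped, paste0(m, ": price root undefined"))
    } else {
      rows[[length(rows) + 1]] <- tibble::tibble(
        key = m, statistic = "price_root", q = 0.5,
        value = pr$price_root, N = pr$N, T = pr$T)
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::bind_cols(month_parts(out$key), out[setdiff(names(out), "key")])
  attr(out, "skipped_months") <- skipped
  out
}

#' Summarize a monthly statistic series
#'
#' Arithmetic mean of the monthly values with a 95% t-interval
#' (`mean +/- t_{0.975, m-1} * sd / sqrt(m)` over the m months).
#'
#' @param values numeric vector of monthly values (length >= 2).
#' @param name statistic name carried into the result.
#' @param level confidence level (default 0.95).
#' @return a `series_summary` list: `statistic`, `values`, `mean`, `ci_low`,
#'   `ci_high`, `n`.
#' @export
summarize_series <- function(values, name = "statistic", level = 0.95) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("CI undefined", call. = FALSE)
  m <- length(values)
  mu <- mean(values)
  half <- stats::qt(1 - (1 - level) / 2, df = m - 1) * stats::sd(values) / sqrt(m)
  structure(list(statistic = name, values = values, mean = mu,
                 ci_low = mu - half, ci_high = mu + half, n = m),
            class = "series_summary")
}

#' @export
print.series_summary <- function(x, ...) {
  cat(sprintf("%s: mean %.4g (95%% CI %.4g to %.4g) over %d months\n",
              x$statistic, x$mean, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Monthly extremes of entity caseloads
#'
#' Per month, the median, 75th centile and maximum of entity caseloads
#' (over operating entities by default, so zero-volume actives do not drag
#' the quantiles), each then summarized across months with a t-interval.
#' Reproduces the headline "monthly medians / upper quartiles / maximums"
#' descriptives of workforce volume spread.
#'
#' @param matrix a `caseload_matrix`.
#' @param operating_only drop zero-count entities within each month first.
#' @return list with `monthly` (tibble: year, month, median, p75, max) and
#'   `summary` (named list of [summarize_series()] results).
#' @export
monthly_extremes <- function(matrix, operating_only = TRUE) {
  stopifnot(inherits(matrix, "caseload_matrix"), nrow(matrix) >= 1)
  rows <- lapply(rownames(matrix), function(m) {
    v <- matrix[m, ]
    if (operating_only) v <- v[v >= 1]
    if (length(v) == 0) return(NULL)
    tibble::tibble(key = m,
                   median = stats::quantile(v, 0.5, type = 7, names = FALSE),
                   p75 = stats::quantile(v, 0.75, type = 7, names = FALSE),
                   max = max(v))
  })
  monthly <- dplyr::bind_rows(rows)
  monthly <- dplyr::bind_cols(month_parts(monthly$key),
                              monthly[setdiff(names(monthly), "key")])
  list(
    monthly = monthly,
    summary = list(
      median = summarize_series(monthly$median, "monthly_median"),
      p75 = summarize_series(monthly$p75, "monthly_p75"),
      max = summarize_series(monthly$max, "monthly_max")
    )
  )
}
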