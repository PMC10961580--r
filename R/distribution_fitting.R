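#' Build a caseload frequency table for one month
#'
#' Tabulates, for one month of a caseload matrix, how many entities (Y)
#' performed each caseload (X), including the X = 0 bin. This is the object
#' that Lotka-type inverse-power and exponential-decay curves are fitted to.
#'
#' @param matrix a `caseload_matrix`.
#' @param month a `"YYYY-MM"` key present in the matrix.
#' @return a tibble of class `frequency_table` with columns `x` (caseload)
#'   and `y` (number of entities), sorted by `x`, carrying a `month`
#'   attribute. `sum(y)` always equals the number of entities in the matrix.
#' @export
build_frequency_table <- function(matrix, month) {
  stopifnot(inherits(matrix, "caseload_matrix"))
  if (!month %in% rownames(matrix)) {
    stop("month not in matrix: ", month, call. = FALSE)
  }
  counts <- matrix[month, ]
  tab <- table(counts)
  out <- tibble::tibble(
    x = as.integer(names(tab)),
    y = as.integer(tab)
  )
  structure(out, class = c("frequency_table", class(out)), month = month)
}

#' Construct a frequency table from explicit (x, y) pairs
#'
#' @param x distinct non-negative caseload values.
#' @param y positive entity counts, same length as `x`.
#' @param month optional `"YYYY-MM"` label.
#' @return a `frequency_table` tibble.
#' @export
frequency_table <- function(x, y, month = NA_character_) {
  stopifnot(length(x) == length(y), !anyDuplicated(x), all(x >= 0), all(y > 0))
  ord <- order(x)
  out <- tibble::tibble(x = as.numeric(x)[ord], y = as.numeric(y)[ord])
  structure(out, class = c("frequency_table", class(out)), month = month)
}

# Points actually entering a fit, after zero-handling.
fit_points <- function(freq, family, include_zero) {
  if (family == "power" && include_zero) {
    stop("power law undefined at X = 0", call. = FALSE)
  }
  pts <- tibble::tibble(x = as.numeric(freq$x), y = as.numeric(freq$y))
  if (!include_zero) pts <- pts[pts$x >= 1, , drop = FALSE]
  pts
}

#' Fit a decay curve to a frequency table
#'
#' Fits either an inverse-power curve `Y = a * X^(-b)` (Lotka's law family)
#' or an exponential decay `Y = a * exp(-b * X)` by nonlinear least squares
#' on the raw Y scale, seeded from the log-linearized OLS estimate. Both
#' families are fitted on X >= 1 by default; the X = 0 bin (providers with no
#' operations that month) is reported alongside, never silently discarded,
#' and `include_zero = TRUE` is rejected for the power family since the model
#' is undefined there.
#'
#' The AIC uses the Gaussian profile-likelihood convention
#' `n * log(rss / n) + 2 * (p + 1)` with p = 2 curve parameters plus one for
#' the error variance, which makes AICs comparable across families fitted to
#' identical points on the same scale.
#'
#' @param freq a `frequency_table`.
#' @param family `"exponential"` or `"power"`.
#' @param include_zero include the X = 0 bin in the fitted points
#'   (exponential only).
#' @param weights `"none"` (default, unweighted least squares) or
#'   `"poisson"` (weights 1/max(Y,1), for count-type heteroscedasticity).
#' @return a `curve_fit` list: `family`, `a`, `b`, their standard errors,
#'   `rss`, `n_obs`, `n_params`, `loglik`, `aic`, `zero_bin` (the Y at X = 0,
#'   or 0), and `month`.
#' @export
fit_curve <- function(freq, family = c("exponential", "power"),
                      include_zero = FALSE, weights = c("none", "poisson")) {
  family <- match.arg(family)
  weights <- match.arg(weights)
  pts <- fit_points(freq, family, include_zero)
  if (nrow(pts) < 3) stop("insufficient support", call. = FALSE)

  # log-linearized seed: ln Y ~ ln X (power) or ln Y ~ X (exponential)
  lx <- if (family == "power") log(pts$x) else pts$x
  ols <- stats::lm.fit(cbind(1, lx), log(pts$y))
  a0 <- exp(ols$coefficients[[1]])
  b0 <- -ols$coefficients[[2]]
  w <- if (weights == "poisson") 1 / pmax(pts$y, 1) else rep(1, nrow(pts))
  form <- if (family == "power") y ~ a * x^(-b) else y ~ a * exp(-b * x)

  est <- tryCatch({
    fit <- minpack.lm::nlsLM(form, data = pts,
                             start = list(a = a0, b = b0), weights = w,
                             control = minpack.lm::nls.lm.control(maxiter = 500))
    se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                   error = function(e) c(NA_real_, NA_real_))
    list(a = stats::coef(fit)[["a"]], b = stats::coef(fit)[["b"]],
         se_a = se[[1]], se_b = se[[2]])
  }, error = function(e) {
    # Degenerate tables can defeat the Levenberg-Marquardt path; refine the
    # log-linear seed by direct objective minimization instead.
    obj <- function(p) {
      mu <- if (family == "power") exp(p[1]) * pts$x^(-p[2]) else exp(p[1]) * exp(-p[2] * pts$x)
      sum(w * (pts$y - mu)^2)
    }
    o <- stats::optim(c(log(a0), b0), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    list(a = exp(o$par[1]), b = o$par[2], se_a = NA_real_, se_b = NA_real_)
  })

  mu <- if (family == "power") est$a * pts$x^(-est$b) else est$a * exp(-est$b * pts$x)
  rss <- sum(w * (pts$y - mu)^2)
  n <- nrow(pts)
  p <- 2L
  loglik <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  structure(list(
    family = family, a = est$a, b = est$b,
    se_a = est$se_a, se_b = est$se_b,
    rss = rss, n_obs = n, n_params = p,
    loglik = loglik,
    aic = n * log(rss / n) + 2 * (p + 1),
    zero_bin = sum(freq$y[freq$x == 0]),
    weights = weights,
    month = attr(freq, "month")
  ), class = "curve_fit")
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf("<curve_fit %s: a = %.4g, b = %.4g, rss = %.4g, AIC = %.2f (n = %d)>\n",
              x$family, x$a, x$b, x$rss, x$aic, x$n_obs))
  invisible(x)
}

#' Compare curve families on one frequency table by AIC
#'
#' Fits each family to the identical point set (zero-handling is forced
#' identical across families, so AICs are commensurable) and ranks them by
#' AIC. Ties are broken toward fewer parameters, then lexical family name,
#' so the preferred family is always unique.
#'
#' @param freq a `frequency_table`.
#' @param families character vector of families to compare.
#' @param weights passed to [fit_curve()].
#' @return a `fit_comparison` list with `fits` (named list of `curve_fit`),
#'   `delta_aic` (named, minimum 0) and `preferred`.
#' @export
compare_families <- function(freq, families = c("power", "exponential"),
                             weights = "none") {
  stopifnot(length(families) >= 2)
  # Zero-handling forced identical: all families fitted on X >= 1.
  fits <- lapply(families, function(f) {
    fit_curve(freq, family = f, include_zero = FALSE, weights = weights)
  })
  names(fits) <- families
  if (length(unique(vapply(fits, function(f) f$n_obs, integer(1)))) != 1) {
    stop("families fitted on mismatched point sets; comparison invalid", call. = FALSE)
  }
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  best <- min(aics)
  delta <- ifelse(aics == best, 0, aics - best)
  cand <- names(which(delta == 0))
  if (length(cand) > 1) {
    np <- vapply(fits[cand], function(f) f$n_params, integer(1))
    cand <- cand[np == min(np)]
    cand <- sort(cand)[1]
  }
  structure(list(fits = fits, delta_aic = delta, preferred = cand,
                 month = attr(freq, "month")),
            class = "fit_comparison")
}

#' @export
print.fit_comparison <- function(x, ...) {
  cat("<fit_comparison> preferred:", x$preferred, "\n")
  for (f in names(x$fits)) {
    cat(sprintf("  %-12s AIC %8.2f  (delta %.2f)\n",
                f, x$fits[[f]]$aic, x$delta_aic[[f]]))
  }
  invisible(x)
}

#' Pool monthly curve fits
#'
#' Two-stage analogue of a mixed-effects fit: per-month curves are combined
#' into pooled fixed-effect estimates by inverse-variance weighting (using
#' each fit's Gauss-Newton curvature standard errors), with the dispersion of
#' the monthly estimates reported as a between-month standard deviation.
#' Months whose fits carry no usable standard error (e.g. exact fits) fall
#' back to equal weights for both parameters.
#'
#' @param monthly a list of `curve_fit` objects of the same family.
#' @return a `pooled_fit` list: `family`, `fixed_a`, `fixed_b`,
#'   `between_month_sd_a`, `between_month_sd_b`, `n_months`, `monthly_fits`.
#' @export
pool_monthly_fits <- function(monthly) {
  stopifnot(length(monthly) >= 2)
  fams <- unique(vapply(monthly, function(f) f$family, character(1)))
  if (length(fams) != 1) stop("cannot pool fits of mixed families", call. = FALSE)
  a <- vapply(monthly, function(f) f$a, numeric(1))
  b <- vapply(monthly, function(f) f$b, numeric(1))
  se_a <- vapply(monthly, function(f) f$se_a, numeric(1))
  se_b <- vapply(monthly, function(f) f$se_b, numeric(1))
  wmean <- function(est, se) {
    w <- 1 / se^2
    if (any(!is.finite(w))) w <- rep(1, length(est))
    sum(w * est) / sum(w)
  }
  structure(list(
    family = fams,
    fixed_a = wmean(a, se_a), fixed_b = wmean(b, se_b),
    between_month_sd_a = stats::sd(a), between_month_sd_b = stats::sd(b),
    n_months = length(monthly),
    monthly_fits = monthly
  ), class = "pooled_fit")
}

#' @export
print.pooled_fit <- function(x, ...) {
  cat(sprintf("<pooled_fit %s over %d months: a = %.4g (sd %.3g), b = %.4g (sd %.3g)>\n",
              x$family, x$n_months, x$fixed_a, x$between_month_sd_a,
              x$fixed_b, x$between_month_sd_b))
  invisible(x)
}

#' Log-log coordinates of a frequency table
#'
#' Natural-log pairs for the classic Lotka diagnostic plot: an inverse-power
#' law is a straight line in these coordinates. The X = 0 bin cannot be
#' log-transformed and is omitted with a notice attribute.
#'
#' @param freq a `frequency_table`.
#' @return tibble with columns `log_x`, `log_y`; attribute `zero_bin_omitted`
#'   is `TRUE` when an X = 0 entry was dropped.
#' @export
loglog_points <- function(freq) {
  keep <- freq$x >= 1
  out <- tibble::tibble(log_x = log(freq$x[keep]), log_y = log(freq$y[keep]))
  attr(out, "zero_bin_omitted") <- any(!keep)
  out
}
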