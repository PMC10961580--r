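#' Configure a synthetic registry
#'
#' Parameters for the synthetic registry generator. The defaults emulate the
#' scale and shape of a national spinal-surgery registry: ~650 providers
#' across ~285 units over the 58 months from May 2016 to February 2021,
#' heavily right-skewed monthly caseloads with modal value 0 (gamma-Poisson,
#' shape 0.5, mean 4 operations per provider-month, giving ~150,000 events),
#' and roughly half of providers operating at more than one unit.
#'
#' Rate models:
#' * `gamma_poisson` — a latent monthly rate per provider drawn once from a
#'   gamma distribution (`rate_params$shape`, `rate_params$mean`), monthly
#'   counts Poisson around it. Produces geometric-like (exponential-decay)
#'   caseload frequency tables.
#' * `zeta_power` — counts drawn iid per provider-month from a zeta
#'   (discrete power-law) distribution with exponent `rate_params$s`,
#'   support 1..`rate_params$kmax` (default 1e5). Produces Lotka-type
#'   inverse-power frequency tables.
#' * `geometric` — counts iid geometric with `rate_params$p` (support 0+).
#' * `explicit` — `rate_params$rates` gives each provider's monthly rate;
#'   counts are Poisson around it, or exactly equal to it when
#'   `rate_params$dispersion = "none"`.
#'
#' @param n_providers,n_units entity counts.
#' @param months character vector of `"YYYY-MM"` keys.
#' @param rate_model one of `"gamma_poisson"`, `"zeta_power"`, `"geometric"`,
#'   `"explicit"`.
#' @param rate_params named list of model parameters (see above).
#' @param multi_unit_prob probability a provider is affiliated to 2+ units.
#' @param seed integer seed; the same config always yields the same data.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_providers = 650,
                             n_units = 285,
                             months = month_seq("2016-05", "2021-02"),
                             rate_model = c("gamma_poisson", "zeta_power",
                                            "geometric", "explicit"),
                             rate_params = list(shape = 0.5, mean = 4),
                             multi_unit_prob = 0.529,
                             seed = 1L) {
  rate_model <- match.arg(rate_model)
  stopifnot(n_providers >= 1, n_units >= 1, length(months) >= 1,
            multi_unit_prob >= 0, multi_unit_prob <= 1)
  structure(list(
    n_providers = as.integer(n_providers),
    n_units = as.integer(n_units),
    months = months,
    rate_model = rate_model,
    rate_params = rate_params,
    multi_unit_prob = multi_unit_prob,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# iid draws from a truncated zeta distribution P(X = k) proportional to k^-s.
rzeta_trunc <- function(n, s, kmax = 1e5) {
  k <- seq_len(kmax)
  sample(k, n, replace = TRUE, prob = k^(-s))
}

#' Generate a synthetic caseload matrix
#'
#' Draws monthly caseload counts for every provider under the configured
#' rate model. Ground-truth latent rates (gamma-Poisson and explicit models)
#' are attached as the `rates` attribute so parameter-recovery tests can
#' compare against truth.
#'
#' @param config a [synthetic_config()].
#' @return a provider-level `caseload_matrix` with attribute `rates` (named
#'   numeric, or NULL for direct-draw models).
#' @export
generate_caseloads <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  providers <- sprintf("S%04d", seq_len(config$n_providers))
  n_m <- length(config$months)
  n_p <- config$n_providers
  p <- config$rate_params
  withr::with_seed(config$seed, {
    res <- switch(config$rate_model,
      gamma_poisson = {
        stopifnot(!is.null(p$shape), !is.null(p$mean))
        rates <- stats::rgamma(n_p, shape = p$shape, scale = p$mean / p$shape)
        list(counts = stats::rpois(n_m * n_p, rep(rates, each = n_m)),
             rates = rates)
      },
      zeta_power = {
        stopifnot(!is.null(p$s))
        kmax <- if (is.null(p$kmax)) 1e5 else p$kmax
        list(counts = rzeta_trunc(n_m * n_p, p$s, kmax), rates = NULL)
      },
      geometric = {
        stopifnot(!is.null(p$p))
        list(counts = stats::rgeom(n_m * n_p, p$p), rates = NULL)
      },
      explicit = {
        stopifnot(!is.null(p$rates), length(p$rates) == n_p)
        rates <- as.numeric(p$rates)
        cnt <- if (identical(p$dispersion, "none")) {
          rep(rates, each = n_m)
        } else {
          stats::rpois(n_m * n_p, rep(rates, each = n_m))
        }
        list(counts = cnt, rates = rates)
      },
      stop("unknown rate model: ", config$rate_model, call. = FALSE)
    )
    mat <- matrix(as.integer(res$counts), nrow = n_m,
                  dimnames = list(config$months, providers))
    if (!is.null(res$rates)) names(res$rates) <- providers
    structure(mat,
              class = c("caseload_matrix", "matrix", "array"),
              entity_kind = "provider",
              rates = res$rates,
              audit = list(n_events_in = sum(mat), n_outside_window = 0L,
                           n_excluded_inactive = 0L, n_counted = sum(mat)))
  })
}

#' Expand a caseload matrix into a dated registry event table
#'
#' Each cell count becomes that many events dated uniformly within the
#' month. Providers are affiliated to 1 unit, plus (with probability
#' `multi_unit_prob`) a geometric number of extra units, capped at 7 total;
#' each event's unit is drawn uniformly from the provider's affiliations.
#' Re-aggregating the result with [monthly_caseloads()] (all providers
#' active, window covering the months) reproduces the matrix exactly.
#'
#' @param matrix a `caseload_matrix` from [generate_caseloads()].
#' @param config the same [synthetic_config()].
#' @return a `case_event_table`; its `provider_units` attribute records each
#'   provider's unit affiliations.
#' @export
generate_registry_events <- function(matrix, config) {
  stopifnot(inherits(matrix, "caseload_matrix"),
            inherits(config, "synthetic_config"))
  units <- sprintf("U%03d", seq_len(config$n_units))
  providers <- colnames(matrix)
  months <- rownames(matrix)
  withr::with_seed(config$seed + 1L, {
    n_extra <- stats::rbinom(length(providers), 1, config$multi_unit_prob) *
      (1L + stats::rgeom(length(providers), 0.6))
    n_aff <- pmin(1L + n_extra, 7L, config$n_units)
    affil <- lapply(n_aff, function(k) sample(units, k))
    names(affil) <- providers

    long <- caseload_long(matrix)
    long <- long[long$count > 0, , drop = FALSE]
    key <- sprintf("%04d-%02d", long$year, long$month)
    prov <- rep(long$entity_id, long$count)
    mkey <- rep(key, long$count)
    starts <- month_first_day(mkey)
    ndays <- vapply(unique(mkey), month_days, integer(1))[mkey]
    dates <- starts + floor(stats::runif(length(prov)) * ndays)
    # vectorized uniform pick among each event's provider affiliations
    aff_n <- vapply(affil, length, integer(1))
    aff_vec <- unlist(affil, use.names = FALSE)
    aff_start <- stats::setNames(cumsum(c(0L, utils::head(aff_n, -1))),
                                 names(affil))
    idx <- pmax(1L, ceiling(stats::runif(length(prov)) * aff_n[prov]))
    unit <- aff_vec[aff_start[prov] + idx]
    ev <- case_event_table(prov, unit, dates)
    attr(ev, "provider_units") <- affil
    ev
  })
}

#' Deterministic Pareto-tail population
#'
#' A noise-free population of volumes set to the Pareto quantile function
#' `(1 - p)^(-1/alpha)` at probabilities `(i - 0.5) / N`. With tail index
#' `alpha = log(5)/log(4)` (~1.161) this is the self-similar 80/20
#' population: the top 20% of entities hold 80% of the volume at any scale.
#'
#' @param N population size (>= 100).
#' @param tail_index Pareto tail index alpha; must exceed 1 (finite mean).
#' @return numeric vector of N volumes (ascending in i, hence descending in
#'   size), identical for identical inputs.
#' @examples
#' v <- make_pareto_tail_population(1000, log(5) / log(4))
#' @export
make_pareto_tail_population <- function(N, tail_index) {
  stopifnot(N >= 100)
  if (tail_index <= 1) stop("tail_index must exceed 1 (infinite mean otherwise)",
                            call. = FALSE)
  p <- (seq_len(N) - 0.5) / N
  (1 - p)^(-1 / tail_index)
}

#' Specify a pandemic-style shock
#'
#' @param shock_months `"YYYY-MM"` keys in which the shock applies.
#' @param band_multipliers named numeric vector (names = band indices) of
#'   rate multipliers in `[0, 1]`; e.g. `c("1" = 1, "5" = 0.3)` leaves the
#'   lowest-volume band untouched and suppresses the top band to 30%.
#' @return a `shock_spec` list.
#' @export
shock_spec <- function(shock_months, band_multipliers) {
  stopifnot(all(band_multipliers >= 0), all(band_multipliers <= 1),
            !is.null(names(band_multipliers)))
  structure(list(shock_months = shock_months,
                 band_multipliers = band_multipliers),
            class = "shock_spec")
}

#' Apply a volume shock to selected months
#'
#' Emulates the pandemic signature in which high-volume providers lose
#' disproportionately many cases: in each shock month, every entity's count
#' is binomially thinned with its band's multiplier. Non-shock months are
#' untouched. Entities missing from the assignment are treated as band 1
#' with a notice.
#'
#' @param matrix a `caseload_matrix`.
#' @param assignment an [assign_bands()] result.
#' @param shock a [shock_spec()]; its months must exist in the matrix.
#'   Bands without an explicit multiplier keep multiplier 1.
#' @param seed integer seed for the thinning draws.
#' @return the shocked `caseload_matrix`; attribute `shock_notices` lists
#'   unassigned entities defaulted to band 1.
#' @export
apply_shock <- function(matrix, assignment, shock, seed = 1L) {
  stopifnot(inherits(matrix, "caseload_matrix"),
            inherits(assignment, "band_assignment"),
            inherits(shock, "shock_spec"))
  missing_m <- setdiff(shock$shock_months, rownames(matrix))
  if (length(missing_m)) {
    stop("shock months absent from matrix: ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  }
  band_of <- stats::setNames(assignment$band, assignment$entity_id)
  entities <- colnames(matrix)
  bands <- band_of[entities]
  notices <- character(0)
  if (anyNA(bands)) {
    notices <- paste0("unassigned entities defaulted to band 1: ",
                      sum(is.na(bands)))
    bands[is.na(bands)] <- 1L
  }
  mult <- rep(1, length(entities))
  known <- as.character(bands) %in% names(shock$band_multipliers)
  mult[known] <- shock$band_multipliers[as.character(bands)[known]]
  out <- matrix
  withr::with_seed(seed, {
    for (m in shock$shock_months) {
      out[m, ] <- stats::rbinom(length(entities), matrix[m, ], mult)
    }
  })
  attr(out, "shock_notices") <- notices
  out
}
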