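#' Assign entities to equal-contribution volume bands
#'
#' Partitions entities into bands that each account for a fixed share
#' (default 20%) of total reference-period operations, built from the
#' lowest-volume entities upward: band 1 is the (largest) group of
#' lowest-volume entities contributing the first 20% of operations, and the
#' final band is the small group of highest-volume entities contributing the
#' last 20%. An entity belongs wholly to the band containing its
#' cumulative-share endpoint — people are not split across bands — and the
#' final band absorbs any remainder. Entities with zero reference volume are
#' unassigned.
#'
#' @param volumes named numeric vector: reference-period volume per entity.
#' @param band_share share of total operations per band, in (0, 0.5].
#' @return a tibble of class `band_assignment` with columns `entity_id`,
#'   `volume`, `cum_share` (the entity's endpoint) and `band`; attributes
#'   `band_share` and `n_bands` (= `ceiling(1/band_share)`).
#' @examples
#' assign_bands(c(a = 1, b = 1, c = 1, d = 1, e = 1, f = 5, g = 10))
#' @export
assign_bands <- function(volumes, band_share = 0.2) {
  if (!(band_share > 0 && band_share <= 0.5)) {
    stop("band_share must lie in (0, 0.5]", call. = FALSE)
  }
  stopifnot(all(volumes >= 0))
  if (all(volumes == 0)) stop("no operations in reference period", call. = FALSE)
  ids <- names(volumes)
  if (is.null(ids)) ids <- as.character(seq_along(volumes))
  keep <- volumes > 0
  v <- as.numeric(volumes[keep])
  ids <- ids[keep]
  ord <- order(v, ids)  # ascending volume, ties by id
  v <- v[ord]
  ids <- ids[ord]
  cum <- cumsum(v) / sum(v)
  n_bands <- as.integer(ceiling(1 / band_share - 1e-9))
  # endpoint in ((b-1)*share, b*share] => band b; final band takes remainder
  band <- pmin(as.integer(ceiling(cum / band_share - 1e-9)), n_bands)
  # a lone contributor spans every band; the partition degenerates to band 1
  if (length(v) == 1) band <- 1L
  out <- tibble::tibble(entity_id = ids, volume = v, cum_share = cum,
                        band = band)
  structure(out, class = c("band_assignment", class(out)),
            band_share = band_share, n_bands = n_bands)
}

#' Track volume bands across time periods
#'
#' For each band and period, computes each member entity's mean monthly
#' volume within the period (means, not totals, so unequal-length periods
#' remain comparable), then summarizes the entities with box-plot statistics:
#' type-7 quartiles and Tukey 1.5*IQR whiskers with outliers listed.
#'
#' @param matrix a `caseload_matrix` containing the assignment's entities.
#' @param assignment an [assign_bands()] result.
#' @param periods named list of character vectors of `"YYYY-MM"` keys; must
#'   be pairwise non-overlapping and present in the matrix.
#' @return tibble with one row per band x period: `band`, `period`, `n`,
#'   `min`, `q1`, `median`, `q3`, `max`, `n_outliers`, and a list-column
#'   `outliers`; empty cells are omitted with a `skipped_cells` attribute.
#' @export
track_bands <- function(matrix, assignment, periods) {
  stopifnot(inherits(matrix, "caseload_matrix"),
            inherits(assignment, "band_assignment"))
  if (is.null(names(periods)) || any(names(periods) == "")) {
    stop("periods must be a named list", call. = FALSE)
  }
  all_months <- unlist(periods)
  if (anyDuplicated(all_months)) stop("periods overlap", call. = FALSE)
  missing_m <- setdiff(all_months, rownames(matrix))
  if (length(missing_m)) {
    stop("period months absent from matrix: ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  }
  missing_e <- setdiff(assignment$entity_id, colnames(matrix))
  if (length(missing_e)) {
    stop("assignment entities absent from matrix: ",
         paste(utils::head(missing_e, 5), collapse = ", "), call. = FALSE)
  }
  skipped <- character(0)
  rows <- list()
  for (b in sort(unique(assignment$band))) {
    members <- assignment$entity_id[assignment$band == b]
    for (p in names(periods)) {
      sub <- matrix[periods[[p]], members, drop = FALSE]
      vals <- colMeans(sub)
      if (length(vals) == 0) {
        skipped <- c(skipped, paste0("band ", b, " x ", p))
        next
      }
      q <- stats::quantile(vals, c(.25, .5, .75), type = 7, names = FALSE)
      iqr <- q[3] - q[1]
      out_lo <- q[1] - 1.5 * iqr
      out_hi <- q[3] + 1.5 * iqr
      outl <- vals[vals < out_lo | vals > out_hi]
      rows[[length(rows) + 1]] <- tibble::tibble(
        band = b, period = p, n = length(vals),
        min = min(vals), q1 = q[1], median = q[2], q3 = q[3], max = max(vals),
        n_outliers = length(outl), outliers = list(unname(outl))
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped_cells") <- skipped
  out
}
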