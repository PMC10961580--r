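#' Configure an end-to-end pipeline run
#'
#' Bundles every setting the pipeline needs: the input (a registry CSV or a
#' [synthetic_config()]), the study window and activity rule, the analysis
#' window over which fits and summaries are pooled, concentration settings,
#' banding periods, and annotation dates echoed into exports.
#'
#' @param input_csv path to a registry CSV, or `NULL` to simulate.
#' @param synthetic a [synthetic_config()] used when `input_csv` is `NULL`.
#' @param column_map,date_format passed to [parse_registry()].
#' @param study_window a [study_window()].
#' @param activity an [activity_rule()].
#' @param analysis_window length-2 character vector of `"YYYY-MM"` keys
#'   (inclusive) over which fits, summaries and band reference volumes are
#'   computed; must lie within the study window.
#' @param q_list target shares for concentration statistics.
#' @param denominator_rule,interpolate concentration settings.
#' @param band_share share of operations per volume band.
#' @param band_periods named list of `"YYYY-MM"` vectors to track bands
#'   across; `NULL` derives a `reference` period (the analysis window) and,
#'   when later months exist, a `post` period.
#' @param annotations named character vector of annotation dates copied into
#'   the manifest and plot-data exports (e.g. tariff or lockdown dates).
#' @param out_dir output directory for artifacts.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input_csv = NULL,
                            synthetic = synthetic_config(),
                            column_map = c(provider = "consultant_in_charge",
                                           unit = "unit",
                                           date = "procedure_completed_date"),
                            date_format = "iso",
                            study_window = default_study_window(),
                            activity = activity_rule("2019-04-01"),
                            analysis_window = c("2019-04", "2020-03"),
                            q_list = c(0.5, 0.8),
                            denominator_rule = "operating_only",
                            interpolate = TRUE,
                            band_share = 0.2,
                            band_periods = NULL,
                            annotations = c(best_practice_tariff = "2019-04-01",
                                            lockdown_1 = "2020-03-25",
                                            lockdown_2 = "2020-11-05",
                                            lockdown_3 = "2021-01-05"),
                            out_dir = tempfile("caseconc_run_")) {
  stopifnot(inherits(study_window, "study_window"),
            inherits(activity, "activity_rule"),
            length(analysis_window) == 2)
  if (!all(q_list > 0 & q_list <= 1)) {
    stop("q_list values must lie in (0, 1]", call. = FALSE)
  }
  study_months <- month_seq(study_window$start, study_window$end)
  analysis_months <- month_seq(analysis_window[1], analysis_window[2])
  if (!all(analysis_months %in% study_months)) {
    stop("analysis window must lie within the study window", call. = FALSE)
  }
  if (!is.null(band_periods)) {
    stopifnot(is.list(band_periods), !is.null(names(band_periods)))
  }
  structure(list(
    input_csv = input_csv, synthetic = synthetic,
    column_map = column_map, date_format = date_format,
    study_window = study_window, activity = activity,
    analysis_window = analysis_window,
    q_list = q_list, denominator_rule = denominator_rule,
    interpolate = interpolate,
    band_share = band_share, band_periods = band_periods,
    annotations = annotations,
    out_dir = out_dir
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Accepts the same fields as [pipeline_config()] with windows given as
#' `[start, end]` pairs and a `synthetic:` block of [synthetic_config()]
#' fields.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$input_csv)) args$input_csv <- y$input_csv
  if (!is.null(y$synthetic)) {
    args$synthetic <- do.call(synthetic_config, y$synthetic)
  }
  if (!is.null(y$study_window)) {
    args$study_window <- study_window(y$study_window[[1]], y$study_window[[2]])
  }
  if (!is.null(y$activity_cutoff)) args$activity <- activity_rule(y$activity_cutoff)
  for (f in c("date_format", "analysis_window", "q_list", "denominator_rule",
              "interpolate", "band_share", "out_dir")) {
    if (!is.null(y[[f]])) args[[f]] <- unlist(y[[f]])
  }
  if (!is.null(y$band_periods)) {
    args$band_periods <- lapply(y$band_periods, function(p) {
      month_seq(p[[1]], p[[length(p)]])
    })
  }
  if (!is.null(y$column_map)) args$column_map <- unlist(y$column_map)
  if (!is.null(y$annotations)) args$annotations <- unlist(y$annotations)
  do.call(pipeline_config, args)
}

# default study period: May 2016 to late February 2021
default_study_window <- function() study_window("2016-05-01", "2021-02-27")

# 32-bit FNV-1a fingerprint of a string, as 8 hex digits.
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- h - h %% 256 + bitwXor(as.integer(h %% 256), b)  # xor the low byte
    # multiply by the FNV prime 16777619, split as 403 + 2^24 so every
    # intermediate stays below 2^53
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_fingerprint <- function(config) {
  json <- jsonlite::toJSON(config_manifest(config), auto_unbox = TRUE)
  fnv1a(as.character(json))
}

# JSON-serializable view of a pipeline_config
config_manifest <- function(config) {
  list(
    input_csv = config$input_csv,
    synthetic = if (!is.null(config$synthetic)) unclass(config$synthetic),
    study_window = c(format(config$study_window$start),
                     format(config$study_window$end)),
    activity_cutoff = format(config$activity$activity_cutoff),
    analysis_window = config$analysis_window,
    q_list = config$q_list,
    denominator_rule = config$denominator_rule,
    interpolate = config$interpolate,
    band_share = config$band_share,
    band_periods = config$band_periods,
    annotations = as.list(config$annotations)
  )
}

#' Run the full case-volume concentration pipeline
#'
#' Executes ingest, caseload aggregation, frequency fitting and family
#' comparison, concentration series and summaries, monthly extremes, and
#' band tracking; writes every artifact (tidy CSVs, JSON summaries, a JSON
#' manifest with the configuration fingerprint, and a text report) to
#' `config$out_dir`. A failing stage aborts with the stage name and removes
#' the partial outputs. Re-running an identical configuration is idempotent.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) the report bundle: a list with elements `summary`,
#'   `audit`, `fits`, `pooled`, `concentration`, `extremes`, `bands`,
#'   `manifest`, `files`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  say <- function(...) if (!quiet) message("[caseconc] ", ...)
  emit <- function(name, writer) {
    path <- file.path(config$out_dir, name)
    writer(path)
    written <<- c(written, path)
    path
  }
  stage <- "setup"
  bundle <- tryCatch({
    # --- ingest -----------------------------------------------------------
    stage <- "ingest"
    if (is.null(config$input_csv)) {
      say("simulating synthetic registry")
      mat0 <- generate_caseloads(config$synthetic)
      events_all <- generate_registry_events(mat0, config$synthetic)
      registry_csv <- file.path(config$out_dir, "registry.csv")
      readr::write_csv(
        tibble::tibble(unit = events_all$unit_id,
                       consultant_in_charge = events_all$provider_id,
                       procedure_completed_date = format(events_all$event_date)),
        registry_csv)
      written <- c(written, registry_csv)
    } else {
      registry_csv <- config$input_csv
    }
    events <- parse_registry(registry_csv, config$column_map, config$date_format)
    events <- filter_window(events, config$study_window)
    say(nrow(events), " in-window events")

    stage <- "caseloads"
    actives <- active_providers(events, config$activity)
    if (length(actives) == 0) stop("no active providers under the activity rule")
    mat <- monthly_caseloads(events, actives, config$study_window, "provider")
    summ <- registry_summary(mat, events)
    audit <- c(event_audit(events), event_audit(mat),
               list(n_active_providers = length(actives)))
    emit("caseloads.csv", function(p) readr::write_csv(caseload_long(mat), p))
    emit("registry_summary.json", function(p) {
      jsonlite::write_json(unclass(summ), p, auto_unbox = TRUE, digits = NA)
    })
    emit("audit.json", function(p) {
      jsonlite::write_json(audit, p, auto_unbox = TRUE, digits = NA)
    })

    # --- frequency fits over the analysis window --------------------------
    stage <- "distribution_fitting"
    analysis_months <- month_seq(config$analysis_window[1],
                                 config$analysis_window[2])
    comparisons <- list()
    fit_rows <- list()
    for (m in analysis_months) {
      freq <- build_frequency_table(mat, m)
      cmp <- tryCatch(compare_families(freq), error = function(e) NULL)
      if (is.null(cmp)) next  # e.g. too few support points that month
      comparisons[[m]] <- cmp
      for (fam in names(cmp$fits)) {
        f <- cmp$fits[[fam]]
        fit_rows[[length(fit_rows) + 1]] <- tibble::tibble(
          month = m, family = fam, a = f$a, b = f$b, rss = f$rss,
          n_obs = f$n_obs, aic = f$aic, delta_aic = cmp$delta_aic[[fam]],
          preferred = cmp$preferred)
      }
    }
    if (length(comparisons) == 0) stop("no month in the analysis window was fittable")
    fits_tbl <- dplyr::bind_rows(fit_rows)
    pooled <- lapply(c(power = "power", exponential = "exponential"), function(fam) {
      fits <- lapply(comparisons, function(cmp) cmp$fits[[fam]])
      if (length(fits) >= 2) pool_monthly_fits(fits) else NULL
    })
    emit("fits_monthly.csv", function(p) readr::write_csv(fits_tbl, p))
    emit("pooled_fits.json", function(p) {
      jsonlite::write_json(lapply(pooled, function(pf) {
        if (is.null(pf)) return(NULL)
        pf$monthly_fits <- NULL
        unclass(pf)
      }), p, auto_unbox = TRUE, digits = NA)
    })

    # --- concentration ----------------------------------------------------
    stage <- "concentration"
    series <- monthly_concentration_series(mat, config$q_list,
                                           config$denominator_rule,
                                           config$interpolate)
    key <- sprintf("%04d-%02d", series$year, series$month)
    in_aw <- key %in% analysis_months
    conc_summaries <- list()
    for (q in config$q_list) {
      vals <- series$value[in_aw & series$statistic == "fraction_q" & series$q == q]
      if (length(vals) >= 2) {
        conc_summaries[[sprintf("fraction_q%g", q)]] <-
          summarize_series(vals, sprintf("fraction covering %g", q))
      }
    }
    pr_vals <- series$value[in_aw & series$statistic == "price_root"]
    if (length(pr_vals) >= 2) {
      conc_summaries$price_root <- summarize_series(pr_vals, "price root")
    }
    extremes <- monthly_extremes(mat)
    emit("concentration_series.csv", function(p) readr::write_csv(series, p))
    emit("concentration_summary.json", function(p) {
      jsonlite::write_json(lapply(conc_summaries, unclass), p,
                           auto_unbox = TRUE, digits = NA)
    })
    emit("monthly_extremes.csv", function(p) readr::write_csv(extremes$monthly, p))
    emit("extremes_summary.json", function(p) {
      jsonlite::write_json(lapply(extremes$summary, unclass), p,
                           auto_unbox = TRUE, digits = NA)
    })

    # --- banding ----------------------------------------------------------
    stage <- "banding"
    ref_vols <- colSums(mat[analysis_months, , drop = FALSE])
    assignment <- assign_bands(ref_vols, config$band_share)
    periods <- config$band_periods
    if (is.null(periods)) {
      periods <- list(reference = analysis_months)
      later <- rownames(mat)[rownames(mat) > analysis_months[length(analysis_months)]]
      if (length(later) > 0) periods$post <- later
    }
    boxstats <- track_bands(mat, assignment, periods)
    emit("band_assignment.csv", function(p) {
      readr::write_csv(tibble::as_tibble(assignment), p)
    })
    emit("band_boxstats.csv", function(p) {
      readr::write_csv(dplyr::select(boxstats, -"outliers"), p)
    })

    # --- manifest + report ------------------------------------------------
    stage <- "report"
    manifest <- list(
      package = "caseconc",
      version = as.character(utils::packageVersion("caseconc")),
      seed = if (!is.null(config$synthetic)) config$synthetic$seed,
      config = config_manifest(config),
      config_fingerprint = config_fingerprint(config),
      artifacts = basename(written)
    )
    bundle <- list(summary = summ, audit = audit, fits = fits_tbl,
                   pooled = pooled, comparisons = comparisons,
                   concentration = list(series = series, summaries = conc_summaries),
                   extremes = extremes,
                   bands = list(assignment = assignment, boxstats = boxstats,
                                periods = periods),
                   manifest = manifest)
    emit("manifest.json", function(p) {
      jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA)
    })
    emit("report.txt", function(p) write_report(bundle, p))
    bundle$files <- written
    bundle
  }, error = function(e) {
    unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  say("wrote ", length(bundle$files), " artifacts to ", config$out_dir)
  invisible(bundle)
}

#' Write a human-readable pipeline report
#'
#' Formats the report bundle produced by [run_pipeline()]: registry summary,
#' the preferred curve family per analysed month with pooled coefficients,
#' the concentration summaries (Pareto fractions and Price root with 95%
#' CIs) and the band trajectories. Every number is taken verbatim from the
#' bundle, which is serialized unchanged to the stage artifacts.
#'
#' @param bundle the [run_pipeline()] result.
#' @param path file to write; `NULL` returns the lines invisibly.
#' @return (invisibly) the report lines.
#' @export
write_report <- function(bundle, path = NULL) {
  s <- bundle$summary
  fmt_ci <- function(ss, scale = 1, unit = "") {
    sprintf("%.3g%s (95%% CI %.3g to %.3g)", ss$mean * scale, unit,
            ss$ci_low * scale, ss$ci_high * scale)
  }
  lines <- c(
    "Case-volume concentration report",
    "================================",
    "",
    sprintf("Operations: %d; monthly median %.1f (IQR %.1f-%.1f)",
            s$total_events, s$monthly_event_median,
            s$monthly_event_iqr[1], s$monthly_event_iqr[2]),
    sprintf("Providers: %d distinct, %d active; monthly operating median %.1f (IQR %.1f-%.1f)",
            s$distinct_providers, s$n_active_providers, s$monthly_provider_median,
            s$monthly_provider_iqr[1], s$monthly_provider_iqr[2]),
    sprintf("Units: %d; providers at 2+ units: %d (max %d)",
            s$distinct_units, s$multi_unit_provider_count, s$max_units_per_provider),
    "",
    "Frequency-curve selection (per analysed month):"
  )
  for (m in names(bundle$comparisons)) {
    cmp <- bundle$comparisons[[m]]
    aics <- vapply(cmp$fits, function(f) f$aic, numeric(1))
    lines <- c(lines, sprintf("  %s: preferred %s (AIC %s)",
                              m, cmp$preferred,
                              paste(sprintf("%s %.1f", names(aics), aics),
                                    collapse = ", ")))
  }
  for (fam in names(bundle$pooled)) {
    pf <- bundle$pooled[[fam]]
    if (is.null(pf)) next
    lines <- c(lines, sprintf(
      "  pooled %s: a = %.3f (between-month sd %.3f), b = %.4f (sd %.4f)",
      fam, pf$fixed_a, pf$between_month_sd_a, pf$fixed_b, pf$between_month_sd_b))
  }
  lines <- c(lines, "", "Concentration (analysis window):")
  for (nm in names(bundle$concentration$summaries)) {
    ss <- bundle$concentration$summaries[[nm]]
    scale <- if (grepl("fraction", nm)) 100 else 1
    unit <- if (grepl("fraction", nm)) "%" else ""
    lines <- c(lines, sprintf("  %s: %s", ss$statistic, fmt_ci(ss, scale, unit)))
  }
  lines <- c(lines, "", "Monthly caseload extremes:")
  for (nm in names(bundle$extremes$summary)) {
    lines <- c(lines, sprintf("  %s: %s", nm, fmt_ci(bundle$extremes$summary[[nm]])))
  }
  lines <- c(lines, "", "Volume bands (median of per-entity mean monthly volume):")
  bs <- bundle$bands$boxstats
  for (i in seq_len(nrow(bs))) {
    lines <- c(lines, sprintf("  band %d, %s: median %.2f (IQR %.2f-%.2f, n = %d)",
                              bs$band[i], bs$period[i], bs$median[i],
                              bs$q1[i], bs$q3[i], bs$n[i]))
  }
  if (!is.null(bundle$manifest$config$annotations)) {
    ann <- bundle$manifest$config$annotations
    lines <- c(lines, "", "Annotation dates:",
               sprintf("  %s: %s", names(ann), unlist(ann)))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Check report/artifact consistency
#'
#' Re-reads the serialized stage artifacts of a pipeline run and asserts
#' that the numbers in the in-memory bundle equal them, so every reported
#' figure is traceable to a file.
#'
#' @param bundle a [run_pipeline()] result.
#' @param out_dir the run's output directory.
#' @return `TRUE` (invisibly); errors on any mismatch.
#' @export
verify_artifacts <- function(bundle, out_dir) {
  chk <- function(ok, what) if (!isTRUE(ok)) stop("artifact mismatch: ", what, call. = FALSE)
  summ <- jsonlite::read_json(file.path(out_dir, "registry_summary.json"),
                              simplifyVector = TRUE)
  chk(summ$total_events == bundle$summary$total_events, "total_events")
  chk(isTRUE(all.equal(summ$monthly_provider_median,
                       bundle$summary$monthly_provider_median)),
      "monthly_provider_median")
  fits <- readr::read_csv(file.path(out_dir, "fits_monthly.csv"),
                          show_col_types = FALSE, progress = FALSE)
  chk(isTRUE(all.equal(fits$aic, bundle$fits$aic, tolerance = 1e-8)), "fit AICs")
  series <- readr::read_csv(file.path(out_dir, "concentration_series.csv"),
                            show_col_types = FALSE, progress = FALSE)
  chk(isTRUE(all.equal(series$value, bundle$concentration$series$value,
                       tolerance = 1e-8)), "concentration series")
  cs <- jsonlite::read_json(file.path(out_dir, "concentration_summary.json"),
                            simplifyVector = TRUE)
  for (nm in names(bundle$concentration$summaries)) {
    chk(isTRUE(all.equal(cs[[nm]]$mean, bundle$concentration$summaries[[nm]]$mean,
                         tolerance = 1e-8)), paste0("summary ", nm))
  }
  bs <- readr::read_csv(file.path(out_dir, "band_boxstats.csv"),
                        show_col_types = FALSE, progress = FALSE)
  chk(isTRUE(all.equal(bs$median, bundle$bands$boxstats$median, tolerance = 1e-8)),
      "band medians")
  invisible(TRUE)
}
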