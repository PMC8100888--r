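# Threshold sensitivity sweep, incidence arithmetic, and report rendering.

#' Incidence per 100,000 person-years at risk
#'
#' Exact arithmetic: `rate = events / person_years * 100000`, with an
#' integer-rounded rate for display. The numerator may be a summed
#' probability (non-integer) as in the summed-probability incidence.
#'
#' @param events Event count (or summed probabilities), >= 0.
#' @param person_years Person-years at risk, > 0.
#' @return One-row tibble: events, person_years, rate_per_1e5_pyar,
#'   rate_per_1e5_rounded, annual_incidence.
#' @export
incidence <- function(events, person_years) {
  if (!is.numeric(person_years) || person_years <= 0) {
    stop("`person_years` must be positive", call. = FALSE)
  }
  if (events < 0) stop("`events` must be non-negative", call. = FALSE)
  rate <- events / person_years * 1e5
  tibble::tibble(
    events = events, person_years = person_years,
    rate_per_1e5_pyar = rate,
    rate_per_1e5_rounded = round(rate),
    annual_incidence = events / person_years
  )
}

#' Sensitivity sweep over the self-harm probability threshold
#'
#' Re-runs staging, exposure construction (with the regimen requisites
#' re-checked), and the chosen Cox model at every threshold, reusing the
#' probabilities computed once. Outcome counts and retained regimen sets
#' shrink monotonically as the threshold rises; the sweep asserts the
#' outcome-count monotonicity. Thresholds with zero events are reported as
#' infeasible and skipped.
#'
#' @param metavisits Meta-visits with `selfharm_prob` (see
#'   [crossfit_probabilities()]).
#' @param patients,fills Claims tibbles.
#' @param vocab A `code_vocabulary`.
#' @param thresholds Probability thresholds (default the ten-point grid
#'   0.20-0.95 plus coded-only 1.0).
#' @param covariate_sets Passed to [extract_baseline_covariates()].
#' @param covariates Baseline covariate columns for the model.
#' @param model `"model1"` or `"model2"`.
#' @param min_intervals,min_events Regimen requisites per threshold.
#' @param grace_days Exposure grace period.
#' @param spline_vars,spline_df Spline settings for [assemble_model()].
#' @param start_year Calendar year of day 0.
#' @return Object of class `threshold_sweep`: list with `summary` tibble
#'   (threshold, staged, events, regimens_retained, feasible) and
#'   `hr_tables` (one tidy table per feasible threshold).
#' @export
threshold_sweep <- function(metavisits, patients, fills, vocab,
                            thresholds = c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7,
                                           0.8, 0.9, 0.95, 1.0),
                            covariate_sets = list(),
                            covariates = character(),
                            model = "model1",
                            min_intervals = 50, min_events = 5,
                            grace_days = 30,
                            spline_vars = c("age_at_index",
                                            "prior_unique_bd_drugs"),
                            spline_df = 4, start_year = 2010) {
  stopifnot("selfharm_prob" %in% names(metavisits))
  thresholds <- sort(thresholds)
  res <- list()
  hr_tables <- list()
  prev_events <- Inf
  for (t in thresholds) {
    staged <- stage_patients(metavisits, patients, vocab, threshold = t,
                             fills = fills)
    n_events <- sum(staged$end_reason == "outcome")
    if (n_events > prev_events) {
      stop("outcome counts must be non-increasing in the threshold",
           call. = FALSE)
    }
    prev_events <- n_events
    if (n_events == 0) {
      res[[length(res) + 1]] <- tibble::tibble(
        threshold = t, staged = nrow(staged), events = 0,
        regimens_retained = 0L, feasible = FALSE
      )
      next
    }
    iv <- assign_regimen_timeline(fills, staged, vocab,
                                  grace_days = grace_days)
    iv <- collapse_regimens(iv, min_intervals = min_intervals,
                            min_events = min_events)
    bl <- extract_baseline_covariates(staged, metavisits, fills, patients,
                                      vocab, covariate_sets = covariate_sets,
                                      start_year = start_year)
    rows <- emit_counting_process(staged, iv, metavisits, fills, vocab,
                                  baseline = bl)
    fitted <- tryCatch(
      suppressWarnings(assemble_model(rows, model = model,
                                      covariates = covariates,
                                      spline_vars = spline_vars,
                                      spline_df = spline_df)),
      error = function(e) NULL
    )
    retained <- setdiff(unique(rows$regimen), "no_drug")
    res[[length(res) + 1]] <- tibble::tibble(
      threshold = t, staged = nrow(staged), events = n_events,
      regimens_retained = length(retained), feasible = !is.null(fitted)
    )
    if (!is.null(fitted)) {
      tab <- fitted$hr_table
      tab$threshold <- t
      hr_tables[[as.character(t)]] <- tab
    }
  }
  structure(
    list(summary = dplyr::bind_rows(res), hr_tables = hr_tables,
         model = model),
    class = "threshold_sweep"
  )
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat("<threshold_sweep>", x$model, "\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.threshold_sweep <- function(x, ...) {
  dplyr::bind_rows(x$hr_tables)
}

#' Render the analysis artifacts to a directory
#'
#' Writes publication-shaped delimited tables (hazard-ratio tables shaped
#' like the study's regression tables, sweep summary, regimen catalog,
#' classification metrics, incidence summary, spline curves) and a JSON
#' run manifest with seeds, row counts and software versions. Re-rendering
#' from the same artifacts is byte-identical.
#'
#' @param dir Output directory.
#' @param models Named list of `harm_cox_model` objects.
#' @param sweep Optional `threshold_sweep`.
#' @param metrics Optional metrics tibble.
#' @param incidence_tbl Optional incidence tibble.
#' @param catalog Optional regimen catalog (from [collapse_regimens()]).
#' @param curves Optional named list of spline-curve tibbles.
#' @param seed Seed to record.
#' @param config Arbitrary configuration list recorded (hashed) in the
#'   manifest.
#' @return The manifest list, invisibly.
#' @export
render_report <- function(dir, models = list(), sweep = NULL, metrics = NULL,
                          incidence_tbl = NULL, catalog = NULL, curves = NULL,
                          seed = NA_integer_, config = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    seed = seed,
    config_hash = rlang::hash(config),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("harmimpute")),
    stages = list()
  )
  drop_lists <- function(d) d[, !vapply(d, is.list, logical(1)), drop = FALSE]
  for (nm in names(models)) {
    tab <- models[[nm]]$hr_table
    readr::write_csv(drop_lists(tab), file.path(dir, paste0(nm, "_hr.csv")))
    manifest$stages[[nm]] <- list(rows = nrow(tab))
  }
  if (!is.null(sweep)) {
    readr::write_csv(sweep$summary, file.path(dir, "sweep_summary.csv"))
    all_tab <- dplyr::bind_rows(sweep$hr_tables)
    readr::write_csv(drop_lists(all_tab), file.path(dir, "sweep_hr.csv"))
    manifest$stages$sweep <- list(rows = nrow(sweep$summary))
  }
  if (!is.null(metrics)) {
    readr::write_csv(metrics, file.path(dir, "metrics.csv"))
    manifest$stages$metrics <- list(rows = nrow(metrics))
  }
  if (!is.null(incidence_tbl)) {
    readr::write_csv(incidence_tbl, file.path(dir, "incidence.csv"))
    manifest$stages$incidence <- list(rows = nrow(incidence_tbl))
  }
  if (!is.null(catalog)) {
    readr::write_csv(catalog, file.path(dir, "regimen_catalog.csv"))
    manifest$stages$catalog <- list(rows = nrow(catalog))
  }
  for (nm in names(curves)) {
    readr::write_csv(curves[[nm]], file.path(dir, paste0("curve_", nm, ".csv")))
    manifest$stages[[paste0("curve_", nm)]] <- list(rows = nrow(curves[[nm]]))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
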