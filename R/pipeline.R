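# End-to-end convenience wrapper over the pipeline stages.

#' Run the full analysis pipeline on simulated (or read-in) claims
#'
#' Convenience chain: meta-visit construction and labeling, optional
#' cross-validated imputation, staging at a threshold, exposure-interval
#' construction with regimen collapsing, baseline covariates, counting-
#' process rows, and the main Cox model. Each intermediate artifact is
#' returned so stages can also be driven individually.
#'
#' @param sim A `claims_sim` (or a list with patients, visits, fills,
#'   vocab).
#' @param threshold Self-harm probability threshold (default 0.5).
#' @param impute Run [crossfit_probabilities()]? When FALSE, probabilities
#'   are 0 and only coded self-harm defines outcomes.
#' @param k Cross-validation folds.
#' @param seed Seed for fold assignment.
#' @param covariate_sets Named list of code sets for baseline covariates;
#'   defaults to the simulation's confounder codes when available.
#' @param covariates Baseline covariate columns to include in the model;
#'   default: names of `covariate_sets`.
#' @param min_intervals,min_events Regimen-retention requisites.
#' @param grace_days Exposure grace period.
#' @param model `"model1"`, `"model2"`, or `"none"` to skip fitting.
#' @param spline_vars,spline_df Spline settings.
#' @param min_support Feature support threshold for imputation.
#' @param lambda Ridge penalty for the classifier.
#' @return List with metavisits, staged, intervals, catalog, baseline,
#'   rows, and (unless skipped) the fitted model.
#' @export
run_pipeline <- function(sim, threshold = 0.5, impute = TRUE, k = 5,
                         seed = 1, covariate_sets = NULL, covariates = NULL,
                         min_intervals = 50, min_events = 5, grace_days = 30,
                         model = "model1",
                         spline_vars = c("age_at_index",
                                         "prior_unique_bd_drugs"),
                         spline_df = 4, min_support = 10, lambda = 1e-3) {
  vocab <- sim$vocab
  start_year <- sim$params$start_year %||% 2010
  mv <- build_meta_visits(sim$visits)
  mv <- label_coded_selfharm(mv, vocab)
  if (impute) {
    mv <- crossfit_probabilities(mv, sim$patients, vocab, k = k, seed = seed,
                                 min_support = min_support, lambda = lambda,
                                 start_year = start_year)
  } else {
    mv$selfharm_prob <- 0
    mv$fold <- NA_integer_
  }
  staged <- stage_patients(mv, sim$patients, vocab, threshold = threshold,
                           fills = sim$fills)
  iv <- assign_regimen_timeline(sim$fills, staged, vocab,
                                grace_days = grace_days)
  iv <- collapse_regimens(iv, min_intervals = min_intervals,
                          min_events = min_events)
  covariate_sets <- covariate_sets %||%
    (if (length(sim$confounder_codes))
       as.list(sim$confounder_codes) else list())
  bl <- extract_baseline_covariates(staged, mv, sim$fills, sim$patients,
                                    vocab, covariate_sets = covariate_sets,
                                    start_year = start_year)
  rows <- emit_counting_process(staged, iv, mv, sim$fills, vocab,
                                baseline = bl)
  out <- list(metavisits = mv, staged = staged, intervals = iv,
              catalog = attr(iv, "catalog"), baseline = bl, rows = rows)
  if (model != "none" && sum(rows$event) > 0) {
    covariates <- covariates %||% names(covariate_sets)
    out$model <- suppressWarnings(assemble_model(
      rows, model = model, covariates = covariates,
      spline_vars = spline_vars, spline_df = spline_df
    ))
  }
  out
}
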