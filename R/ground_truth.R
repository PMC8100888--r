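# Planted ground truth for the synthetic claims world.

#' Default planted confounders
#'
#' Two patient-level binary confounders that both raise the self-harm hazard
#' and tilt treatment assignment, creating the indication bias the factorial
#' covariate-selection procedure is designed to detect. `target` names the
#' regimen whose assignment weight is tilted for carriers; `NA` tilts all
#' drug regimens against "no drug".
#'
#' @return Tibble with columns name, prevalence, assign_effect,
#'   hazard_effect, target.
#' @export
default_confounders <- function() {
  tibble::tribble(
    ~name,             ~prevalence, ~assign_effect, ~hazard_effect, ~target,
    "substance_abuse", 0.20,        0.9,            0.8,            "LITHIUM+MSA",
    "prior_injury",    0.15,        0.7,            0.6,            NA_character_
  )
}

#' Planted ground truth for the synthetic claims generator
#'
#' Encodes the data-generating conditions: per-regimen log hazard ratios
#' versus lithium monotherapy, confounder effects on treatment assignment and
#' on the log hazard, the psychotherapy effect, the probability that a true
#' self-harm event receives an explicit self-harm code (the under-recording
#' phenomenon; roughly 1 event in 19 is coded in US claims), and the baseline
#' hazard of true self-harm events per person-day.
#'
#' Regimen labels are either `"no_drug"`, an agent name (monotherapy), or a
#' `+`-joined sorted set of drug-class names (combination therapy).
#'
#' @param regimen_log_hr Named numeric: planted log hazard ratio per regimen,
#'   relative to lithium monotherapy (which must be present with value 0).
#' @param regimen_base_weights Named numeric assignment weights, same names.
#' @param confounders Tibble as returned by [default_confounders()]; may have
#'   zero rows to switch confounding off.
#' @param psychotherapy_log_hr Log hazard ratio of psychotherapy exposure.
#' @param psychotherapy_prob Probability an exposure episode carries
#'   psychotherapy.
#' @param coding_fraction Probability in (0, 1] that a true event is coded.
#' @param baseline_hazard True-event hazard per person-day for a lithium
#'   interval with no confounders and no psychotherapy (>= 0; 0 gives a null
#'   event process).
#' @param seed Integer seed for the generator.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(regimen_log_hr = c(
                           "lithium" = 0, "lamotrigine" = -0.30,
                           "quetiapine" = 0.15, "haloperidol" = 0.50,
                           "LITHIUM+MSA" = 0.30, "no_drug" = -0.58
                         ),
                         regimen_base_weights = c(
                           "lithium" = 0.16, "lamotrigine" = 0.14,
                           "quetiapine" = 0.12, "haloperidol" = 0.06,
                           "LITHIUM+MSA" = 0.12, "no_drug" = 0.40
                         ),
                         confounders = default_confounders(),
                         psychotherapy_log_hr = log(0.59),
                         psychotherapy_prob = 0.35,
                         coding_fraction = 1 / 19,
                         baseline_hazard = 4e-5,
                         seed = 1) {
  if (!is.numeric(coding_fraction) || coding_fraction <= 0 || coding_fraction > 1) {
    stop("`coding_fraction` must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(baseline_hazard) || baseline_hazard < 0) {
    stop("`baseline_hazard` must be non-negative", call. = FALSE)
  }
  if (is.null(names(regimen_log_hr)) || !"lithium" %in% names(regimen_log_hr)) {
    stop("`regimen_log_hr` must be named and include the lithium reference",
         call. = FALSE)
  }
  if (!setequal(names(regimen_log_hr), names(regimen_base_weights))) {
    stop("`regimen_base_weights` must name the same regimens as `regimen_log_hr`",
         call. = FALSE)
  }
  regimen_base_weights <- regimen_base_weights[names(regimen_log_hr)]
  if (!is.null(confounders) && nrow(confounders) > 0) {
    stopifnot(all(c("name", "prevalence", "assign_effect", "hazard_effect",
                    "target") %in% names(confounders)))
  }
  structure(
    list(
      regimen_log_hr = regimen_log_hr,
      regimen_base_weights = regimen_base_weights,
      confounders = confounders %||% default_confounders()[0, ],
      psychotherapy_log_hr = psychotherapy_log_hr,
      psychotherapy_prob = psychotherapy_prob,
      coding_fraction = coding_fraction,
      baseline_hazard = baseline_hazard,
      seed = as.integer(seed)
    ),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>\n")
  cat("  regimens:", paste(names(x$regimen_log_hr), collapse = ", "), "\n")
  cat("  coding fraction:", format(x$coding_fraction, digits = 4),
      "  baseline hazard/day:", format(x$baseline_hazard, digits = 4), "\n")
  cat("  confounders:", if (nrow(x$confounders)) paste(x$confounders$name, collapse = ", ") else "none", "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# map a regimen label to the concrete agent set used when emitting fills
regimen_agents <- function(label, vocab) {
  if (label == "no_drug") return(character(0))
  drugs <- vocab$drugs
  if (label %in% drugs$agent) return(label)
  classes <- strsplit(label, "+", fixed = TRUE)[[1]]
  if (label %in% c("MULTI_MSA", "MULTI_SGA")) {
    cls <- sub("MULTI_", "", label)
    return(utils::head(drugs$agent[drugs$class == cls], 2))
  }
  if (!all(classes %in% drugs$class)) {
    stop("unknown regimen label: ", label, call. = FALSE)
  }
  # one agent per class, deterministically the first listed
  vapply(classes, function(cl) drugs$agent[drugs$class == cl][1], character(1))
}
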