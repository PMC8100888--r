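# Eligibility, the prespecified sequence of events, and baseline covariates.

#' Check cohort eligibility
#'
#' Inclusion: two or more bipolar-disorder diagnosis codes over the
#' observation period (occurrences summed across meta-visits). Exclusion:
#' any other major-mental-illness diagnosis (major depressive disorder,
#' schizophrenia, schizoaffective disorder) at any time.
#'
#' @param metavisits Meta-visits (codes list-column required).
#' @param vocab A `code_vocabulary`.
#' @param min_bd_codes Minimum BD code occurrences (default 2).
#' @return Tibble with patient_id, eligible (logical), reason
#'   (`NA` when eligible, else `insufficient_bd_codes` / `exclusion_mmi`).
#' @export
check_eligibility <- function(metavisits, vocab, min_bd_codes = 2) {
  stopifnot(inherits(vocab, "code_vocabulary"))
  bd <- codes_with_role(vocab, "bd_diagnosis")
  mmi <- codes_with_role(vocab, "exclusion_mmi")
  mv <- metavisits
  mv$.n_bd <- codes_count_in(mv$codes, bd)
  mv$.any_mmi <- codes_any_in(mv$codes, mmi)
  per <- dplyr::summarise(
    dplyr::group_by(mv, .data$patient_id),
    n_bd = sum(.data$.n_bd),
    any_mmi = any(.data$.any_mmi),
    .groups = "drop"
  )
  per$reason <- dplyr::case_when(
    per$any_mmi ~ "exclusion_mmi",
    per$n_bd < min_bd_codes ~ "insufficient_bd_codes",
    TRUE ~ NA_character_
  )
  tibble::tibble(
    patient_id = per$patient_id,
    eligible = is.na(per$reason),
    reason = per$reason
  )
}

#' Stage eligible patients through the prespecified sequence of events
#'
#' For each eligible patient, locates: (1) the index visit — the first
#' BD-coded meta-visit preceded by at least `lookback_days` days of
#' enrollment before its last day; (2) the index exposure day — the last
#' day of the index visit, which is time zero; (3) the first post-index
#' outcome meta-visit at the active threshold; and the earliest censoring
#' event among a self-harm-unrelated inpatient/ER meta-visit, the onset of
#' a censoring condition (censoring-condition diagnosis or anti-dementia
#' drug fill), and the end of enrollment. When several fall on the same
#' day, outcome takes precedence, then hospitalization, then condition.
#'
#' @param metavisits Meta-visits with `selfharm_prob` and `coded_selfharm`
#'   columns (see [crossfit_probabilities()]).
#' @param patients Patients tibble with enrollment columns.
#' @param vocab A `code_vocabulary`.
#' @param threshold Self-harm probability threshold defining outcomes.
#' @param fills Optional fills tibble (for anti-dementia censoring).
#' @param lookback_days Required enrollment days before the index exposure
#'   (default 365 = 12 months of continuous enrollment).
#' @return Tibble of staged patients: patient_id, index metavisit_id,
#'   index_start_day, index_exposure_day, observation_end_day, end_reason
#'   (`outcome`, `censor_hospitalization`, `censor_condition`,
#'   `end_of_observation`), and index-visit characteristics. Patients not
#'   staged are listed in `attr(, "not_staged")` with a reason.
#' @export
stage_patients <- function(metavisits, patients, vocab, threshold = 0.5,
                           fills = NULL, lookback_days = 365) {
  stopifnot(inherits(vocab, "code_vocabulary"))
  elig <- check_eligibility(metavisits, vocab)
  mv <- apply_threshold(metavisits, threshold)
  mv <- dplyr::inner_join(
    mv, patients[, c("patient_id", "enroll_start_day", "enroll_end_day")],
    by = "patient_id"
  )
  mv <- dplyr::arrange(mv, .data$patient_id, .data$start_day)
  bd <- codes_with_role(vocab, "bd_diagnosis")
  cen <- codes_with_role(vocab, "censoring_condition")
  mv$has_bd <- codes_any_in(mv$codes, bd)
  mv$has_cen <- codes_any_in(mv$codes, cen)

  keep <- elig$patient_id[elig$eligible]
  mv <- mv[mv$patient_id %in% keep, ]

  # first qualifying row per patient, fully vectorized: mv is sorted by
  # patient and start day, so the first non-duplicated hit per patient wins
  pid_all <- unique(mv$patient_id)
  first_row_per_patient <- function(cond) {
    rows <- which(cond)
    rows <- rows[!duplicated(mv$patient_id[rows])]
    out <- rep(NA_integer_, length(pid_all))
    out[match(mv$patient_id[rows], pid_all)] <- rows
    out
  }
  ix <- first_row_per_patient(
    mv$has_bd & (mv$end_day - mv$enroll_start_day) >= lookback_days
  )
  index_exposure <- mv$end_day[ix]
  t0_of_row <- index_exposure[match(mv$patient_id, pid_all)]
  post <- !is.na(t0_of_row) & mv$start_day > t0_of_row
  r_out <- first_row_per_patient(post & mv$outcome)
  r_hosp <- first_row_per_patient(post & mv$has_inpatient_or_er & !mv$outcome)
  r_cen <- first_row_per_patient(post & mv$has_cen)
  safe_ix <- ifelse(is.na(ix), 1L, ix)
  per <- tibble::tibble(
    patient_id = pid_all,
    .ix = ix,
    index_metavisit_id = mv$metavisit_id[ix],
    index_start_day = mv$start_day[ix],
    index_exposure_day = index_exposure,
    outpatient_in_index = !is.na(ix) &
      vapply(mv$settings[safe_ix], function(s) "outpatient" %in% s,
             logical(1)),
    inpatient_er_in_index = !is.na(ix) & mv$has_inpatient_or_er[safe_ix],
    index_codes = mv$codes[safe_ix],
    d_out = mv$start_day[r_out],
    d_hosp = mv$start_day[r_hosp],
    d_cen = mv$start_day[r_cen],
    enroll_start_day = mv$enroll_start_day[!duplicated(mv$patient_id)],
    enroll_end_day = mv$enroll_end_day[!duplicated(mv$patient_id)]
  )

  # anti-dementia fills after the index day censor at the fill day
  d_adem <- rep(NA_real_, nrow(per))
  if (!is.null(fills) && nrow(fills) > 0) {
    adem <- fills[fills$drug_id %in% vocab$antidementia$drug_id, ]
    if (nrow(adem) > 0) {
      ad <- dplyr::inner_join(adem,
                              per[, c("patient_id", "index_exposure_day")],
                              by = "patient_id")
      ad <- ad[!is.na(ad$index_exposure_day) &
                 ad$fill_day > ad$index_exposure_day, ]
      if (nrow(ad) > 0) {
        adm <- dplyr::summarise(dplyr::group_by(ad, .data$patient_id),
                                d = min(.data$fill_day), .groups = "drop")
        d_adem[match(adm$patient_id, per$patient_id)] <- adm$d
      }
    }
  }
  d_cond <- pmin(per$d_cen, d_adem, na.rm = TRUE)

  cand <- cbind(outcome = per$d_out, censor_hospitalization = per$d_hosp,
                censor_condition = d_cond,
                end_of_observation = per$enroll_end_day)
  cand[is.na(cand)] <- Inf
  end_day <- do.call(pmin, as.data.frame(cand))
  reason_idx <- max.col(-cand, ties.method = "first")  # column order = precedence
  reason <- colnames(cand)[reason_idx]

  has_index <- !is.na(per$.ix)
  has_follow <- has_index & end_day > per$index_exposure_day
  not_staged <- dplyr::bind_rows(
    elig[!elig$eligible, c("patient_id", "reason")],
    tibble::tibble(patient_id = per$patient_id[!has_index],
                   reason = "no_index"),
    tibble::tibble(patient_id = per$patient_id[has_index & !has_follow],
                   reason = "no_followup")
  )

  staged <- per[has_follow, ]
  staged$observation_end_day <- end_day[has_follow]
  staged$end_reason <- reason[has_follow]
  staged$.ix <- NULL
  staged$d_out <- NULL; staged$d_hosp <- NULL; staged$d_cen <- NULL
  staged <- staged[, c("patient_id", "index_metavisit_id", "index_start_day",
                       "index_exposure_day", "observation_end_day",
                       "end_reason", "outpatient_in_index",
                       "inpatient_er_in_index", "index_codes",
                       "enroll_start_day", "enroll_end_day")]
  attr(staged, "not_staged") <- not_staged
  attr(staged, "threshold") <- threshold
  staged
}

#' Extract baseline covariates from the one-year lookback window
#'
#' Binary presence of configured code sets within
#' `[index_exposure_day - 365, index_exposure_day - 1]`, plus prior coded
#' self-harm, prior hospitalization/ER, sex, age at index, the number of
#' unique BD drugs filled during the lookback, and index-visit
#' characteristics (mood polarity from the BD codes of the index meta-visit
#' with an explicit unknown-polarity indicator, and outpatient presence).
#'
#' @param staged Output of [stage_patients()].
#' @param metavisits Labeled meta-visits.
#' @param fills Fills tibble.
#' @param patients Patients tibble.
#' @param vocab A `code_vocabulary`.
#' @param covariate_sets Named list of code vectors; each yields one binary
#'   covariate (presence of any of its codes in the lookback window).
#' @param start_year Calendar year of day 0.
#' @return Tibble, one row per staged patient, with one column per
#'   covariate.
#' @export
extract_baseline_covariates <- function(staged, metavisits, fills, patients,
                                        vocab, covariate_sets = list(),
                                        start_year = 2010) {
  stopifnot(inherits(vocab, "code_vocabulary"))
  sh <- codes_with_role(vocab, "self_harm")
  mv <- dplyr::inner_join(
    metavisits[, c("patient_id", "start_day", "codes", "has_inpatient_or_er",
                   "coded_selfharm")],
    staged[, c("patient_id", "index_exposure_day")],
    by = "patient_id"
  )
  look <- mv[mv$start_day >= mv$index_exposure_day - 365 &
               mv$start_day <= mv$index_exposure_day - 1, ]
  per <- dplyr::summarise(
    dplyr::group_by(look, .data$patient_id),
    prior_self_harm = as.numeric(any(.data$coded_selfharm)),
    prior_hospitalization = as.numeric(any(.data$has_inpatient_or_er)),
    lookback_codes = list(unique(unlist(.data$codes))),
    .groups = "drop"
  )
  out <- dplyr::left_join(
    staged[, c("patient_id", "index_exposure_day", "index_codes",
               "outpatient_in_index")],
    per, by = "patient_id"
  )
  out$prior_self_harm[is.na(out$prior_self_harm)] <- 0
  out$prior_hospitalization[is.na(out$prior_hospitalization)] <- 0
  empty <- vapply(out$lookback_codes, is.null, logical(1))
  out$lookback_codes[empty] <- list(character(0))

  for (nm in names(covariate_sets)) {
    set <- covariate_sets[[nm]]
    out[[nm]] <- vapply(out$lookback_codes, function(cd) as.numeric(any(cd %in% set)),
                        numeric(1))
  }

  # index-visit mood polarity from BD code subtypes
  subtypes <- stats::setNames(vocab$codes$subtype, vocab$codes$code)
  pol <- vapply(out$index_codes, function(cd) {
    st <- stats::na.omit(unname(subtypes[cd[cd %in% names(subtypes)]]))
    if ("depression" %in% st) "depression" else if ("mania" %in% st) "mania"
    else "unknown"
  }, character(1))
  out$index_depression <- as.numeric(pol == "depression")
  out$index_mania <- as.numeric(pol == "mania")
  out$polarity_unknown <- as.numeric(pol == "unknown")
  out$outpatient_in_index <- as.numeric(out$outpatient_in_index)

  demo <- patients[, c("patient_id", "sex", "birth_year")]
  out <- dplyr::left_join(out, demo, by = "patient_id")
  out$male <- as.numeric(out$sex == "M")
  out$age_at_index <- (start_year + out$index_exposure_day %/% 365) -
    out$birth_year

  bd_drugs <- vocab$drugs$drug_id
  fl <- dplyr::inner_join(
    fills[fills$drug_id %in% bd_drugs, ],
    staged[, c("patient_id", "index_exposure_day")], by = "patient_id"
  )
  fl <- fl[fl$fill_day >= fl$index_exposure_day - 365 &
             fl$fill_day <= fl$index_exposure_day - 1, ]
  nprior <- dplyr::summarise(dplyr::group_by(fl, .data$patient_id),
                             prior_unique_bd_drugs = dplyr::n_distinct(.data$drug_id),
                             .groups = "drop")
  out <- dplyr::left_join(out, nprior, by = "patient_id")
  out$prior_unique_bd_drugs[is.na(out$prior_unique_bd_drugs)] <- 0
  out$lookback_codes <- NULL
  out$index_codes <- NULL
  out$sex <- NULL
  out$birth_year <- NULL
  out
}
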