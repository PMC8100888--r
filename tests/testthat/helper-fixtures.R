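# Shared fixtures, built in code at test time.

# hand-built vocabulary with a simple parent chain A -> B -> C among the
# background codes, for closure and feature tests
chain_vocab <- function() {
  structure(
    list(
      codes = tibble::tibble(
        code = c("A", "B", "C", "SH1", "SH_ROOT", "PX1", "BD1", "BD2",
                 "BD3", "MMI1", "CEN1", "PSY1"),
        role = c("background", "background", "background", "self_harm",
                 "self_harm", "proxy_injury", "bd_diagnosis", "bd_diagnosis",
                 "bd_diagnosis", "exclusion_mmi", "censoring_condition",
                 "psychotherapy_procedure"),
        depth = c(3L, 2L, 1L, 2L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L),
        subtype = c(NA, NA, NA, NA, NA, NA, "depression", "mania",
                    NA, NA, NA, NA)
      ),
      parent_links = tibble::tibble(
        code = c("A", "B", "SH1"),
        parent = c("B", "C", "SH_ROOT")
      ),
      drugs = harmimpute:::default_drug_table(),
      antidementia = tibble::tibble(drug_id = "D90", agent = "donepezil")
    ),
    class = "code_vocabulary"
  )
}

mk_visits <- function(patient_id, setting, start_day, end_day = start_day,
                      codes = list(character(0))) {
  tibble::tibble(patient_id = patient_id, setting = setting,
                 start_day = start_day, end_day = end_day,
                 codes = codes)
}

mk_patients <- function(ids, enroll_start = 0, enroll_end = 2000,
                        sex = "F", birth_year = 1980) {
  tibble::tibble(patient_id = ids, sex = sex, birth_year = birth_year,
                 enroll_start_day = enroll_start, enroll_end_day = enroll_end)
}

# a staged-patient row without running the staging machinery, for driving
# the exposure module directly
mk_staged <- function(patient_id, index_exposure_day, observation_end_day,
                      end_reason = "end_of_observation") {
  tibble::tibble(
    patient_id = patient_id,
    index_metavisit_id = paste0(patient_id, "_1"),
    index_start_day = index_exposure_day,
    index_exposure_day = index_exposure_day,
    observation_end_day = observation_end_day,
    end_reason = end_reason,
    outpatient_in_index = TRUE, inpatient_er_in_index = FALSE,
    index_codes = list(character(0)),
    enroll_start_day = 0, enroll_end_day = observation_end_day
  )
}

mk_fills <- function(patient_id, drug_id, fill_day, days_supply) {
  tibble::tibble(patient_id = patient_id, drug_id = drug_id,
                 fill_day = fill_day, days_supply = as.integer(days_supply))
}

# ground truth for parameter-recovery worlds: two active regimens plus
# drug-free periods, no confounding, fully coded outcomes
recovery_gt <- function(seed, lam = -0.4, nodrug = -0.58,
                        baseline_hazard = 6e-5, coding_fraction = 1) {
  ground_truth(
    regimen_log_hr = c(lithium = 0, lamotrigine = lam, no_drug = nodrug),
    regimen_base_weights = c(lithium = 0.4, lamotrigine = 0.3, no_drug = 0.3),
    confounders = default_confounders()[0, ],
    coding_fraction = coding_fraction,
    baseline_hazard = baseline_hazard, seed = seed
  )
}

# sparse-utilization population for recovery experiments (classifier bypassed)
recovery_sim <- function(gt, vocab, n_patients, seed) {
  simulate_population(gt, vocab, n_patients = n_patients, seed = seed,
                      outpatient_rate = 1 / 365,
                      nonevent_hosp_rate = 0.08 / 365)
}

# simple exponential-survival counting-process rows with a known log-hazard
# function of a single covariate; censoring at a fixed horizon
sim_simple_rows <- function(n, loghr_fun, censor = 3, seed = 1) {
  set.seed(seed)
  x <- runif(n, 20, 80)
  rate <- 0.2 * exp(loghr_fun(x))
  t <- rexp(n, rate)
  tibble::tibble(
    start = 0, stop = pmin(t, censor), event = t <= censor, age = x
  )
}

shared_test_vocab <- local({
  v <- NULL
  function() {
    if (is.null(v)) v <<- generate_vocabulary(seed = 42)
    v
  }
})

# independent partial-likelihood oracle for a single binary covariate on
# right-censored (start, stop, event] rows, evaluated over a fine grid
grid_search_loglik <- function(rows, z, grid = seq(-2, 2, by = 1e-5)) {
  ev_times <- sort(rows$stop[rows$event])
  ll <- vapply(grid, function(b) {
    s <- 0
    for (t in ev_times) {
      at_risk <- rows$start < t & rows$stop >= t
      dead <- rows$event & rows$stop == t
      s <- s + sum(b * z[dead & at_risk]) -
        sum(dead & at_risk) * log(sum(exp(b * z[at_risk])))
    }
    s
  }, numeric(1))
  grid[which.max(ll)]
}

four_subject_rows <- function() {
  tibble::tibble(start = 0, stop = c(1, 3, 2, 2),
                 event = c(TRUE, TRUE, FALSE, TRUE),
                 z = c(1, 0, 1, 0))
}

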