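mk_labeled <- function(visits, vocab) {
  mv <- label_coded_selfharm(build_meta_visits(visits), vocab)
  mv$selfharm_prob <- 0
  mv$fold <- NA_integer_
  mv
}

test_that("eligibility requires two BD codes and no excluding diagnosis", {
  vocab <- chain_vocab()
  v <- dplyr::bind_rows(
    mk_visits("P1", "outpatient", 10, 10, list("BD1")),            # one code
    mk_visits("P2", "outpatient", 10, 10, list("BD1")),
    mk_visits("P2", "outpatient", 100, 100, list(c("BD2", "A"))),
    mk_visits("P3", "outpatient", 10, 10, list(c("BD1", "BD2"))),
    mk_visits("P3", "outpatient", 50, 50, list("BD1")),
    mk_visits("P3", "outpatient", 900, 900, list("MMI1"))          # excluded
  )
  mv <- mk_labeled(v, vocab)
  el <- check_eligibility(mv, vocab)
  el <- el[order(el$patient_id), ]
  expect_equal(el$eligible, c(FALSE, TRUE, FALSE))
  expect_equal(el$reason, c("insufficient_bd_codes", NA, "exclusion_mmi"))
})

test_that("the index visit is the first BD meta-visit with a full lookback", {
  vocab <- chain_vocab()
  # first BD meta-visit has only 200 days of prior enrollment, the second 400
  v <- dplyr::bind_rows(
    mk_visits("P1", "outpatient", 200, 200, list("BD1")),
    mk_visits("P1", "outpatient", 400, 400, list("BD2")),
    mk_visits("P1", "outpatient", 800, 800, list("A"))
  )
  mv <- mk_labeled(v, vocab)
  st <- stage_patients(mv, mk_patients("P1"), vocab, threshold = 0.5)
  expect_equal(nrow(st), 1)
  expect_equal(st$index_exposure_day, 400)
  expect_equal(st$end_reason, "end_of_observation")
  expect_equal(st$observation_end_day, 2000)
})

test_that("non-outcome hospitalization and censoring conditions end follow-up", {
  vocab <- chain_vocab()
  base <- dplyr::bind_rows(
    mk_visits("P1", "outpatient", 100, 100, list("BD1")),
    mk_visits("P1", "outpatient", 400, 400, list("BD2"))
  )
  # plain hospitalization at day 700 (no self-harm code)
  v1 <- dplyr::bind_rows(base, mk_visits("P1", "inpatient", 700, 702, list("A")))
  st1 <- stage_patients(mk_labeled(v1, vocab), mk_patients("P1"), vocab, 0.5)
  expect_equal(st1$end_reason, "censor_hospitalization")
  expect_equal(st1$observation_end_day, 700)
  # coded self-harm hospitalization at day 700 is an outcome instead
  v2 <- dplyr::bind_rows(base, mk_visits("P1", "inpatient", 700, 702,
                                         list(c("SH1", "PX1"))))
  st2 <- stage_patients(mk_labeled(v2, vocab), mk_patients("P1"), vocab, 0.5)
  expect_equal(st2$end_reason, "outcome")
  # censoring-condition onset before any outcome
  v3 <- dplyr::bind_rows(base, mk_visits("P1", "outpatient", 600, 600,
                                         list("CEN1")),
                         mk_visits("P1", "inpatient", 700, 700,
                                   list(c("SH1", "PX1"))))
  st3 <- stage_patients(mk_labeled(v3, vocab), mk_patients("P1"), vocab, 0.5)
  expect_equal(st3$end_reason, "censor_condition")
  expect_equal(st3$observation_end_day, 600)
  # an anti-dementia fill censors at the fill day
  st4 <- stage_patients(mk_labeled(v1, vocab), mk_patients("P1"), vocab, 0.5,
                        fills = mk_fills("P1", "D90", 550, 30))
  expect_equal(st4$end_reason, "censor_condition")
  expect_equal(st4$observation_end_day, 550)
})

test_that("imputed probabilities create outcomes only above the threshold", {
  vocab <- chain_vocab()
  v <- dplyr::bind_rows(
    mk_visits("P1", "outpatient", 100, 100, list("BD1")),
    mk_visits("P1", "outpatient", 400, 400, list("BD2")),
    mk_visits("P1", "ER", 800, 800, list("PX1"))
  )
  mv <- mk_labeled(v, vocab)
  mv$selfharm_prob[mv$start_day == 800] <- 0.7
  st_low <- stage_patients(mv, mk_patients("P1"), vocab, threshold = 0.5)
  st_high <- stage_patients(mv, mk_patients("P1"), vocab, threshold = 0.9)
  expect_equal(st_low$end_reason, "outcome")
  expect_equal(st_high$end_reason, "censor_hospitalization")
})

test_that("staging invariants hold on a simulated population", {
  vocab <- shared_test_vocab()
  gt <- ground_truth(coding_fraction = 0.4, baseline_hazard = 3e-4, seed = 47)
  sim <- simulate_population(gt, vocab, n_patients = 600, seed = 47)
  mv <- label_coded_selfharm(build_meta_visits(sim$visits), vocab)
  mv <- crossfit_probabilities(mv, sim$patients, vocab, k = 5, seed = 8)
  st <- stage_patients(mv, sim$patients, vocab, threshold = 0.5,
                       fills = sim$fills)
  # every staged patient has a full lookback before the index exposure
  expect_true(all(st$index_exposure_day - st$enroll_start_day >= 365))
  expect_true(all(st$observation_end_day > st$index_exposure_day))
  expect_true(all(st$end_reason[st$end_reason == "outcome"] == "outcome"))
  # staged set invariant to meta-visit input ordering
  set.seed(2)
  st2 <- stage_patients(mv[sample(nrow(mv)), ], sim$patients, vocab,
                        threshold = 0.5, fills = sim$fills)
  st2 <- st2[match(st$patient_id, st2$patient_id), ]
  expect_equal(st$observation_end_day, st2$observation_end_day)
  expect_equal(st$end_reason, st2$end_reason)
  # raising the threshold never adds outcome patients
  st_hi <- stage_patients(mv, sim$patients, vocab, threshold = 0.9,
                          fills = sim$fills)
  out_lo <- st$patient_id[st$end_reason == "outcome"]
  out_hi <- st_hi$patient_id[st_hi$end_reason == "outcome"]
  expect_true(all(out_hi %in% out_lo))
})

test_that("baseline covariates summarize the lookback year", {
  vocab <- chain_vocab()
  v <- dplyr::bind_rows(
    mk_visits("P1", "outpatient", 50, 50, list("BD1")),
    mk_visits("P1", "inpatient", 300, 300, list(c("SH1", "PX1"))),  # 100d pre
    mk_visits("P1", "outpatient", 350, 350, list("A")),
    mk_visits("P1", "outpatient", 400, 400, list("BD1")),           # index
    mk_visits("P2", "outpatient", 50, 50, list("BD2")),
    mk_visits("P2", "outpatient", 420, 420, list("BD2")),           # index
    mk_visits("P3", "outpatient", 60, 60, list("BD3")),
    mk_visits("P3", "outpatient", 430, 430, list("BD3"))            # index
  )
  mv <- mk_labeled(v, vocab)
  pats <- mk_patients(c("P1", "P2", "P3"), birth_year = c(1990, 1960, 1975),
                      sex = c("F", "M", "F"))
  st <- stage_patients(mv, pats, vocab, threshold = 0.5)
  fills <- mk_fills("P1", c("D01", "D03"), c(100, 200), 30)
  bl <- extract_baseline_covariates(st, mv, fills, pats, vocab,
                                    covariate_sets = list(has_A = "A"))
  bl <- bl[order(bl$patient_id), ]
  expect_equal(bl$prior_self_harm, c(1, 0, 0))
  expect_equal(bl$prior_hospitalization, c(1, 0, 0))
  expect_equal(bl$has_A, c(1, 0, 0))
  expect_equal(bl$male, c(0, 1, 0))
  expect_equal(bl$prior_unique_bd_drugs, c(2, 0, 0))
  # index polarity from the BD code subtype; absence means unknown
  expect_equal(bl$index_depression, c(1, 0, 0))  # BD1 is the depression code
  expect_equal(bl$index_mania, c(0, 1, 0))       # BD2 is the mania code
  expect_equal(bl$polarity_unknown, c(0, 0, 1))  # BD3 carries no polarity
  expect_equal(bl$outpatient_in_index, c(1, 1, 1))
  expect_equal(bl$age_at_index,
               c(2010 + 1 - 1990, 2010 + 1 - 1960, 2010 + 1 - 1975))
})
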