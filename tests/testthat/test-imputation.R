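test_that("features expand codes to ancestors and exclude the label leak", {
  vocab <- chain_vocab()
  mv <- build_meta_visits(dplyr::bind_rows(
    mk_visits("P1", "ER", 1, 1, list("A")),
    mk_visits("P1", "ER", 50, 50, list(c("SH1", "PX1"))),
    mk_visits("P2", "ER", 1, 1, list("A"))
  ))
  mv <- label_coded_selfharm(mv, vocab)
  pats <- mk_patients(c("P1", "P2"))
  fb <- build_features(mv, pats, vocab, min_support = 1)
  x <- as.matrix(fb$x)
  # leaf A lights up A, B and C through the hierarchy
  expect_equal(unname(x[1, c("A", "B", "C")]), c(1, 1, 1))
  # the self-harm code and its exclusive ancestors never appear as features
  expect_false(any(c("SH1", "SH_ROOT") %in% colnames(x)))
  expect_true("PX1" %in% colnames(x))
  # identical codes/age/sex/year give identical vectors
  expect_equal(unname(x[1, ]), unname(x[3, ]))
})

test_that("feature support filtering drops rare codes", {
  vocab <- chain_vocab()
  mv <- build_meta_visits(dplyr::bind_rows(
    mk_visits(paste0("P", 1:5), "ER", 1:5, 1:5,
              c(list("A"), rep(list("C"), 4)))
  ))
  mv <- label_coded_selfharm(mv, vocab)
  fb <- build_features(mv, mk_patients(paste0("P", 1:5)), vocab,
                       min_support = 5)
  # A and B appear once each, C five times (own + ancestor occurrences)
  expect_true("C" %in% colnames(fb$x))
  expect_false(any(c("A", "B") %in% colnames(fb$x)))
  expect_error(build_features(mv, mk_patients("P1"), vocab),
               "unknown patients")
})

test_that("cross-fitted probabilities honor the out-of-fold discipline", {
  vocab <- shared_test_vocab()
  gt <- ground_truth(coding_fraction = 0.5, baseline_hazard = 1.5e-4, seed = 31)
  sim <- simulate_population(gt, vocab, n_patients = 1600, seed = 31)
  mv <- label_coded_selfharm(build_meta_visits(sim$visits), vocab)
  scored <- crossfit_probabilities(mv, sim$patients, vocab, k = 5, seed = 8)
  in_er <- scored$has_inpatient_or_er
  # outpatient-only meta-visits get probability zero and no fold
  expect_true(all(scored$selfharm_prob[!in_er] == 0))
  expect_true(all(is.na(scored$fold[!in_er])))
  # every fold holds both classes (stratification audit)
  tab <- table(scored$fold[in_er], scored$coded_selfharm[in_er])
  expect_equal(nrow(tab), 5)
  expect_true(all(tab > 0))
  expect_true(all(scored$selfharm_prob >= 0 & scored$selfharm_prob <= 1))
  # deterministic for a fixed seed
  scored2 <- crossfit_probabilities(mv, sim$patients, vocab, k = 5, seed = 8)
  expect_identical(scored$selfharm_prob, scored2$selfharm_prob)
  # a strong proxy bundle supports high cross-validated AUC, as in real
  # claims where self-harm has strong injury-code correlates
  auc <- rank_auc(scored$selfharm_prob[in_er], scored$coded_selfharm[in_er])
  expect_gte(auc, 0.95)
})

test_that("permuted labels yield chance-level cross-validated AUC", {
  vocab <- shared_test_vocab()
  gt <- ground_truth(coding_fraction = 0.5, baseline_hazard = 3e-4, seed = 37)
  sim <- simulate_population(gt, vocab, n_patients = 900, seed = 37)
  mv <- label_coded_selfharm(build_meta_visits(sim$visits), vocab)
  in_er <- which(mv$has_inpatient_or_er)
  set.seed(99)
  mv$coded_selfharm[in_er] <- sample(mv$coded_selfharm[in_er])
  scored <- crossfit_probabilities(mv, sim$patients, vocab, k = 5, seed = 8)
  auc <- rank_auc(scored$selfharm_prob[in_er], scored$coded_selfharm[in_er])
  expect_lt(abs(auc - 0.5), 0.05)
})

test_that("crossfit refuses degenerate class counts and supports patient folds", {
  vocab <- shared_test_vocab()
  gt <- ground_truth(coding_fraction = 0.5, baseline_hazard = 3e-4, seed = 41)
  sim <- simulate_population(gt, vocab, n_patients = 400, seed = 41)
  mv <- label_coded_selfharm(build_meta_visits(sim$visits), vocab)
  mv0 <- mv
  mv0$coded_selfharm <- FALSE
  expect_error(crossfit_probabilities(mv0, sim$patients, vocab, k = 5),
               "class-1")
  scored <- crossfit_probabilities(mv, sim$patients, vocab, k = 3, seed = 8,
                                   fold_level = "patient")
  pid_folds <- tapply(scored$fold[scored$has_inpatient_or_er],
                      scored$patient_id[scored$has_inpatient_or_er],
                      function(f) length(unique(f)))
  expect_true(all(pid_folds == 1))
})

test_that("thresholding is a strict inequality with coded events always in", {
  mv <- tibble::tibble(
    patient_id = c("P1", "P2", "P3", "P4"),
    has_inpatient_or_er = c(TRUE, TRUE, TRUE, FALSE),
    coded_selfharm = c(FALSE, TRUE, FALSE, FALSE),
    selfharm_prob = c(0.5, 0.1, 0.51, 0.99)
  )
  out <- apply_threshold(mv, 0.5)
  # p = 0.5 at t = 0.5 is NOT an outcome ("over" the threshold is strict)
  expect_equal(out$outcome, c(FALSE, TRUE, TRUE, FALSE))
  # coded meta-visits are outcomes at every threshold
  expect_true(apply_threshold(mv, 0.9)$outcome[2])
  # at t = 1 the outcome set is exactly the coded set
  expect_equal(apply_threshold(mv, 1)$outcome, mv$coded_selfharm)
  expect_error(apply_threshold(mv, 1.2), "\\[0, 1\\]")
})

test_that("outcome sets are nested across thresholds", {
  vocab <- shared_test_vocab()
  gt <- ground_truth(coding_fraction = 0.4, baseline_hazard = 3e-4, seed = 43)
  sim <- simulate_population(gt, vocab, n_patients = 700, seed = 43)
  mv <- label_coded_selfharm(build_meta_visits(sim$visits), vocab)
  mv <- crossfit_probabilities(mv, sim$patients, vocab, k = 5, seed = 8)
  prev <- NULL
  for (t in c(0.2, 0.4, 0.6, 0.8, 0.95, 1)) {
    cur <- which(apply_threshold(mv, t)$outcome)
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("classification metrics reproduce hand-computed confusion tables", {
  # perfect classifier
  m <- classification_metrics(counts = c(tp = 10, fn = 0, fp = 0, tn = 50))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$mcc, 1)
  # empty classes give undefined metrics, not zero
  m0 <- classification_metrics(counts = c(tp = 0, fn = 0, fp = 3, tn = 5))
  expect_true(is.na(m0$sensitivity))
  # MCC equals a brute-force computation on random confusion tables
  set.seed(7)
  for (i in 1:20) {
    cc <- sample(0:200, 4, replace = TRUE)
    m <- classification_metrics(counts = c(tp = cc[1], fn = cc[2],
                                           fp = cc[3], tn = cc[4]))
    tp <- cc[1]; fn <- cc[2]; fp <- cc[3]; tn <- cc[4]
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    mcc_bf <- if (den == 0) NA_real_ else (tp * tn - fp * fn) / den
    expect_equal(m$mcc, mcc_bf, tolerance = 1e-12)
  }
})

test_that("the rank-statistic AUC matches an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  y <- rbinom(300, 1, 0.2)
  p <- runif(300) + 0.3 * y
  ours <- rank_auc(p, y)
  ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
  expect_true(is.na(rank_auc(p, rep(1, 300))))
})
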