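test_that("the four-subject fixture recovers the closed-form coefficient", {
  rows <- four_subject_rows()
  fit <- fit_cox(rows, "z")
  expect_equal(unname(coef(fit$fit)), 0.5 * log(2), tolerance = 1e-6)
  # and matches the grid-search partial-likelihood oracle
  oracle <- grid_search_loglik(rows, rows$z)
  expect_equal(unname(coef(fit$fit)), oracle, tolerance = 1e-4)
  # fitted partial likelihood improves on the null
  g <- glance(fit)
  expect_gte(g$loglik, g$loglik_null)
  td <- tidy(fit)
  expect_equal(td$hr, sqrt(2), tolerance = 1e-6)
  expect_equal(td$conf.low, exp(td$estimate - 1.96 * td$std.error))
})

test_that("degenerate inputs are rejected by name", {
  rows <- four_subject_rows()
  rows$flat <- 1
  expect_error(fit_cox(rows, c("z", "flat")), "flat")
  rows0 <- rows
  rows0$event <- FALSE
  expect_error(fit_cox(rows0, "z"), "no events")
  expect_error(fit_cox(rows, "missing_col"), "missing_col")
})

test_that("Benjamini-Yekutieli matches direct evaluation and p.adjust", {
  p <- c(0.001, 0.02, 0.04, 0.5)
  by <- benjamini_yekutieli(p, q = 0.05)
  # direct formula: c(4) = 25/12, thresholds k * 0.05 / (4 * c(4))
  cm <- sum(1 / (1:4))
  expect_equal(by$thresholds, (1:4) * 0.05 / (4 * cm))
  expect_equal(round(by$thresholds, 3), c(0.006, 0.012, 0.018, 0.024))
  expect_equal(by$reject, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(by$k, 1L)
  expect_equal(by$p_cutoff, 0.001)
  # degenerate inputs
  expect_equal(sum(benjamini_yekutieli(rep(1, 5))$reject), 0)
  expect_equal(sum(benjamini_yekutieli(p, q = 0)$reject), 0)
  expect_equal(benjamini_yekutieli(numeric(0))$k, 0L)
  expect_error(benjamini_yekutieli(c(0.5, 1.2)), "\\[0, 1\\]")
  # agreement with stats::p.adjust and nesting inside Benjamini-Hochberg
  set.seed(4)
  for (i in 1:10) {
    ps <- runif(20)^2
    by_i <- benjamini_yekutieli(ps, q = 0.05)
    expect_equal(by_i$reject, p.adjust(ps, "BY") <= 0.05)
    bh <- p.adjust(ps, "BH") <= 0.05
    expect_true(all(!by_i$reject | bh))  # BY rejections are a subset of BH
  }
})

test_that("spline terms expose a reference-anchored hazard-ratio curve", {
  rows <- sim_simple_rows(800, function(x) 0.03 * (x - 50), seed = 21)
  rows <- add_spline(rows, "age", df = 4, reference_value = 50)
  fit <- fit_cox(rows, spline_term_names(rows, "age"))
  curve <- spline_hazard_curve(fit, "age")
  at_ref <- curve[curve$x == 50, ]
  expect_equal(at_ref$hr, 1)
  expect_equal(at_ref$conf.low, 1)
  expect_equal(at_ref$conf.high, 1)
  expect_true(all(curve$conf.low <= curve$hr & curve$hr <= curve$conf.high))
  # with too few distinct values the term degrades to linear
  rows2 <- tibble::tibble(start = 0, stop = 1:8,
                          event = rep(c(TRUE, FALSE), 4),
                          age = rep(c(30, 50), 4))
  expect_warning(rows2 <- add_spline(rows2, "age", df = 4), "linear term")
  expect_equal(spline_term_names(rows2, "age"), "age_lin")
})

test_that("nonlinear spline components keep their nominal null size", {
  # pure linear hazard: the joint nonlinear test should reject at ~5%
  pvals <- vapply(1:50, function(r) {
    rows <- sim_simple_rows(250, function(x) 0.02 * (x - 50), seed = 100 + r)
    rows <- add_spline(rows, "age", df = 4)
    fit <- fit_cox(rows, spline_term_names(rows, "age"))
    spline_joint_test(fit, "age")$p.value
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_lte(rate, 0.14)  # 0.05 + 3 binomial sigma at 50 replicates
})

test_that("a planted U-shaped age effect is recovered by the spline fit", {
  rows <- sim_simple_rows(5000, function(x) 0.0015 * (x - 50)^2, seed = 33)
  rows <- add_spline(rows, "age", df = 4, reference_value = 50)
  fit <- fit_cox(rows, spline_term_names(rows, "age"))
  curve <- spline_hazard_curve(fit, "age",
                               at = seq(25, 75, by = 0.5))
  expect_lt(abs(curve$x[which.min(curve$log_hr)] - 50), 10)
  # strongly nonlinear: the joint test rejects
  expect_lt(spline_joint_test(fit, "age")$p.value, 0.01)
})

test_that("model 2 partitions person-time into four treatment categories", {
  vocab <- shared_test_vocab()
  gt <- ground_truth(coding_fraction = 1, baseline_hazard = 3e-4, seed = 51)
  sim <- simulate_population(gt, vocab, n_patients = 800, seed = 51)
  pl <- run_pipeline(sim, threshold = 1, impute = FALSE, model = "model2",
                     min_intervals = 20, min_events = 3)
  m2 <- pl$model
  expect_s3_class(m2, "harm_cox_model")
  rows <- m2$rows
  pt_by_cat <- tapply(rows$stop - rows$start, rows$treat4, sum)
  expect_equal(sum(pt_by_cat), sum(rows$stop - rows$start))
  expect_equal(length(pt_by_cat), 4)
  # category assignment matches the regimen/psychotherapy cross
  expect_true(all(
    (rows$treat4 == "no_treatment") ==
      (rows$regimen == "no_drug" & rows$psychotherapy == 0)
  ))
  expect_true(all(
    (rows$treat4 == "psychotherapy_and_pharmacotherapy") ==
      (rows$regimen != "no_drug" & rows$psychotherapy == 1)
  ))
})

test_that("a planted protective psychotherapy effect surfaces in model 2", {
  vocab <- shared_test_vocab()
  gt <- ground_truth(coding_fraction = 1, baseline_hazard = 4e-4, seed = 53,
                     psychotherapy_log_hr = log(0.45),
                     psychotherapy_prob = 0.45)
  sim <- simulate_population(gt, vocab, n_patients = 3000, seed = 53,
                             outpatient_rate = 2 / 365)
  pl <- run_pipeline(sim, threshold = 1, impute = FALSE, model = "model2",
                     min_intervals = 20, min_events = 3)
  tab <- tidy(pl$model)
  psy <- tab[tab$term == "treat4psychotherapy_alone", ]
  expect_lt(psy$hr, 1)
  expect_lt(psy$conf.high, 1)
})

test_that("regimens without events are dropped from model 1 with a message", {
  rows <- tibble::tibble(
    start = 0, stop = c(5, 7, 9, 4, 6, 8),
    event = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
    regimen = c("lithium", "lithium", "quetiapine", "quetiapine",
                "ghost", "ghost"),
    psychotherapy = c(0, 1, 0, 1, 0, 1),
    prior_unique_bd_drugs = 0, age_at_index = c(30, 40, 50, 35, 45, 55)
  )
  expect_message(
    m <- assemble_model(rows, "model1", spline_vars = character()),
    "ghost"
  )
  expect_false(any(grepl("ghost", tidy(m)$term)))
  expect_equal(m$dropped, "ghost")
})
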