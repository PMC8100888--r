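test_that("the folded design has the documented shape and reference run", {
  d <- build_design(78, 512)
  expect_equal(dim(d$X), c(513, 78))
  expect_equal(d$reference_run_index, 513)
  expect_true(all(d$X[513, ] == -1))
  expect_true(all(d$X %in% c(-1, 1)))
  # fold-over property: every factorial run's negation is also a run
  runs <- d$X[-513, ]
  expect_equal(runs[257:512, ], -runs[1:256, ])
  # balanced columns
  expect_true(all(colSums(runs) == 0))
})

test_that("resolution IV holds exhaustively for the 7-factor 16-run design", {
  d <- build_design(7, 16)
  expect_equal(dim(d$X), c(17, 7))
  X <- d$X[-17, ]
  # brute force over all 21 column pairs: no main effect equals (+/-) any
  # two-column product, and all are orthogonal to it
  for (a in 1:6) for (b in (a + 1):7) {
    prod_col <- X[, a] * X[, b]
    for (j in 1:7) {
      expect_gt(sum(abs(X[, j] - prod_col)), 0)
      expect_gt(sum(abs(X[, j] + prod_col)), 0)
      expect_equal(sum(X[, j] * prod_col), 0)
    }
  }
  expect_true(verify_resolution4(d))
  # the programmatic check also passes at the full published scale
  expect_true(verify_resolution4(build_design(78, 512)))
})

test_that("capacity violations name the minimal feasible run count", {
  expect_error(build_design(8, 16), "n_base_runs.*>= 32")
  expect_error(build_design(255, 512), NA)
  expect_error(build_design(256, 512), ">= 1024")
  expect_error(build_design(10, 100), "power of 2")
})

doe_world <- function(seed, n = 900, confounders = default_confounders(),
                      n_noise = 4, hazard = 5e-4) {
  vocab <- shared_test_vocab()
  gt <- ground_truth(coding_fraction = 1, baseline_hazard = hazard,
                     confounders = confounders, seed = seed)
  sim <- simulate_population(gt, vocab, n_patients = n, seed = seed,
                             outpatient_rate = 2 / 365,
                             nonevent_hosp_rate = 0.1 / 365)
  # noise covariates: background codes appearing at random in visits
  noise_codes <- setdiff(codes_with_role(vocab, "background"),
                         sim$confounder_codes)[seq_len(n_noise)]
  sets <- c(as.list(sim$confounder_codes),
            stats::setNames(as.list(noise_codes),
                            paste0("noise", seq_len(n_noise))))
  pl <- run_pipeline(sim, threshold = 1, impute = FALSE,
                     covariate_sets = sets, model = "none",
                     min_intervals = 20, min_events = 3)
  list(rows = pl$rows, covariates = names(sets), sim = sim)
}

test_that("factorial runs produce deterministic treatment coefficients", {
  w <- doe_world(seed = 61)
  d <- build_design(length(w$covariates), 16,
                    covariate_names = w$covariates)
  runs <- suppressMessages(run_factorial(w$rows, d))
  expect_equal(nrow(runs$Y), 17)
  expect_true(all(stats::complete.cases(runs$Y)))
  # the reference run equals a treatment-only fit on the same retained levels
  ev <- tapply(w$rows$event, w$rows$regimen, sum)
  kept_rows <- w$rows[!w$rows$regimen %in% names(ev)[ev < 3], ]
  ref_fit <- suppressWarnings(fit_cox(dplyr::mutate(
    kept_rows, regimen = stats::relevel(factor(.data$regimen), ref = "lithium")
  ), c("regimen", "psychotherapy")))
  expect_equal(unname(runs$Y[17, ]),
               unname(coef(ref_fit$fit)[colnames(runs$Y)]), tolerance = 1e-8)
  # duplicated design rows give identical coefficient rows
  d2 <- d
  d2$X[2, ] <- d2$X[1, ]
  runs2 <- suppressMessages(run_factorial(w$rows, d2))
  expect_equal(runs2$Y[1, ], runs2$Y[2, ])
  expect_error(run_factorial(w$rows, build_design(3, 8,
                                                  c("nope1", "nope2", "nope3"))),
               "not in rows")
})

test_that("covariate scoring matches the normal-equations oracle", {
  set.seed(71)
  d <- build_design(7, 16)
  Y <- matrix(rnorm(17 * 3), 17, 3, dimnames = list(NULL, paste0("t", 1:3)))
  sc <- score_covariates(Y, design = d, alpha = 0.05)
  X1 <- cbind(1, d$X)
  for (i in 1:3) {
    beta <- solve(t(X1) %*% X1, t(X1) %*% Y[, i])
    expect_equal(unname(sc$estimates[, i]), unname(beta[-1]),
                 tolerance = 1e-10)
  }
  # default alpha follows the 0.05 / n_treatments rule
  sc2 <- score_covariates(Y, design = d)
  expect_equal(sc2$alpha, 0.05 / 3)
  Y66 <- matrix(rnorm(17 * 66), 17, 66)
  expect_equal(score_covariates(Y66, design = d)$alpha, 0.05 / 66)
})

test_that("inert covariates are discarded and planted confounders score", {
  w <- doe_world(seed = 73, n = 1200)
  d <- build_design(length(w$covariates), 16,
                    covariate_names = w$covariates)
  runs <- suppressMessages(run_factorial(w$rows, d))
  sc <- score_covariates(runs)
  expect_true(all(sc$counts >= 0 & sc$counts <= ncol(runs$Y)))
  # a constant all-zero covariate never changes a fit: force one
  rows0 <- w$rows
  rows0$inert <- rbinom(nrow(rows0), 1, 0.5)  # noise unrelated to anything
  d0 <- build_design(length(w$covariates) + 1, 16,
                     covariate_names = c(w$covariates, "inert"))
  sc0 <- score_covariates(suppressMessages(run_factorial(rows0, d0)))
  expect_true(sc0$counts[["substance_abuse"]] >= 1)
  tidy_sc <- tidy(sc0)
  expect_true(all(tidy_sc$discarded == (tidy_sc$n_significant == 0)))
})

test_that("backward elimination respects ordering and the stop rule", {
  w <- doe_world(seed = 79, n = 1200)
  d <- build_design(length(w$covariates), 16,
                    covariate_names = w$covariates)
  sc <- score_covariates(suppressMessages(run_factorial(w$rows, d)))
  # stop_p = 0: nothing is "highly significant", everything is eliminated
  be0 <- backward_eliminate(w$rows, sc, stop_p = 0)
  expect_length(be0$final, 0)
  expect_equal(nrow(be0$trace), length(setdiff(names(sc$counts),
                                               sc$discarded)))
  # drops are ordered by increasing significance count
  expect_true(all(diff(be0$trace$n_significant) >= 0))
  # a permissive stop keeps the strongest candidates
  be <- backward_eliminate(w$rows, sc, stop_p = 1e-3)
  expect_true(all(be$final %in% names(sc$counts)))
  # empty candidate set returns an empty trace
  sc_empty <- sc
  sc_empty$discarded <- names(sc$counts)
  be_e <- backward_eliminate(w$rows, sc_empty)
  expect_length(be_e$final, 0)
  expect_equal(nrow(be_e$trace), 0)
})

test_that("bias norms vanish at the reference run and flag confounders", {
  w <- doe_world(seed = 83, n = 1200)
  d <- build_design(length(w$covariates), 16,
                    covariate_names = w$covariates)
  runs <- suppressMessages(run_factorial(w$rows, d))
  bn <- bias_norm(runs)
  expect_equal(bn$yprime[d$reference_run_index], 0)
  expect_true(all(bn$yprime >= 0))
  expect_setequal(bn$table$covariate, w$covariates)
  # determinism: same rows + same design => identical result
  runs2 <- suppressMessages(run_factorial(w$rows, d))
  expect_identical(runs$Y, runs2$Y)
  expect_identical(bias_norm(runs2)$yprime, bn$yprime)
})
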