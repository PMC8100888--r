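# Fractional-factorial covariate-impact selection: a resolution-IV two-level
# design over pretreatment covariates, one Cox fit per run, per-treatment
# regressions of the coefficient matrix on the design, and bias diagnostics.

#' Build a resolution-IV two-level fractional factorial design
#'
#' Constructs a saturated resolution-III design on `n_base_runs / 2` runs
#' (all interaction columns of a full two-level factorial in Yates order),
#' takes the first `n_covariates` columns, and folds it over (appends the
#' sign-reversed runs), which lifts the resolution to IV: main effects are
#' orthogonal to, and never aliased with, two-factor interactions. An
#' all-exclude reference run is appended last.
#'
#' @param n_covariates Number of candidate covariates (columns).
#' @param n_base_runs Total factorial runs (a power of 2); the fold-over
#'   capacity requires `n_covariates <= n_base_runs / 2 - 1`.
#' @param covariate_names Optional column names.
#' @return Object of class `factorial_design`: list with the run matrix
#'   `X` (`n_base_runs + 1` rows of +1/-1), `resolution`, and
#'   `reference_run_index`.
#' @export
build_design <- function(n_covariates, n_base_runs,
                         covariate_names = NULL) {
  if (n_base_runs < 4 || bitwAnd(n_base_runs, n_base_runs - 1L) != 0) {
    stop("`n_base_runs` must be a power of 2 (>= 4)", call. = FALSE)
  }
  cap <- n_base_runs / 2 - 1
  if (n_covariates < 1 || n_covariates > cap) {
    min_runs <- 2^ceiling(log2(2 * (n_covariates + 1)))
    stop("fold-over capacity exceeded: ", n_covariates, " covariates need ",
         "`n_base_runs` >= ", min_runs, call. = FALSE)
  }
  m <- n_base_runs / 2
  k <- as.integer(log2(m))
  base <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))  # m x k
  # Yates-order interaction columns: column j is the product over the base
  # factors in the binary representation of j
  D <- vapply(seq_len(n_covariates), function(j) {
    bits <- which(bitwAnd(j, 2^(seq_len(k) - 1)) > 0)
    apply(base[, bits, drop = FALSE], 1, prod)
  }, numeric(m))
  X <- rbind(D, -D, matrix(-1, 1, n_covariates))
  colnames(X) <- covariate_names %||% paste0("C", seq_len(n_covariates))
  rownames(X) <- NULL
  structure(
    list(X = X, n_base_runs = n_base_runs, resolution = 4L,
         reference_run_index = nrow(X)),
    class = "factorial_design"
  )
}

#' Verify the resolution-IV aliasing structure of a design
#'
#' Checks, over the factorial runs (reference run excluded), that no
#' main-effect column equals (up to sign) the elementwise product of any
#' two distinct columns, and that every main-effect column is orthogonal to
#' every two-column product. Exhaustive for small designs; pairs are
#' sampled above `max_pairs`.
#'
#' @param design A `factorial_design`.
#' @param max_pairs Maximum column pairs to check exhaustively.
#' @return TRUE if the checks pass, FALSE otherwise.
#' @export
verify_resolution4 <- function(design, max_pairs = 5000) {
  X <- design$X[-design$reference_run_index, , drop = FALSE]
  p <- ncol(X)
  pairs <- utils::combn(p, 2)
  if (ncol(pairs) > max_pairs) {
    pairs <- pairs[, sample.int(ncol(pairs), max_pairs), drop = FALSE]
  }
  for (q in seq_len(ncol(pairs))) {
    prod_col <- X[, pairs[1, q]] * X[, pairs[2, q]]
    dots <- abs(as.numeric(crossprod(X, prod_col)))
    if (any(dots > 1e-8)) return(FALSE)     # non-orthogonal => aliased
    if (any(colSums(abs(X - prod_col)) == 0) ||
        any(colSums(abs(X + prod_col)) == 0)) return(FALSE)
  }
  TRUE
}

#' @export
print.factorial_design <- function(x, ...) {
  cat("<factorial_design>", nrow(x$X), "runs x", ncol(x$X),
      "covariates (resolution IV, fold-over; reference run",
      x$reference_run_index, ")\n")
  invisible(x)
}

#' Run the factorial: one Cox fit per design run
#'
#' For every run, fits the Cox model with the treatment terms always
#' included and covariate j included iff `X[run, j] = +1`, and records the
#' treatment coefficients. Runs whose fit fails are recorded as NA rows;
#' more than `max_fail_frac` failures is an error.
#'
#' @param rows Counting-process rows; `regimen` must already be a factor
#'   with the reference level first (see [assemble_model()]), or character
#'   (releveled to `reference`).
#' @param design A `factorial_design` whose column names are covariate
#'   columns of `rows`.
#' @param treatment_terms Terms always included (default
#'   `c("regimen", "psychotherapy")`).
#' @param reference Reference regimen when `regimen` is character.
#' @param max_fail_frac Maximum tolerated fraction of failed runs.
#' @param min_level_events Regimen levels with fewer events are dropped
#'   before the runs (their partial-likelihood contributions are divergent
#'   or undefined).
#' @return Object of class `doe_runs`: list with the coefficient matrix
#'   `Y` (runs x treatment coefficients), `failed` run indices, and the
#'   design.
#' @export
run_factorial <- function(rows, design, treatment_terms = c("regimen",
                                                            "psychotherapy"),
                          reference = "lithium", max_fail_frac = 0.05,
                          min_level_events = 3) {
  stopifnot(inherits(design, "factorial_design"))
  covars <- colnames(design$X)
  missing_cov <- setdiff(covars, names(rows))
  if (length(missing_cov)) {
    stop("design covariates not in rows: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  if (is.character(rows$regimen)) {
    rows$regimen <- stats::relevel(factor(rows$regimen), ref = reference)
  }
  if ("regimen" %in% treatment_terms) {
    # regimen levels with (almost) no events have divergent or undefined
    # coefficients and poison the whole coefficient matrix; drop them up
    # front, for the same convergence reason the interval/event requisites
    # exist
    ev <- tapply(rows$event, rows$regimen, sum)
    dead <- names(ev)[is.na(ev) | ev < min_level_events]
    if (length(dead)) {
      message("factorial runs drop low-event regimen(s): ",
              paste(dead, collapse = ", "))
      rows <- rows[!rows$regimen %in% dead, ]
      rows$regimen <- droplevels(rows$regimen)
    }
  }
  n_runs <- nrow(design$X)
  Y <- NULL
  failed <- integer(0)
  treat_idx <- NULL
  for (r in seq_len(n_runs)) {
    terms <- c(treatment_terms, covars[design$X[r, ] > 0])
    fit <- tryCatch(suppressWarnings(fit_cox(rows, terms)),
                    error = function(e) NULL)
    if (!is.null(fit) && anyNA(stats::coef(fit$fit))) fit <- NULL  # singular
    if (is.null(fit)) {
      failed <- c(failed, r)
      next
    }
    co <- stats::coef(fit$fit)
    if (is.null(treat_idx)) {
      treat_idx <- grep(paste0("^(", paste(treatment_terms, collapse = "|"),
                               ")"), names(co), value = TRUE)
      Y <- matrix(NA_real_, n_runs, length(treat_idx),
                  dimnames = list(NULL, treat_idx))
    }
    Y[r, ] <- co[treat_idx]
  }
  if (length(failed) > n_runs * max_fail_frac) {
    stop(length(failed), " of ", n_runs, " factorial runs failed to fit",
         call. = FALSE)
  }
  structure(list(Y = Y, failed = failed, design = design,
                 treatment_terms = treatment_terms),
            class = "doe_runs")
}

#' Score covariates by their impact on treatment coefficients
#'
#' For each treatment coefficient column of `Y`, runs an ordinary least
#' squares regression of the column on all covariate columns of the design
#' matrix and counts, per covariate, in how many of the treatment
#' regressions it is significant at `alpha` (default the Bonferroni-style
#' `0.05 / n_treatments` used to rank candidates). Covariates never
#' significant are discarded.
#'
#' @param runs A `doe_runs` object (or a bare Y matrix with `design`).
#' @param design The `factorial_design` (taken from `runs` if omitted).
#' @param alpha Per-test significance level; default `0.05 / ncol(Y)`.
#' @return Object of class `doe_scores`: list with `counts` (named),
#'   `min_p` (named; minimum p across treatments), `pvalues`
#'   (covariate x treatment matrix), `discarded`, `alpha`.
#' @export
score_covariates <- function(runs, design = NULL, alpha = NULL) {
  if (inherits(runs, "doe_runs")) {
    Y <- runs$Y
    design <- design %||% runs$design
  } else {
    Y <- runs
  }
  stopifnot(inherits(design, "factorial_design"))
  X <- design$X
  ok <- stats::complete.cases(Y)
  Yc <- Y[ok, , drop = FALSE]
  Xc <- X[ok, , drop = FALSE]
  if (qr(cbind(1, Xc))$rank < ncol(Xc) + 1) {
    stop("design matrix is rank deficient over the successful runs",
         call. = FALSE)
  }
  alpha <- alpha %||% (0.05 / ncol(Yc))
  p <- ncol(Xc)
  pvals <- matrix(NA_real_, p, ncol(Yc),
                  dimnames = list(colnames(Xc), colnames(Yc)))
  ests <- pvals
  for (i in seq_len(ncol(Yc))) {
    sm <- summary(stats::lm(Yc[, i] ~ Xc))
    pvals[, i] <- sm$coefficients[-1, 4]
    ests[, i] <- sm$coefficients[-1, 1]
  }
  counts <- rowSums(pvals < alpha)
  min_p <- apply(pvals, 1, min)
  structure(
    list(counts = counts, min_p = min_p, pvalues = pvals, estimates = ests,
         discarded = names(counts)[counts == 0], alpha = alpha),
    class = "doe_scores"
  )
}

#' @export
tidy.doe_scores <- function(x, ...) {
  tibble::tibble(covariate = names(x$counts), n_significant = unname(x$counts),
                 min_p = unname(x$min_p),
                 discarded = names(x$counts) %in% x$discarded)
}

#' Backward elimination of low-impact covariates
#'
#' Starting from the covariates that survived [score_covariates()], ordered
#' by increasing significance count (ties broken by larger minimum p),
#' iteratively drops the least-impactful covariate and refits the full Cox
#' model with the remaining set, stopping as soon as the next candidate is
#' highly significant (minimum p across the treatment-impact regressions
#' below `stop_p`). With `stop_p = 0` nothing qualifies as highly
#' significant and every candidate is eliminated.
#'
#' @param rows Counting-process rows.
#' @param scores A `doe_scores` object.
#' @param treatment_terms Terms always included in the refits.
#' @param reference Reference regimen for character `regimen`.
#' @param stop_p Threshold operationalizing "highly significant".
#' @return List: `final` covariate set, `trace` tibble (step, dropped,
#'   n_significant, min_p, loglik).
#' @export
backward_eliminate <- function(rows, scores,
                               treatment_terms = c("regimen", "psychotherapy"),
                               reference = "lithium", stop_p = 1e-3) {
  stopifnot(inherits(scores, "doe_scores"))
  if (is.character(rows$regimen)) {
    rows$regimen <- stats::relevel(factor(rows$regimen), ref = reference)
  }
  cand <- setdiff(names(scores$counts), scores$discarded)
  if (length(cand) == 0) {
    return(list(final = character(0),
                trace = tibble::tibble(step = integer(), dropped = character(),
                                       n_significant = numeric(),
                                       min_p = numeric(), loglik = numeric())))
  }
  ord <- cand[order(scores$counts[cand], -scores$min_p[cand])]
  current <- ord
  trace <- list()
  step <- 0L
  for (nxt in ord) {
    if (scores$min_p[nxt] < stop_p) break   # highly significant: stop
    step <- step + 1L
    current <- setdiff(current, nxt)
    ll <- NA_real_
    if (length(current) > 0 || length(treatment_terms) > 0) {
      refit <- tryCatch(suppressWarnings(fit_cox(rows, c(treatment_terms,
                                                         current))),
                        error = function(e) NULL)
      if (!is.null(refit)) ll <- refit$fit$loglik[2]
    }
    trace[[step]] <- tibble::tibble(
      step = step, dropped = nxt,
      n_significant = unname(scores$counts[nxt]),
      min_p = unname(scores$min_p[nxt]), loglik = ll
    )
  }
  list(final = current,
       trace = if (length(trace)) dplyr::bind_rows(trace) else
         tibble::tibble(step = integer(), dropped = character(),
                        n_significant = numeric(), min_p = numeric(),
                        loglik = numeric()))
}

#' Bias norms: how much covariate inclusion shifts treatment estimates
#'
#' For every run, the Euclidean distance between its treatment-coefficient
#' vector (row of `Y`) and the reference run's vector; the distances are
#' regressed on the design matrix by OLS to identify the covariates whose
#' inclusion most shifts the treatment estimates (largest bias sources).
#'
#' @param runs A `doe_runs` object.
#' @param design Optional `factorial_design` override.
#' @return List: `yprime` (per-run distances; 0 at the reference run),
#'   `table` tibble (covariate, estimate, std.error, p.value) sorted by
#'   significance.
#' @export
bias_norm <- function(runs, design = NULL) {
  stopifnot(inherits(runs, "doe_runs"))
  design <- design %||% runs$design
  Y <- runs$Y
  ref <- design$reference_run_index
  if (anyNA(Y[ref, ])) stop("reference run failed; bias norms undefined",
                            call. = FALSE)
  d <- sweep(Y, 2, Y[ref, ], "-")
  yprime <- sqrt(rowSums(d^2))
  ok <- stats::complete.cases(Y)
  sm <- summary(stats::lm(yprime[ok] ~ design$X[ok, , drop = FALSE]))
  co <- sm$coefficients[-1, , drop = FALSE]
  tab <- tibble::tibble(
    covariate = colnames(design$X),
    estimate = co[, 1], std.error = co[, 2], p.value = co[, 4]
  )
  list(yprime = yprime,
       table = dplyr::arrange(tab, .data$p.value))
}
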