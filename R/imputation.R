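# Cross-validated probabilistic imputation of self-harm for inpatient/ER
# meta-visits: sparse binary features over hierarchy-expanded codes plus
# age/sex/start-year, penalized logistic regression, out-of-fold scoring.

#' Build the sparse feature matrix for self-harm classification
#'
#' One row per meta-visit. Features are age at meta-visit start, a male-sex
#' indicator, the calendar start year, and a binary indicator for every
#' non-self-harm code present in the meta-visit expanded to all of its
#' vocabulary ancestors. Self-harm codes and ancestors reachable only from
#' the self-harm set are excluded (they would leak the label); code
#' indicators observed fewer than `min_support` times are dropped.
#'
#' @param metavisits Labeled meta-visits (see [label_coded_selfharm()]).
#' @param patients Patients tibble with sex and birth_year.
#' @param vocab A `code_vocabulary`.
#' @param min_support Minimum number of meta-visits a code indicator must
#'   appear in to be kept.
#' @param start_year Calendar year of day 0 (for ages and start-year
#'   features).
#' @return List with the sparse matrix `x` (dgCMatrix), the row-aligned
#'   `meta` tibble, and `features` (column names).
#' @export
build_features <- function(metavisits, patients, vocab, min_support = 10,
                           start_year = 2010) {
  stopifnot(inherits(vocab, "code_vocabulary"))
  miss <- setdiff(unique(metavisits$patient_id), patients$patient_id)
  if (length(miss) > 0) {
    stop("meta-visits reference unknown patients: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  mv <- dplyr::left_join(
    metavisits,
    patients[, c("patient_id", "sex", "birth_year")],
    by = "patient_id"
  )
  yr <- start_year + mv$start_day %/% 365L
  age <- yr - mv$birth_year

  anc <- ancestor_map(vocab)
  banned <- union(codes_with_role(vocab, "self_harm"),
                  selfharm_exclusive_ancestors(vocab))
  expanded <- lapply(mv$codes, function(cd) {
    cd <- cd[cd %in% names(anc)]           # unknown codes contribute nothing
    setdiff(unique(unlist(anc[cd], use.names = FALSE)), banned)
  })
  lens <- lengths(expanded)
  code_levels <- sort(unique(unlist(expanded, use.names = FALSE)))
  keep <- code_levels
  if (length(code_levels) > 0) {
    j_all <- match(unlist(expanded, use.names = FALSE), code_levels)
    support <- tabulate(j_all, nbins = length(code_levels))
    keep <- code_levels[support >= min_support]
  }
  i <- rep(seq_len(nrow(mv)), lens)
  j <- match(unlist(expanded, use.names = FALSE), keep)
  ok <- !is.na(j)
  x_codes <- Matrix::sparseMatrix(
    i = i[ok], j = j[ok], x = 1,
    dims = c(nrow(mv), length(keep)),
    dimnames = list(NULL, keep)
  )
  x <- cbind(
    Matrix::Matrix(cbind(age = age, male = as.numeric(mv$sex == "M"),
                         start_year = yr), sparse = TRUE),
    x_codes
  )
  list(x = methods::as(x, "CsparseMatrix"), meta = metavisits,
       features = colnames(x))
}

#' Out-of-fold self-harm probabilities by k-fold cross-validation
#'
#' Fits a penalized (ridge) logistic regression of the coded self-harm label
#' on the feature matrix over the inpatient/ER meta-visits only, using
#' k-fold cross-validation stratified by class so that every fold holds
#' positive examples. Every inpatient/ER meta-visit is scored by the model
#' that never saw it in training; outpatient-only meta-visits receive
#' probability 0 (self-harm coding during purely outpatient episodes is
#' negligible). The classifier is pluggable through `fit_fun`/`predict_fun`.
#'
#' @param metavisits Labeled meta-visits.
#' @param patients Patients tibble.
#' @param vocab A `code_vocabulary`.
#' @param k Number of folds (default 5).
#' @param seed Seed for the fold assignment.
#' @param lambda Ridge penalty passed to glmnet.
#' @param min_support Passed to [build_features()].
#' @param start_year Calendar year of day 0.
#' @param fold_level `"metavisit"` (default; the unit of analysis) or
#'   `"patient"` (all meta-visits of a patient share a fold, preventing
#'   within-patient leakage).
#' @param fit_fun,predict_fun Optional classifier override:
#'   `fit_fun(x, y)` returns a model, `predict_fun(model, x)` a probability
#'   vector.
#' @return `metavisits` with numeric `selfharm_prob` and integer `fold`
#'   (NA for outpatient-only rows) columns.
#' @export
crossfit_probabilities <- function(metavisits, patients, vocab, k = 5, seed = 1,
                                   lambda = 1e-3, min_support = 10,
                                   start_year = 2010,
                                   fold_level = c("metavisit", "patient"),
                                   fit_fun = NULL, predict_fun = NULL) {
  fold_level <- match.arg(fold_level)
  if (!"coded_selfharm" %in% names(metavisits)) {
    stop("run label_coded_selfharm() first", call. = FALSE)
  }
  in_er <- metavisits$has_inpatient_or_er
  y <- as.numeric(metavisits$coded_selfharm[in_er])
  if (sum(y) < k) {
    stop("need at least k = ", k, " class-1 inpatient/ER meta-visits; have ",
         sum(y), call. = FALSE)
  }
  fb <- build_features(metavisits[in_er, ], patients, vocab,
                       min_support = min_support, start_year = start_year)
  x <- fb$x

  withr_seed(seed)
  fold <- integer(length(y))
  if (fold_level == "metavisit") {
    for (cl in c(0, 1)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    pids <- unique(metavisits$patient_id[in_er])
    pf <- stats::setNames(sample(rep_len(seq_len(k), length(pids))), pids)
    fold <- unname(pf[metavisits$patient_id[in_er]])
    if (any(vapply(seq_len(k), function(f) sum(y[fold == f]), 0) == sum(y))) {
      stop("patient-level folds left some folds without class-1 examples",
           call. = FALSE)
    }
  }

  if (is.null(fit_fun)) {
    # warm-started path down to the target penalty; a single small lambda
    # can diverge in glmnet's coordinate descent
    lambda_path <- exp(seq(log(0.5), log(lambda), length.out = 25))
    fit_fun <- function(x, y) {
      glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                     lambda = lambda_path, standardize = TRUE)
    }
    predict_fun <- function(model, x) {
      as.numeric(stats::predict(model, newx = x, s = lambda,
                                type = "response"))
    }
  }
  prob <- numeric(length(y))
  for (f in seq_len(k)) {
    tr <- fold != f
    model <- fit_fun(x[tr, , drop = FALSE], y[tr])
    prob[!tr] <- predict_fun(model, x[!tr, , drop = FALSE])
  }

  metavisits$selfharm_prob <- 0
  metavisits$selfharm_prob[in_er] <- prob
  metavisits$fold <- NA_integer_
  metavisits$fold[in_er] <- fold
  metavisits
}

#' Flag outcome meta-visits at a probability threshold
#'
#' A meta-visit is an outcome when it carries a self-harm code ("coded
#' and/or imputed": coded meta-visits are outcomes at every threshold) or
#' when it has an inpatient/ER component and its imputed probability
#' strictly exceeds `threshold`. At `threshold = 1` the outcome set is
#' exactly the coded set.
#'
#' @param metavisits Meta-visits with `selfharm_prob` and `coded_selfharm`.
#' @param threshold Probability threshold in `[0, 1]`; the comparison is a
#'   strict `>`.
#' @return `metavisits` with a logical `outcome` column.
#' @export
apply_threshold <- function(metavisits, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 1) {
    stop("`threshold` must be a single value in [0, 1]", call. = FALSE)
  }
  if (!"selfharm_prob" %in% names(metavisits)) {
    stop("run crossfit_probabilities() first", call. = FALSE)
  }
  metavisits$outcome <- metavisits$coded_selfharm |
    (metavisits$has_inpatient_or_er & metavisits$selfharm_prob > threshold)
  metavisits
}

#' Area under the ROC curve by the rank statistic
#'
#' Wilcoxon-Mann-Whitney AUC: the probability that a random positive is
#' ranked above a random negative, with average ranks for ties.
#'
#' @param probabilities Numeric scores.
#' @param labels Binary labels (0/1 or logical).
#' @return AUC in `[0, 1]`; NA if either class is empty.
#' @export
rank_auc <- function(probabilities, labels) {
  y <- as.numeric(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(probabilities)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics against the coded label
#'
#' Computes sensitivity, specificity and the Matthews correlation
#' coefficient from a confusion table in which the coded self-harm label is
#' treated as truth and imputation (probability above the threshold) as the
#' prediction: TP = coded and imputed, FN = coded not imputed, FP = imputed
#' not coded, TN = neither. AUC is added when probabilities and labels are
#' supplied. A metric whose defining denominator is empty is reported as NA
#' (undefined), never 0.
#'
#' @param counts Named vector/list with `n_coded_imputed`,
#'   `n_coded_not_imputed`, `n_imputed_not_coded`, `n_neither` (or `tp`,
#'   `fn`, `fp`, `tn`). Omit to derive from `probabilities`, `labels`,
#'   `threshold`.
#' @param probabilities,labels Optional scores and coded labels for AUC
#'   (and for the counts when `counts` is NULL).
#' @param threshold Threshold used to derive counts from probabilities.
#' @return One-row tibble: tp, fn, fp, tn, threshold, sensitivity,
#'   specificity, mcc, auc.
#' @export
classification_metrics <- function(counts = NULL, probabilities = NULL,
                                   labels = NULL, threshold = 0.5) {
  if (is.null(counts)) {
    if (is.null(probabilities) || is.null(labels)) {
      stop("supply `counts` or both `probabilities` and `labels`",
           call. = FALSE)
    }
    y <- as.numeric(labels)
    pred <- probabilities > threshold
    counts <- c(tp = sum(y == 1 & pred), fn = sum(y == 1 & !pred),
                fp = sum(y == 0 & pred), tn = sum(y == 0 & !pred))
  }
  counts <- unlist(counts)
  nm <- names(counts)
  pick <- function(a, b) as.numeric(counts[[if (a %in% nm) a else b]])
  tp <- pick("n_coded_imputed", "tp"); fn <- pick("n_coded_not_imputed", "fn")
  fp <- pick("n_imputed_not_coded", "fp"); tn <- pick("n_neither", "tn")
  if (any(c(tp, fn, fp, tn) < 0)) stop("counts must be non-negative",
                                       call. = FALSE)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
  tibble::tibble(
    tp = tp, fn = fn, fp = fp, tn = tn, threshold = threshold,
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    mcc = if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den,
    auc = if (!is.null(probabilities) && !is.null(labels)) {
      rank_auc(probabilities, labels)
    } else NA_real_
  )
}
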