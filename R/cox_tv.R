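# Time-varying proportional-hazards models on counting-process rows,
# natural-spline terms with a separable linear component, and
# Benjamini-Yekutieli multiple-testing correction.

#' Fit a Cox model on counting-process rows
#'
#' Thin, contract-checked wrapper around [survival::coxph()] on
#' `Surv(start, stop, event)` rows with Efron tie handling by default.
#' Terms that are constant across all rows are rejected by name before
#' fitting (non-identifiable).
#'
#' @param rows Counting-process tibble with start, stop, event columns.
#' @param terms Character vector of column names to use as predictors;
#'   factors are expanded by `coxph`.
#' @param ties Tie-handling method (default `"efron"`).
#' @param ... Passed to [survival::coxph()].
#' @return Object of class `coxtv_fit` wrapping the `coxph` fit.
#' @export
fit_cox <- function(rows, terms, ties = "efron", ...) {
  stopifnot(all(c("start", "stop", "event") %in% names(rows)))
  if (sum(rows$event) < 1) stop("no events in `rows`", call. = FALSE)
  missing_terms <- setdiff(terms, names(rows))
  if (length(missing_terms)) {
    stop("terms not in `rows`: ", paste(missing_terms, collapse = ", "),
         call. = FALSE)
  }
  const <- terms[vapply(terms, function(tm) {
    v <- rows[[tm]]
    length(unique(v[!is.na(v)])) < 2
  }, logical(1))]
  if (length(const)) {
    stop("non-identifiable term(s) constant across rows: ",
         paste(const, collapse = ", "), call. = FALSE)
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(start, stop, event) ~",
    paste(paste0("`", terms, "`"), collapse = " + ")
  ))
  fit <- survival::coxph(fml, data = rows, ties = ties, ...)
  if (!is.null(fit$info) && !isTRUE(fit$converged %||% TRUE)) {
    warning("coxph did not converge", call. = FALSE)
  }
  structure(
    list(fit = fit, terms = terms, ties = ties,
         n = nrow(rows), n_events = sum(rows$event),
         spline_info = attr(rows, "spline_info")),
    class = "coxtv_fit"
  )
}

#' @export
print.coxtv_fit <- function(x, ...) {
  cat("<coxtv_fit>", x$n, "rows,", x$n_events, "events; ties =", x$ties, "\n")
  print(tidy.coxtv_fit(x), n = 20)
  invisible(x)
}

#' Tidy a `coxtv_fit`
#'
#' Per-term coefficient, standard error, hazard ratio and symmetric
#' log-scale Wald 95% CI and p-value.
#'
#' @param x A `coxtv_fit`.
#' @param ... Unused.
#' @return Tibble: term, estimate, std.error, hr, conf.low, conf.high,
#'   p.value.
#' @export
tidy.coxtv_fit <- function(x, ...) {
  co <- stats::coef(x$fit)
  se <- sqrt(diag(stats::vcov(x$fit)))
  tibble::tibble(
    term = names(co),
    estimate = unname(co),
    std.error = unname(se),
    hr = exp(unname(co)),
    conf.low = exp(unname(co) - 1.96 * unname(se)),
    conf.high = exp(unname(co) + 1.96 * unname(se)),
    p.value = 2 * stats::pnorm(-abs(unname(co) / unname(se)))
  )
}

#' Glance at a `coxtv_fit`
#'
#' @param x A `coxtv_fit`.
#' @param ... Unused.
#' @return One-row tibble: n, n_events, loglik_null, loglik, concordance,
#'   converged.
#' @export
glance.coxtv_fit <- function(x, ...) {
  ll <- x$fit$loglik
  tibble::tibble(
    n = x$n, n_events = x$n_events,
    loglik_null = ll[1], loglik = ll[length(ll)],
    concordance = unname(x$fit$concordance["concordance"]),
    converged = is.null(x$fit$info) || !isTRUE(x$fit$fail)
  )
}

#' Natural-spline basis with a separable linear component
#'
#' Builds a natural cubic spline basis (interior knots at quantiles) for a
#' covariate and reparameterizes it into the raw linear term plus
#' `df - 1` nonlinear columns orthogonalized against span{1, x}, so that
#' the linear component is directly reportable and the nonlinear components
#' admit a joint Wald test. With fewer than `df + 2` distinct values the
#' term degrades to linear with a warning.
#'
#' @param rows Data frame of counting-process rows.
#' @param var Name of the numeric column to expand.
#' @param df Spline degrees of freedom (default 4).
#' @param reference_value Reference for hazard-ratio curves (default:
#'   median of `var`).
#' @return `rows` with added columns `<var>_lin` and `<var>_nl1..`; the
#'   basis definition is recorded in `attr(rows, "spline_info")[[var]]` so
#'   curves can be evaluated at new values.
#' @export
add_spline <- function(rows, var, df = 4, reference_value = NULL) {
  x <- rows[[var]]
  if (is.null(x)) stop("no column `", var, "` in rows", call. = FALSE)
  ux <- sort(unique(x))
  info <- attr(rows, "spline_info") %||% list()
  if (length(ux) < df + 2) {
    warning("too few distinct values for a ", df, "-df spline on `", var,
            "`; using a linear term", call. = FALSE)
    rows[[paste0(var, "_lin")]] <- x
    info[[var]] <- list(var = var, df = 1, linear_only = TRUE,
                        reference = reference_value %||% stats::median(x))
    attr(rows, "spline_info") <- info
    return(rows)
  }
  basis <- splines::ns(x, df = df)
  knots <- attr(basis, "knots")
  bknots <- attr(basis, "Boundary.knots")
  # project the ns basis off span{1, x}: remaining columns are purely
  # nonlinear; drop the last (rank df - 1 after removing the linear part)
  Q <- cbind(1, x)
  proj <- qr.solve(crossprod(Q), crossprod(Q, basis))   # 2 x df
  resid <- basis - Q %*% proj
  qr_r <- qr(resid)
  nl <- qr.Q(qr_r)[, seq_len(min(df - 1, qr_r$rank)), drop = FALSE]
  nl <- nl * sqrt(nrow(nl))                              # unit-variance-ish
  # transfer map: nl lies in resid's column space, so new values evaluate as
  # resid_new %*% tmat; resid is rank df-1 (its span contains the linear
  # direction), so use the minimum-norm pseudo-inverse solution
  sv <- svd(resid)
  pos <- sv$d > max(sv$d) * 1e-10
  tmat <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% nl) / sv$d[pos])
  rows[[paste0(var, "_lin")]] <- x
  nl_names <- paste0(var, "_nl", seq_len(ncol(nl)))
  for (j in seq_len(ncol(nl))) rows[[nl_names[j]]] <- nl[, j]
  info[[var]] <- list(
    var = var, df = df, linear_only = FALSE,
    knots = knots, boundary = bknots, proj = proj, tmat = tmat,
    reference = reference_value %||% stats::median(x),
    nl_names = nl_names
  )
  attr(rows, "spline_info") <- info
  rows
}

#' Spline term names for a variable expanded by [add_spline()]
#' @param rows Rows carrying spline info.
#' @param var Variable name.
#' @return Character vector of column names (linear first).
#' @export
spline_term_names <- function(rows, var) {
  info <- attr(rows, "spline_info")[[var]]
  if (is.null(info)) stop("no spline info for `", var, "`", call. = FALSE)
  if (isTRUE(info$linear_only)) return(paste0(var, "_lin"))
  c(paste0(var, "_lin"), info$nl_names)
}

# evaluate the nonlinear basis columns of a fitted spline at new values
eval_spline_nl <- function(info, x) {
  basis <- splines::ns(x, knots = info$knots, Boundary.knots = info$boundary)
  Q <- cbind(1, x)
  resid <- basis - Q %*% info$proj
  resid %*% info$tmat
}

#' Joint Wald test of the nonlinear spline components
#'
#' @param fit A `coxtv_fit` on rows produced by [add_spline()].
#' @param var Spline variable name.
#' @return One-row tibble: statistic, df, p.value.
#' @export
spline_joint_test <- function(fit, var) {
  info <- fit$spline_info[[var]]
  if (is.null(info) || isTRUE(info$linear_only)) {
    return(tibble::tibble(statistic = NA_real_, df = 0L, p.value = NA_real_))
  }
  co <- stats::coef(fit$fit)
  V <- stats::vcov(fit$fit)
  idx <- match(info$nl_names, names(co))
  b <- co[idx]
  W <- as.numeric(t(b) %*% solve(V[idx, idx]) %*% b)
  tibble::tibble(statistic = W, df = length(idx),
                 p.value = stats::pchisq(W, length(idx), lower.tail = FALSE))
}

#' Hazard-ratio curve of a spline term versus its reference value
#'
#' Evaluates `exp(eta(x) - eta(ref))` with pointwise Wald 95% CIs, where
#' `eta` collects the linear and nonlinear spline components. At the
#' reference value the HR is exactly 1 with a zero-width interval.
#'
#' @param fit A `coxtv_fit` on rows produced by [add_spline()].
#' @param var Spline variable name.
#' @param at Values at which to evaluate (default: 100-point grid over the
#'   boundary knots, reference included).
#' @return Tibble: x, log_hr, hr, conf.low, conf.high.
#' @export
spline_hazard_curve <- function(fit, var, at = NULL) {
  info <- fit$spline_info[[var]]
  if (is.null(info)) stop("no spline info for `", var, "`", call. = FALSE)
  ref <- info$reference
  if (is.null(at)) {
    rng <- if (isTRUE(info$linear_only)) ref + c(-1, 1) else info$boundary
    at <- sort(unique(c(ref, seq(rng[1], rng[2], length.out = 100))))
  }
  co <- stats::coef(fit$fit)
  V <- stats::vcov(fit$fit)
  if (isTRUE(info$linear_only)) {
    nmv <- paste0(var, "_lin")
    d <- matrix(at - ref, ncol = 1)
    idx <- match(nmv, names(co))
  } else {
    nl_at <- eval_spline_nl(info, at)
    nl_ref <- eval_spline_nl(info, ref)
    d <- cbind(at - ref, sweep(nl_at, 2, nl_ref, "-"))
    idx <- match(c(paste0(var, "_lin"), info$nl_names), names(co))
  }
  eta <- as.numeric(d %*% co[idx])
  se <- sqrt(pmax(0, rowSums((d %*% V[idx, idx, drop = FALSE]) * d)))
  tibble::tibble(
    x = at, log_hr = eta, hr = exp(eta),
    conf.low = exp(eta - 1.96 * se), conf.high = exp(eta + 1.96 * se)
  )
}

#' Benjamini-Yekutieli false-discovery-rate control
#'
#' Step-up procedure valid under arbitrary dependence: with sorted
#' p-values, find the largest k with `p_(k) <= k q / (m c(m))`, where
#' `c(m) = sum_{i=1}^m 1/i`, and reject the k smallest. The realized p-value
#' cutoff (largest rejected p) and the threshold at k are reported.
#'
#' @param pvalues Numeric p-values in `[0, 1]`.
#' @param q Target false discovery rate (default 0.05).
#' @return List: `reject` (logical, input order), `k`, `p_cutoff` (largest
#'   rejected p; 0 when none), `threshold_at_k`, `thresholds`.
#' @export
benjamini_yekutieli <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0) {
    return(list(reject = logical(0), k = 0L, p_cutoff = 0,
                threshold_at_k = 0, thresholds = numeric(0)))
  }
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(pvalues)
  cm <- sum(1 / seq_len(m))
  thr <- seq_len(m) * q / (m * cm)
  o <- order(pvalues)
  ps <- pvalues[o]
  ok <- which(ps <= thr)
  k <- if (length(ok)) max(ok) else 0L
  reject <- logical(m)
  if (k > 0) reject[o[seq_len(k)]] <- TRUE
  list(reject = reject, k = as.integer(k),
       p_cutoff = if (k > 0) ps[k] else 0,
       threshold_at_k = if (k > 0) thr[k] else 0,
       thresholds = thr)
}

#' Assemble and fit the two study Cox models
#'
#' Model 1 compares every retained regimen to lithium monotherapy, with
#' psychotherapy as a binary time-varying covariate, the selected baseline
#' covariates, and natural-spline terms for age at index and the number of
#' prior unique BD drugs. Model 2 replaces the regimen and psychotherapy
#' terms by a four-category time-varying treatment factor (pharmacotherapy
#' alone / psychotherapy alone / both / no treatment, the last as
#' reference) with the same covariates and splines. Regimens with zero
#' events are dropped from model 1 with a message.
#'
#' @param rows Counting-process rows from [emit_counting_process()].
#' @param model `"model1"` or `"model2"`.
#' @param covariates Character vector of baseline covariate columns.
#' @param reference Reference regimen for model 1 (default `"lithium"`).
#' @param spline_vars Columns receiving spline terms (present columns only).
#' @param spline_df Spline degrees of freedom.
#' @param q FDR level for the Benjamini-Yekutieli correction of the
#'   treatment-term p-values.
#' @return Object of class `harm_cox_model`: list with the `coxtv_fit`,
#'   the ranked `hr_table` (treatment terms BY-adjusted), `dropped`
#'   regimens, and the model label.
#' @export
assemble_model <- function(rows, model = c("model1", "model2"),
                           covariates = character(),
                           reference = "lithium",
                           spline_vars = c("age_at_index",
                                           "prior_unique_bd_drugs"),
                           spline_df = 4, q = 0.05) {
  model <- match.arg(model)
  rows <- dplyr::as_tibble(rows)

  if (model == "model1") {
    ev <- tapply(rows$event, rows$regimen, sum)
    dead <- names(ev)[ev == 0]
    if (length(dead)) {
      message("dropping regimen(s) with no events: ",
              paste(dead, collapse = ", "))
      rows <- rows[!rows$regimen %in% dead, ]
    }
    if (!reference %in% rows$regimen) {
      stop("reference regimen `", reference, "` absent from rows",
           call. = FALSE)
    }
    rows$regimen <- stats::relevel(factor(rows$regimen), ref = reference)
    treat_terms <- c("regimen", "psychotherapy")
  } else {
    rows$treat4 <- factor(
      dplyr::case_when(
        rows$regimen == "no_drug" & rows$psychotherapy == 0 ~ "no_treatment",
        rows$regimen != "no_drug" & rows$psychotherapy == 0 ~
          "pharmacotherapy_alone",
        rows$regimen == "no_drug" & rows$psychotherapy == 1 ~
          "psychotherapy_alone",
        TRUE ~ "psychotherapy_and_pharmacotherapy"
      ),
      levels = c("no_treatment", "pharmacotherapy_alone",
                 "psychotherapy_alone", "psychotherapy_and_pharmacotherapy")
    )
    rows$treat4 <- droplevels(rows$treat4)
    dead <- character(0)
    treat_terms <- "treat4"
  }

  spline_terms <- character(0)
  for (v in intersect(spline_vars, names(rows))) {
    if (length(unique(rows[[v]])) < 2) next
    rows <- add_spline(rows, v, df = spline_df)
    spline_terms <- c(spline_terms, spline_term_names(rows, v))
  }
  terms <- c(treat_terms, covariates, spline_terms)
  fit <- fit_cox(rows, terms)

  tab <- tidy.coxtv_fit(fit)
  is_treat <- if (model == "model1") {
    grepl("^regimen", tab$term)
  } else {
    grepl("^treat4", tab$term)
  }
  by <- benjamini_yekutieli(tab$p.value[is_treat], q = q)
  tab$by_reject <- NA
  tab$by_reject[is_treat] <- by$reject
  tab$is_treatment <- is_treat
  tab <- dplyr::arrange(tab, dplyr::desc(.data$is_treatment),
                        dplyr::desc(.data$hr))

  structure(
    list(fit = fit, hr_table = tab, dropped = dead, model = model,
         by = by, reference = if (model == "model1") reference else
           "no_treatment", rows = rows),
    class = "harm_cox_model"
  )
}

#' @export
print.harm_cox_model <- function(x, ...) {
  cat("<harm_cox_model>", x$model, "- reference:", x$reference, "\n")
  print(x$hr_table, n = 15)
  invisible(x)
}

#' @export
tidy.harm_cox_model <- function(x, ...) x$hr_table

#' @export
glance.harm_cox_model <- function(x, ...) {
  g <- glance.coxtv_fit(x$fit)
  g$model <- x$model
  g$n_by_rejected <- sum(x$by$reject)
  g
}
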