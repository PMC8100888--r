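# Time-varying drug-regimen exposure: per-agent coverage from fills,
# switch-vs-combination resolution, regimen labeling, rare-regimen
# collapsing, and counting-process rows.

#' Canonical regimen label for an agent set
#'
#' No agents gives `"no_drug"`; a single agent is labeled by its name
#' (monotherapy); two or more agents of one class are `MULTI_MSA` /
#' `MULTI_SGA` (those two classes only); any other combination is labeled
#' by its sorted distinct class names joined with `+`.
#'
#' @param agents Character vector of agent names.
#' @param vocab A `code_vocabulary`.
#' @return A single label string.
#' @export
regimen_label <- function(agents, vocab) {
  if (length(agents) == 0) return("no_drug")
  if (length(agents) == 1) return(agents)
  cls <- vocab$drugs$class[match(agents, vocab$drugs$agent)]
  if (anyNA(cls)) stop("unknown agent(s): ",
                       paste(agents[is.na(cls)], collapse = ", "), call. = FALSE)
  ucls <- sort(unique(cls))
  if (length(ucls) == 1 && ucls %in% c("MSA", "SGA")) {
    return(paste0("MULTI_", ucls))
  }
  paste(ucls, collapse = "+")
}

# merge sorted [start, stop) spans, bridging gaps <= grace
merge_spans <- function(start, stop, grace) {
  o <- order(start, stop)
  start <- start[o]; stop <- stop[o]
  reach <- cummax(stop)
  new_run <- c(TRUE, start[-1] > utils::head(reach, -1) + grace)
  grp <- cumsum(new_run)
  cbind(start = tapply(start, grp, min), stop = tapply(reach, grp, max))
}

#' Build the time-varying regimen timeline from drug fills
#'
#' Per agent, drug coverage is the union of `[fill_day, fill_day +
#' days_supply)` spans with gaps of at most `grace_days` bridged. When a new
#' agent starts while a previously active agent has fewer than `grace_days`
#' of residual coverage, the overlap is treated as a regimen switch and the
#' old agent is truncated at the new start; longer overlaps are
#' combinations. The active agent set on each day defines the regimen;
#' uncovered spans are `"no_drug"`; consecutive same-regimen intervals are
#' merged. Intervals are clipped to each patient's observation window
#' `[index_exposure_day, observation_end_day)` and the terminal interval
#' carries the event flag when the observation ended in an outcome.
#'
#' @param fills Fills tibble (patient_id, drug_id, fill_day, days_supply).
#' @param staged Output of [stage_patients()].
#' @param vocab A `code_vocabulary`.
#' @param grace_days Grace period in days for both supply-gap bridging and
#'   the switch rule (default 30).
#' @return Tibble of half-open intervals: patient_id, start_day, stop_day,
#'   regimen, n_classes, event.
#' @export
assign_regimen_timeline <- function(fills, staged, vocab, grace_days = 30) {
  stopifnot(inherits(vocab, "code_vocabulary"))
  bd_ids <- vocab$drugs$drug_id
  known <- c(bd_ids, vocab$antidementia$drug_id)
  if (nrow(fills) > 0 && !all(fills$drug_id %in% known)) {
    stop("unknown drug_id in fills: ",
         paste(utils::head(setdiff(fills$drug_id, known), 5), collapse = ", "),
         call. = FALSE)
  }
  agent_of <- stats::setNames(vocab$drugs$agent, vocab$drugs$drug_id)
  class_of <- stats::setNames(vocab$drugs$class, vocab$drugs$agent)

  fl <- fills[fills$drug_id %in% bd_ids, ]
  fl <- fl[fl$patient_id %in% staged$patient_id, ]
  fl_agent <- unname(agent_of[fl$drug_id])
  idx_by_pat <- split(seq_len(nrow(fl)),
                      factor(fl$patient_id, levels = staged$patient_id))
  fl_day <- fl$fill_day
  fl_supply <- fl$days_supply

  label_cache <- new.env(parent = emptyenv())
  label_of <- function(agents) {
    key <- paste0("r|", paste(agents, collapse = "|"))
    hit <- get0(key, envir = label_cache)
    if (is.null(hit)) {
      hit <- list(regimen_label(agents, vocab),
                  length(unique(class_of[agents])))
      assign(key, hit, envir = label_cache)
    }
    hit
  }

  acc_pid <- vector("list", nrow(staged))
  acc_start <- vector("list", nrow(staged))
  acc_stop <- vector("list", nrow(staged))
  acc_lab <- vector("list", nrow(staged))
  acc_ncl <- vector("list", nrow(staged))
  for (i in seq_len(nrow(staged))) {
    w0 <- staged$index_exposure_day[i]
    w1 <- staged$observation_end_day[i]
    ii <- idx_by_pat[[i]]
    if (length(ii) == 0) {
      acc_pid[[i]] <- staged$patient_id[i]
      acc_start[[i]] <- w0; acc_stop[[i]] <- w1
      acc_lab[[i]] <- "no_drug"; acc_ncl[[i]] <- 0L
      next
    }
    # per-agent merged coverage
    ag <- fl_agent[ii]
    agents <- unique(ag)
    sp_start <- numeric(0); sp_stop <- numeric(0); sp_agent <- integer(0)
    for (a in seq_along(agents)) {
      sel <- ii[ag == agents[a]]
      ms <- merge_spans(fl_day[sel], fl_day[sel] + fl_supply[sel], grace_days)
      sp_start <- c(sp_start, ms[, 1])
      sp_stop <- c(sp_stop, ms[, 2])
      sp_agent <- c(sp_agent, rep.int(a, nrow(ms)))
    }
    # switch rule: truncate an agent with < grace residual at a new start
    for (s in sort(unique(sp_start))) {
      trunc <- sp_start < s & sp_stop > s & sp_stop - s < grace_days
      sp_stop[trunc] <- s
    }
    ok <- sp_stop > sp_start
    sp_start <- sp_start[ok]; sp_stop <- sp_stop[ok]; sp_agent <- sp_agent[ok]
    # elementary intervals over the observation window
    cuts <- sort(unique(c(w0, w1, sp_start, sp_stop)))
    cuts <- cuts[cuts >= w0 & cuts <= w1]
    if (length(cuts) < 2) cuts <- c(w0, w1)
    lo <- cuts[-length(cuts)]; hi <- cuts[-1]
    mid <- (lo + hi) / 2
    lab <- character(length(lo))
    ncl <- integer(length(lo))
    for (j in seq_along(lo)) {
      act <- agents[unique(sp_agent[sp_start <= mid[j] & sp_stop > mid[j]])]
      li <- label_of(sort(act))
      lab[j] <- li[[1]]
      ncl[j] <- li[[2]]
    }
    keep <- c(TRUE, lab[-1] != lab[-length(lab)])
    run_end <- c(which(keep[-1]) , length(lab))
    acc_pid[[i]] <- rep(staged$patient_id[i], sum(keep))
    acc_start[[i]] <- lo[keep]
    acc_stop[[i]] <- hi[run_end]
    acc_lab[[i]] <- lab[keep]
    acc_ncl[[i]] <- ncl[keep]
  }
  out <- tibble::tibble(
    patient_id = unlist(acc_pid, use.names = FALSE),
    start_day = unlist(acc_start, use.names = FALSE),
    stop_day = unlist(acc_stop, use.names = FALSE),
    regimen = unlist(acc_lab, use.names = FALSE),
    n_classes = unlist(acc_ncl, use.names = FALSE)
  )
  # event flag on the terminal interval of outcome patients
  ev <- stats::setNames(staged$end_reason == "outcome", staged$patient_id)
  last <- !duplicated(out$patient_id, fromLast = TRUE)
  out$event <- last & unname(ev[out$patient_id])
  out
}

#' Collapse rare regimens into pooled categories
#'
#' Regimens that fail the power requisites (at least `min_intervals`
#' intervals and at least `min_events` events overall) are pooled:
#' monotherapies into `UNCOMMON_MONOTHERAPY`, within-class multi-agent
#' regimens and two-class combinations into `POLYPHARMACY_2`, and three-
#' and four-or-more-class combinations into `POLYPHARMACY_3` /
#' `POLYPHARMACY_4`. `"no_drug"` is never collapsed.
#'
#' @param intervals Output of [assign_regimen_timeline()].
#' @param min_intervals Minimum interval count to retain a named regimen.
#' @param min_events Minimum event count to retain a named regimen.
#' @return `intervals` with `regimen` relabeled; the pre/post catalog is in
#'   `attr(, "catalog")` (label, n_intervals, n_events, collapsed_to).
#' @export
collapse_regimens <- function(intervals, min_intervals = 1000, min_events = 5) {
  if (min_intervals < 1 || min_events < 1) {
    stop("collapse thresholds must be >= 1", call. = FALSE)
  }
  cat0 <- dplyr::summarise(
    dplyr::group_by(intervals, .data$regimen),
    n_intervals = dplyr::n(),
    n_events = sum(.data$event),
    n_classes = .data$n_classes[1],
    .groups = "drop"
  )
  keep <- cat0$regimen == "no_drug" |
    (cat0$n_intervals >= min_intervals & cat0$n_events >= min_events)
  pooled <- dplyr::case_when(
    keep ~ cat0$regimen,
    cat0$n_classes <= 1 & !grepl("MULTI_", cat0$regimen) ~ "UNCOMMON_MONOTHERAPY",
    cat0$n_classes <= 2 ~ "POLYPHARMACY_2",
    cat0$n_classes == 3 ~ "POLYPHARMACY_3",
    TRUE ~ "POLYPHARMACY_4"
  )
  map <- stats::setNames(pooled, cat0$regimen)
  out <- intervals
  out$regimen <- unname(map[intervals$regimen])
  catalog <- cat0
  catalog$collapsed_to <- pooled
  attr(out, "catalog") <- catalog
  out
}

#' Emit counting-process rows for the Cox models
#'
#' One row per exposure interval with start/stop times relative to the
#' index exposure day (time zero), the event flag on the terminal interval
#' of outcome patients, a time-varying psychotherapy indicator (any
#' psychotherapy procedure code during the interval), the time-updated
#' count of unique BD drugs previously tried (lookback-year fills plus
#' agents started before the current interval), and the baseline covariates
#' replicated across a patient's rows.
#'
#' @param staged Output of [stage_patients()].
#' @param intervals Labeled intervals (after [collapse_regimens()]).
#' @param metavisits Meta-visits (for psychotherapy procedure days).
#' @param fills Fills tibble.
#' @param vocab A `code_vocabulary`.
#' @param baseline Output of [extract_baseline_covariates()] (optional).
#' @return Tibble of counting-process rows: patient_id, start, stop, event,
#'   regimen, psychotherapy, prior_unique_bd_drugs, plus baseline columns.
#' @export
emit_counting_process <- function(staged, intervals, metavisits, fills, vocab,
                                  baseline = NULL) {
  stopifnot(inherits(vocab, "code_vocabulary"))
  rows <- dplyr::inner_join(
    intervals,
    staged[, c("patient_id", "index_exposure_day", "observation_end_day")],
    by = "patient_id"
  )
  bad <- rows$start_day < rows$index_exposure_day |
    rows$stop_day > rows$observation_end_day
  if (any(bad)) {
    stop("interval outside the observation window for ",
         paste(utils::head(unique(rows$patient_id[bad]), 5), collapse = ", "),
         call. = FALSE)
  }
  rows$start <- rows$start_day - rows$index_exposure_day
  rows$stop <- rows$stop_day - rows$index_exposure_day

  # psychotherapy: any psychotherapy-coded meta-visit day inside the interval
  psy <- codes_with_role(vocab, "psychotherapy_procedure")
  mv <- metavisits[codes_any_in(metavisits$codes, psy),
                   c("patient_id", "start_day")]
  rows$.row <- seq_len(nrow(rows))
  if (nrow(mv) > 0) {
    hit <- dplyr::inner_join(rows[, c(".row", "patient_id", "start_day",
                                      "stop_day")],
                             mv, by = "patient_id", suffix = c("", ".psy"),
                             relationship = "many-to-many")
    hit <- hit[hit$start_day.psy >= hit$start_day &
                 hit$start_day.psy < hit$stop_day, ]
    rows$psychotherapy <- as.numeric(rows$.row %in% hit$.row)
  } else {
    rows$psychotherapy <- 0
  }

  # time-updated unique BD drugs previously tried
  agent_of <- stats::setNames(vocab$drugs$agent, vocab$drugs$drug_id)
  fl <- fills[fills$drug_id %in% vocab$drugs$drug_id, ]
  fl <- dplyr::inner_join(fl, staged[, c("patient_id", "index_exposure_day")],
                          by = "patient_id")
  fl <- fl[fl$fill_day >= fl$index_exposure_day - 365, ]
  fl$agent <- unname(agent_of[fl$drug_id])
  firsts <- dplyr::summarise(
    dplyr::group_by(fl, .data$patient_id, .data$agent),
    first_day = min(.data$fill_day), .groups = "drop"
  )
  if (nrow(firsts) > 0) {
    cj <- dplyr::inner_join(rows[, c(".row", "patient_id", "start_day")],
                            firsts, by = "patient_id",
                            relationship = "many-to-many")
    cj <- cj[cj$first_day < cj$start_day, ]
    cnt <- dplyr::summarise(dplyr::group_by(cj, .data$.row),
                            n = dplyr::n_distinct(.data$agent),
                            .groups = "drop")
    rows$prior_unique_bd_drugs <- 0
    rows$prior_unique_bd_drugs[cnt$.row] <- cnt$n
  } else {
    rows$prior_unique_bd_drugs <- 0
  }

  out <- rows[, c("patient_id", "start", "stop", "event", "regimen",
                  "psychotherapy", "prior_unique_bd_drugs")]
  if (!is.null(baseline)) {
    bl <- baseline[, setdiff(names(baseline), "index_exposure_day")]
    out <- dplyr::left_join(out, bl, by = "patient_id")
  }
  out
}
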