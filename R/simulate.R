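# Synthetic longitudinal claims generator with planted ground truth.
#
# Time is day-indexed (day 0 = simulation start); visit intervals are closed
# on both ends, drug coverage and exposure intervals are half-open.

#' Simulate a synthetic claims population
#'
#' Generates patients with enrollment spans, bipolar-disorder diagnosis
#' visits, drug-regimen exposure episodes assigned with confounding, true
#' self-harm events from a piecewise-constant-hazard exponential process,
#' visit streams in three settings, and outpatient drug fills. Each true
#' event produces an inpatient-or-ER visit that always carries a bundle of
#' 3-8 proxy injury codes and carries an explicit self-harm code only with
#' probability `gt$coding_fraction`, emulating outcome under-recording.
#'
#' @param gt A [ground_truth()] object.
#' @param vocab A [generate_vocabulary()] object; defaults to one generated
#'   from the same seed.
#' @param n_patients Number of patients (>= 1).
#' @param horizon_days Simulation horizon in days.
#' @param seed Integer seed; all output tables are byte-identical for a
#'   fixed seed.
#' @param outpatient_rate Background outpatient visit rate per person-day.
#' @param nonevent_hosp_rate Rate per person-day of inpatient/ER visits
#'   unrelated to self-harm (these later act as censoring events and as
#'   class-0 training examples).
#' @param frac_two_bd Fraction of patients receiving two or more BD
#'   diagnosis codes (the rest fail eligibility).
#' @param exclusion_frac Fraction of patients carrying an excluding
#'   major-mental-illness diagnosis code.
#' @param censor_condition_frac Fraction of patients developing a censoring
#'   condition after the index day.
#' @param antidementia_frac Fraction of patients with an anti-dementia drug
#'   fill after the index day.
#' @param episode_mean_days Mean exposure-episode duration (days), on top of
#'   a 30-day minimum.
#' @param start_year Calendar year corresponding to day 0.
#' @return Object of class `claims_sim`: list with tibbles `patients`,
#'   `visits`, `fills`, plus oracle tables `episodes`, `events`,
#'   `confounder_status`, and the `vocab`/`ground_truth` used.
#' @export
simulate_population <- function(gt, vocab = generate_vocabulary(seed = gt$seed),
                                n_patients = 2000, horizon_days = 2000,
                                seed = gt$seed,
                                outpatient_rate = 6 / 365,
                                nonevent_hosp_rate = 0.4 / 365,
                                frac_two_bd = 0.95,
                                exclusion_frac = 0.05,
                                censor_condition_frac = 0.01,
                                antidementia_frac = 0.004,
                                episode_mean_days = 150,
                                start_year = 2010) {
  stopifnot(inherits(gt, "ground_truth"), inherits(vocab, "code_vocabulary"))
  if (n_patients < 1) stop("`n_patients` must be >= 1", call. = FALSE)
  withr_seed(seed)

  n <- n_patients
  pid <- sprintf("P%06d", seq_len(n))
  enroll_start <- sample(0:120, n, replace = TRUE)
  span <- pmin(horizon_days - enroll_start,
               500L + as.integer(round(stats::rexp(n, 1 / 1100))))
  enroll_end <- enroll_start + span
  patients <- tibble::tibble(
    patient_id = pid,
    sex = sample(c("M", "F"), n, replace = TRUE),
    birth_year = start_year - as.integer(round(stats::runif(n, 15, 80))),
    enroll_start_day = enroll_start,
    enroll_end_day = enroll_end
  )

  # patient-level binary confounders
  conf <- gt$confounders
  k_conf <- nrow(conf)
  C <- matrix(0L, n, max(k_conf, 1))
  if (k_conf > 0) {
    for (i in seq_len(k_conf)) C[, i] <- stats::rbinom(n, 1, conf$prevalence[i])
  }
  conf_lp <- if (k_conf > 0) as.numeric(C[, seq_len(k_conf), drop = FALSE] %*%
                                          conf$hazard_effect) else numeric(n)

  bg_leaf <- codes_with_role(vocab, "background")
  # dedicate one background code per confounder; keep them out of the noise
  # pool so baseline covariates built on them are clean indicators
  conf_codes <- character(0)
  if (k_conf > 0) {
    conf_codes <- stats::setNames(utils::tail(bg_leaf, k_conf), conf$name)
    bg_noise <- setdiff(bg_leaf, conf_codes)
  } else {
    bg_noise <- bg_leaf
  }
  bd_codes <- codes_with_role(vocab, "bd_diagnosis")
  sh_codes <- codes_with_role(vocab, "self_harm")
  px_codes <- codes_with_role(vocab, "proxy_injury")
  px_codes <- px_codes[px_codes != "PX_ROOT"]
  mmi_codes <- codes_with_role(vocab, "exclusion_mmi")
  cen_codes <- codes_with_role(vocab, "censoring_condition")
  psy_codes <- codes_with_role(vocab, "psychotherapy_procedure")
  role_leaves <- function(x) x[!grepl("_ROOT$", x)]
  bd_codes <- role_leaves(bd_codes); sh_codes <- role_leaves(sh_codes)
  mmi_codes <- role_leaves(mmi_codes); cen_codes <- role_leaves(cen_codes)
  psy_codes <- role_leaves(psy_codes)

  # ---- BD diagnosis visits and the planted index visit ----------------------
  index_day <- enroll_start + 366L + sample(0:60, n, replace = TRUE)
  has_two_bd <- stats::rbinom(n, 1, frac_two_bd) == 1
  v_bd1 <- tibble::tibble(
    patient_id = pid, setting = "outpatient",
    start_day = enroll_start + sample(5:60, n, replace = TRUE),
    codes = as.list(sample(bd_codes, n, replace = TRUE))
  )
  v_bd1$end_day <- v_bd1$start_day
  v_index <- tibble::tibble(
    patient_id = pid[has_two_bd], setting = "outpatient",
    start_day = index_day[has_two_bd],
    codes = as.list(sample(bd_codes, sum(has_two_bd), replace = TRUE))
  )
  v_index$end_day <- v_index$start_day

  # ---- exposure episodes ----------------------------------------------------
  labels <- names(gt$regimen_log_hr)
  L <- length(labels)
  drug_idx <- which(labels != "no_drug")
  log_w <- log(gt$regimen_base_weights)
  tilt <- matrix(0, n, L)
  if (k_conf > 0) {
    for (i in seq_len(k_conf)) {
      carriers <- C[, i] == 1
      tgt <- conf$target[i]
      if (is.na(tgt)) {
        tilt[carriers, drug_idx] <- tilt[carriers, drug_idx] + conf$assign_effect[i]
      } else {
        j <- match(tgt, labels)
        if (is.na(j)) stop("confounder target not a regimen label: ", tgt,
                           call. = FALSE)
        tilt[carriers, j] <- tilt[carriers, j] + conf$assign_effect[i]
      }
    }
  }

  eps <- vector("list", 128)
  t_cur <- index_day
  active <- rep(TRUE, n)
  rnd <- 0L
  while (any(active) && rnd < 120L) {
    rnd <- rnd + 1L
    idx <- which(active)
    m <- length(idx)
    dur <- 30L + as.integer(round(stats::rexp(m, 1 / episode_mean_days)))
    gumbel <- -log(-log(stats::runif(m * L)))
    score <- matrix(rep(log_w, each = m), m, L) + tilt[idx, , drop = FALSE] +
      matrix(gumbel, m, L)
    lab <- labels[max.col(score)]
    stop_at <- pmin(t_cur[idx] + dur, enroll_end[idx])
    eps[[rnd]] <- tibble::tibble(
      patient_id = pid[idx], start = t_cur[idx], stop = stop_at,
      regimen = lab,
      psychotherapy = stats::rbinom(m, 1, gt$psychotherapy_prob),
      preindex = FALSE
    )
    t_cur[idx] <- stop_at
    active[idx] <- stop_at < enroll_end[idx]
  }
  pre <- tibble::tibble(
    patient_id = pid, start = enroll_start, stop = index_day,
    regimen = "no_drug", psychotherapy = 0L, preindex = TRUE
  )
  episodes <- dplyr::arrange(dplyr::bind_rows(pre, eps), .data$patient_id,
                             .data$start)

  # ---- true self-harm events (piecewise-constant hazard) --------------------
  pat_row <- match(episodes$patient_id, pid)
  lp <- gt$regimen_log_hr[episodes$regimen] + conf_lp[pat_row] +
    episodes$psychotherapy * gt$psychotherapy_log_hr
  haz <- gt$baseline_hazard * exp(lp)
  wait <- ifelse(haz > 0, stats::rexp(nrow(episodes)) / haz, Inf)
  hit <- wait < (episodes$stop - episodes$start)
  events <- tibble::tibble(
    patient_id = episodes$patient_id[hit],
    true_event_day = as.integer(floor(episodes$start[hit] + wait[hit])),
    regimen = episodes$regimen[hit],
    preindex = episodes$preindex[hit]
  )
  events$was_coded <- stats::rbinom(nrow(events), 1, gt$coding_fraction) == 1

  # ---- event visits (inpatient/ER, proxy bundle, coded with probability) ----
  n_ev <- nrow(events)
  v_event <- NULL
  if (n_ev > 0) {
    n_px <- sample(3:8, n_ev, replace = TRUE)
    n_noise <- sample(0:2, n_ev, replace = TRUE)
    ev_codes <- vector("list", n_ev)
    for (i in seq_len(n_ev)) {
      cds <- c(sample(px_codes, n_px[i]),
               if (n_noise[i] > 0) sample(bg_noise, n_noise[i]),
               if (events$was_coded[i]) sample(sh_codes, 1))
      ev_codes[[i]] <- cds
    }
    ev_end <- pmin(events$true_event_day + sample(0:3, n_ev, replace = TRUE),
                   enroll_end[match(events$patient_id, pid)])
    v_event <- tibble::tibble(
      patient_id = events$patient_id,
      setting = sample(c("inpatient", "ER"), n_ev, replace = TRUE),
      start_day = events$true_event_day, end_day = ev_end, codes = ev_codes
    )
  }

  # ---- background outpatient + non-event inpatient/ER visits ----------------
  rand_visits <- function(rate, settings) {
    n_v <- stats::rpois(n, span * rate)
    tot <- sum(n_v)
    if (tot == 0) return(NULL)
    owner <- rep(seq_len(n), n_v)
    day <- enroll_start[owner] +
      as.integer(floor(stats::runif(tot) * (span[owner] + 1)))
    n_c <- sample(1:2, tot, replace = TRUE)
    all_codes <- sample(bg_noise, sum(n_c), replace = TRUE)
    tibble::tibble(
      patient_id = pid[owner],
      setting = sample(settings, tot, replace = TRUE),
      start_day = day, end_day = day,
      codes = unname(split(all_codes, rep(seq_len(tot), n_c)))
    )
  }
  v_out <- rand_visits(outpatient_rate, "outpatient")
  v_hosp <- rand_visits(nonevent_hosp_rate, c("inpatient", "ER"))

  # confounder carriers get a guaranteed lookback visit carrying their code
  v_conf <- NULL
  if (k_conf > 0) {
    rows <- list()
    for (i in seq_len(k_conf)) {
      carriers <- which(C[, i] == 1)
      if (!length(carriers)) next
      d <- index_day[carriers] - sample(30:300, length(carriers), replace = TRUE)
      d <- pmax(d, enroll_start[carriers])
      rows[[i]] <- tibble::tibble(
        patient_id = pid[carriers], setting = "outpatient",
        start_day = d, end_day = d,
        codes = as.list(rep(unname(conf_codes[i]), length(carriers)))
      )
    }
    v_conf <- dplyr::bind_rows(rows)
  }

  # psychotherapy procedure visits within flagged episodes
  post_psy <- episodes[!episodes$preindex & episodes$psychotherapy == 1, ]
  v_psy <- NULL
  if (nrow(post_psy) > 0) {
    d <- post_psy$start + as.integer(floor(stats::runif(nrow(post_psy)) *
      pmin(21, post_psy$stop - post_psy$start)))
    v_psy <- tibble::tibble(
      patient_id = post_psy$patient_id, setting = "outpatient",
      start_day = d, end_day = d,
      codes = as.list(sample(psy_codes, nrow(post_psy), replace = TRUE))
    )
  }

  # excluding MMI diagnoses, censoring conditions
  one_code_visits <- function(who, codeset, day) {
    if (!length(who)) return(NULL)
    tibble::tibble(
      patient_id = pid[who], setting = "outpatient",
      start_day = day, end_day = day,
      codes = as.list(sample(codeset, length(who), replace = TRUE))
    )
  }
  mmi_who <- which(stats::rbinom(n, 1, exclusion_frac) == 1)
  v_mmi <- one_code_visits(
    mmi_who, mmi_codes,
    enroll_start[mmi_who] +
      as.integer(floor(stats::runif(length(mmi_who)) * (span[mmi_who] + 1)))
  )
  cen_who <- which(stats::rbinom(n, 1, censor_condition_frac) == 1 &
                     index_day + 30 < enroll_end)
  v_cen <- one_code_visits(
    cen_who, cen_codes,
    index_day[cen_who] + as.integer(floor(stats::runif(length(cen_who)) *
      (enroll_end[cen_who] - index_day[cen_who])))
  )

  visits <- dplyr::bind_rows(v_bd1, v_index, v_event, v_out, v_hosp, v_conf,
                             v_psy, v_mmi, v_cen)
  visits <- dplyr::arrange(visits, .data$patient_id, .data$start_day,
                           .data$setting)
  visits <- visits[, c("patient_id", "setting", "start_day", "end_day", "codes")]

  # ---- fills ----------------------------------------------------------------
  agent_cache <- lapply(
    stats::setNames(nm = setdiff(labels, "no_drug")), regimen_agents, vocab = vocab
  )
  drug_eps <- episodes[!episodes$preindex & episodes$regimen != "no_drug", ]
  fills <- NULL
  if (nrow(drug_eps) > 0) {
    drug_eps$agents <- agent_cache[drug_eps$regimen]
    fl <- tidyr::unnest(drug_eps[, c("patient_id", "start", "stop", "agents")],
                        cols = "agents")
    n_f <- ceiling((fl$stop - fl$start) / 30)
    fl <- fl[rep(seq_len(nrow(fl)), n_f), ]
    off <- (unlist(lapply(n_f, seq_len)) - 1L) * 30L
    fl$fill_day <- fl$start + off
    fl$days_supply <- as.integer(pmin(30L, fl$stop - fl$fill_day))
    drug_map <- stats::setNames(vocab$drugs$drug_id, vocab$drugs$agent)
    fills <- tibble::tibble(
      patient_id = fl$patient_id, drug_id = unname(drug_map[fl$agents]),
      fill_day = as.integer(fl$fill_day), days_supply = fl$days_supply
    )
  }
  adem_who <- which(stats::rbinom(n, 1, antidementia_frac) == 1 &
                      index_day + 30 < enroll_end)
  if (length(adem_who)) {
    fills <- dplyr::bind_rows(fills, tibble::tibble(
      patient_id = pid[adem_who], drug_id = vocab$antidementia$drug_id[1],
      fill_day = index_day[adem_who] +
        as.integer(floor(stats::runif(length(adem_who)) *
          (enroll_end[adem_who] - index_day[adem_who]))),
      days_supply = 30L
    ))
  }
  if (is.null(fills)) {
    fills <- tibble::tibble(patient_id = character(), drug_id = character(),
                            fill_day = integer(), days_supply = integer())
  }
  fills <- dplyr::arrange(fills, .data$patient_id, .data$fill_day, .data$drug_id)

  conf_status <- tibble::tibble(patient_id = pid)
  if (k_conf > 0) {
    for (i in seq_len(k_conf)) conf_status[[conf$name[i]]] <- C[, i]
  }

  structure(
    list(
      patients = patients, visits = visits, fills = fills,
      episodes = episodes,
      events = events[, c("patient_id", "true_event_day", "was_coded",
                          "regimen", "preindex")],
      confounder_status = conf_status,
      confounder_codes = conf_codes,
      index_day = tibble::tibble(patient_id = pid, planted_index_day = index_day),
      vocab = vocab, ground_truth = gt,
      params = list(n_patients = n, horizon_days = horizon_days, seed = seed,
                    start_year = start_year)
    ),
    class = "claims_sim"
  )
}

#' Oracle table of true self-harm events
#'
#' Ground-truth listing of every true event in a simulated population,
#' including whether it received an explicit self-harm code. Used for
#' recovery and calibration tests; never available in real claims.
#'
#' @param sim A `claims_sim` object.
#' @return Tibble with columns patient_id, true_event_day, was_coded.
#' @export
oracle_event_table <- function(sim) {
  if (!inherits(sim, "claims_sim")) {
    stop("`sim` must be a generated `claims_sim` population", call. = FALSE)
  }
  sim$events[, c("patient_id", "true_event_day", "was_coded")]
}

#' @export
print.claims_sim <- function(x, ...) {
  cat("<claims_sim>", nrow(x$patients), "patients,", nrow(x$visits), "visits,",
      nrow(x$fills), "fills,", nrow(x$events), "true events (",
      sum(x$events$was_coded), "coded )\n")
  invisible(x)
}

#' Write a simulated population as delimited tables
#'
#' Writes `patients.csv`, `visits.csv` (codes `;`-joined), `fills.csv`,
#' `vocabulary.csv` and `ground_truth.json` into a directory.
#'
#' @param sim A `claims_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_claims <- function(sim, dir) {
  stopifnot(inherits(sim, "claims_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(sim$patients, file.path(dir, "patients.csv"))
  v <- sim$visits
  v$codes <- vapply(v$codes, paste, character(1), collapse = ";")
  readr::write_csv(v, file.path(dir, "visits.csv"))
  readr::write_csv(sim$fills, file.path(dir, "fills.csv"))
  vocab <- sim$vocab
  parents <- vapply(
    split(vocab$parent_links$parent, vocab$parent_links$code)[vocab$codes$code],
    function(p) if (is.null(p)) "" else paste(p, collapse = ";"), character(1)
  )
  vtab <- dplyr::bind_rows(
    dplyr::mutate(vocab$codes, parents = unname(parents), agent = NA_character_,
                  class = NA_character_),
    tibble::tibble(code = vocab$drugs$drug_id, role = "drug", depth = NA_integer_,
                   subtype = NA_character_, parents = "",
                   agent = vocab$drugs$agent, class = vocab$drugs$class),
    tibble::tibble(code = vocab$antidementia$drug_id, role = "antidementia_drug",
                   depth = NA_integer_, subtype = NA_character_, parents = "",
                   agent = vocab$antidementia$agent, class = NA_character_)
  )
  readr::write_csv(vtab, file.path(dir, "vocabulary.csv"))
  gt <- sim$ground_truth
  jsonlite::write_json(
    list(regimen_log_hr = as.list(gt$regimen_log_hr),
         regimen_base_weights = as.list(gt$regimen_base_weights),
         confounders = gt$confounders,
         psychotherapy_log_hr = gt$psychotherapy_log_hr,
         psychotherapy_prob = gt$psychotherapy_prob,
         coding_fraction = gt$coding_fraction,
         baseline_hazard = gt$baseline_hazard, seed = gt$seed),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read claims tables written by [write_claims()]
#'
#' @param dir Directory containing the delimited tables.
#' @return List with tibbles `patients`, `visits` (codes as list-column),
#'   `fills`, and the reconstructed `vocab`.
#' @export
read_claims <- function(dir) {
  patients <- readr::read_csv(file.path(dir, "patients.csv"),
                              show_col_types = FALSE)
  visits <- readr::read_csv(file.path(dir, "visits.csv"), show_col_types = FALSE)
  visits$codes <- strsplit(visits$codes, ";", fixed = TRUE)
  fills <- readr::read_csv(file.path(dir, "fills.csv"), show_col_types = FALSE,
                           col_types = readr::cols(patient_id = "c", drug_id = "c"))
  vtab <- readr::read_csv(file.path(dir, "vocabulary.csv"), show_col_types = FALSE)
  is_code <- !vtab$role %in% c("drug", "antidementia_drug")
  codes <- vtab[is_code, c("code", "role", "depth", "subtype")]
  pl <- vtab[is_code & !is.na(vtab$parents) & vtab$parents != "", ]
  parent_links <- tibble::tibble(
    code = rep(pl$code, lengths(strsplit(pl$parents, ";"))),
    parent = unlist(strsplit(pl$parents, ";"))
  )
  vocab <- structure(
    list(codes = tibble::as_tibble(codes), parent_links = parent_links,
         drugs = tibble::tibble(
           drug_id = vtab$code[vtab$role == "drug"],
           agent = vtab$agent[vtab$role == "drug"],
           class = vtab$class[vtab$role == "drug"]
         ),
         antidementia = tibble::tibble(
           drug_id = vtab$code[vtab$role == "antidementia_drug"],
           agent = vtab$agent[vtab$role == "antidementia_drug"]
         )),
    class = "code_vocabulary"
  )
  list(patients = patients, visits = tibble::as_tibble(visits), fills = fills,
       vocab = vocab)
}
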