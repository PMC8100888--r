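# Meta-visits: merged runs of temporally contiguous visits, treated as one
# care episode across outpatient/inpatient/ER settings.

#' Merge consecutive visits into meta-visits
#'
#' Visits of a patient are merged into a single meta-visit whenever they
#' overlap or (by default) abut on adjacent calendar days: a visit joins the
#' current meta-visit when its `start_day` is at most the running maximum
#' `end_day` plus `gap_days`. With `gap_days = 1` a transfer discharged on
#' day d and admitted on day d+1 stays one episode; `gap_days = 0` merges
#' same-day/overlapping spans only.
#'
#' Codes and settings of a meta-visit are the unions over the merged visits.
#' The partition is independent of the input row order.
#'
#' @param visits Tibble with columns patient_id, setting, start_day,
#'   end_day, and a list-column `codes`.
#' @param gap_days Maximum day gap that still merges (default 1 = adjacent
#'   days merge).
#' @return Tibble with one row per meta-visit: patient_id, metavisit_id,
#'   start_day, end_day, settings (list), codes (list), n_visits,
#'   has_inpatient_or_er; ordered by patient and start day.
#' @export
build_meta_visits <- function(visits, gap_days = 1) {
  req <- c("patient_id", "setting", "start_day", "end_day", "codes")
  if (!all(req %in% names(visits))) {
    stop("`visits` must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(visits$start_day > visits$end_day)) {
    bad <- which(visits$start_day > visits$end_day)
    stop("invalid visit interval (start_day > end_day) at rows ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  v <- dplyr::arrange(visits, .data$patient_id, .data$start_day, .data$end_day)
  # per-patient running cummax of end_day without grouped evaluation: shift
  # each patient's days by a distinct large offset, take one global cummax
  p_idx <- match(v$patient_id, unique(v$patient_id))
  big <- max(v$end_day) - min(c(v$start_day, 0)) + 2
  shifted <- cummax(v$end_day + p_idx * big) - p_idx * big
  new_pat <- !duplicated(v$patient_id)
  reach <- c(-Inf, shifted[-length(shifted)])
  reach[new_pat] <- -Inf
  v$.grp <- cumsum(new_pat | v$start_day > reach + gap_days)
  # renumber within patient
  v$.grp <- v$.grp - rep.int(v$.grp[new_pat], rle(p_idx)$lengths) + 1L

  gid <- paste0(v$patient_id, "\r", v$.grp)
  g <- match(gid, unique(gid))                 # appearance order == sorted order
  n_g <- max(g)
  lens <- lengths(v$codes)
  # sorted + deduplicated code union per group, vectorized
  uc <- unlist(v$codes, use.names = FALSE)
  gg <- rep.int(g, lens)
  codes_list <- rep(list(character(0)), n_g)
  if (length(uc) > 0) {
    o <- order(gg, uc, method = "radix")
    gg <- gg[o]; uc <- uc[o]
    dup <- c(FALSE, gg[-1] == gg[-length(gg)] & uc[-1] == uc[-length(uc)])
    codes_by_g <- split(uc[!dup], gg[!dup])
    codes_list[as.integer(names(codes_by_g))] <- codes_by_g
  }

  first <- !duplicated(g)
  cmax <- shifted
  last <- !duplicated(g, fromLast = TRUE)
  set_flag <- function(setting) {
    as.logical(rowsum(as.integer(v$setting == setting), g,
                      reorder = FALSE)[, 1] > 0)
  }
  f_out <- set_flag("outpatient"); f_inp <- set_flag("inpatient")
  f_er <- set_flag("ER")
  combos <- lapply(0:7, function(b) {
    sort(c(if (bitwAnd(b, 1)) "outpatient", if (bitwAnd(b, 2)) "inpatient",
           if (bitwAnd(b, 4)) "ER"))
  })
  out <- tibble::tibble(
    patient_id = v$patient_id[first],
    start_day = v$start_day[first],
    end_day = cmax[last],
    n_visits = tabulate(g, n_g),
    has_inpatient_or_er = f_inp | f_er,
    settings = combos[1 + f_out + 2 * f_inp + 4 * f_er],
    codes = codes_list
  )
  out$metavisit_id <- paste0(out$patient_id, "_",
                             sequence(rle(out$patient_id)$lengths))
  out$.grp <- NULL
  out[, c("patient_id", "metavisit_id", "start_day", "end_day", "settings",
          "codes", "n_visits", "has_inpatient_or_er")]
}

#' Label the coded self-harm phenotype on meta-visits
#'
#' A meta-visit is class 1 (`coded_selfharm = TRUE`) when its code set
#' contains one or more codes from the vocabulary's self-harm set, class 0
#' otherwise. Codes absent from the vocabulary trigger a warning and are
#' treated as background.
#'
#' @param metavisits Output of [build_meta_visits()].
#' @param vocab A `code_vocabulary` with a non-empty self-harm code set.
#' @return `metavisits` with a logical `coded_selfharm` column.
#' @export
label_coded_selfharm <- function(metavisits, vocab) {
  stopifnot(inherits(vocab, "code_vocabulary"))
  sh <- codes_with_role(vocab, "self_harm")
  if (length(sh) == 0) stop("vocabulary has no self-harm codes", call. = FALSE)
  seen <- unique(unlist(metavisits$codes))
  unknown <- setdiff(seen, vocab$codes$code)
  if (length(unknown) > 0) {
    warning(length(unknown), " code(s) not in vocabulary; treated as background",
            call. = FALSE)
  }
  metavisits$coded_selfharm <- codes_any_in(metavisits$codes, sh)
  metavisits
}
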