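# Synthetic code vocabulary: a small DAG of billing codes with role flags and
# a drug -> class map, standing in for a SNOMED-like concept hierarchy.

#' Drug classes used in bipolar-disorder pharmacotherapy
#'
#' The eleven drug classes analysed by the pipeline: lithium, mood-stabilizing
#' anticonvulsants (MSA), second-/third-/first-generation antipsychotics
#' (SGA/TGA/FGA), and five antidepressant classes.
#'
#' @format Character vector of length 11.
#' @export
bd_drug_classes <- c(
  "LITHIUM", "MSA", "SGA", "TGA", "FGA",
  "SSRI", "SNRI", "NDRI", "NASSA", "TRI_TETRA", "MAOI"
)

default_drug_table <- function() {
  tibble::tribble(
    ~drug_id, ~agent,          ~class,
    "D01",    "lithium",       "LITHIUM",
    "D02",    "valproate",     "MSA",
    "D03",    "lamotrigine",   "MSA",
    "D04",    "carbamazepine", "MSA",
    "D05",    "risperidone",   "SGA",
    "D06",    "quetiapine",    "SGA",
    "D07",    "olanzapine",    "SGA",
    "D08",    "clozapine",     "SGA",
    "D09",    "aripiprazole",  "TGA",
    "D10",    "haloperidol",   "FGA",
    "D11",    "fluoxetine",    "SSRI",
    "D12",    "sertraline",    "SSRI",
    "D13",    "venlafaxine",   "SNRI",
    "D14",    "bupropion",     "NDRI",
    "D15",    "mirtazapine",   "NASSA",
    "D16",    "amitriptyline", "TRI_TETRA",
    "D17",    "phenelzine",    "MAOI"
  )
}

#' Generate a synthetic hierarchical code vocabulary
#'
#' Builds an acyclic child-to-parent code hierarchy with one code set per
#' role (self-harm, bipolar diagnosis, excluding major-mental-illness
#' diagnoses, censoring conditions, psychotherapy procedures, proxy injury
#' codes, background noise codes) plus a drug table covering all eleven
#' drug classes and a separate anti-dementia drug list used as a censoring
#' trigger.
#'
#' Background codes are arranged in `max_depth` levels; every code below the
#' root level has one or two parents in the level above, so ancestor closure
#' always terminates. Role-specific codes hang off dedicated role roots,
#' which makes the "exclusive ancestors of the self-harm set" well defined
#' for feature exclusion.
#'
#' @param n_background_codes Number of background (noise) codes, at least 10.
#' @param max_depth Number of hierarchy levels for background codes (>= 1).
#' @param seed Integer seed; the vocabulary is deterministic given the seed.
#' @param n_self_harm,n_proxy,n_bd,n_exclusion,n_censoring,n_psychotherapy
#'   Sizes of the role-specific code sets.
#' @return An object of class `code_vocabulary`: a list with tibbles
#'   `codes` (code, role, depth, subtype), `parent_links` (code, parent),
#'   `drugs` (drug_id, agent, class) and `antidementia` (drug_id, agent).
#' @export
generate_vocabulary <- function(n_background_codes = 120, max_depth = 3, seed = 1,
                                n_self_harm = 3, n_proxy = 10, n_bd = 4,
                                n_exclusion = 3, n_censoring = 3,
                                n_psychotherapy = 3) {
  if (n_background_codes < 10) {
    stop("`n_background_codes` must be at least 10", call. = FALSE)
  }
  if (max_depth < 1) stop("`max_depth` must be at least 1", call. = FALSE)
  withr_seed(seed)

  bg <- sprintf("BG%03d", seq_len(n_background_codes))
  depth <- sort(rep_len(seq_len(max_depth), n_background_codes))
  links <- list()
  if (max_depth > 1) {
    for (d in 2:max_depth) {
      children <- bg[depth == d]
      parents_pool <- bg[depth == d - 1]
      for (ch in children) {
        np <- sample(1:2, 1)
        links[[length(links) + 1]] <- tibble::tibble(
          code = ch, parent = sample(parents_pool, min(np, length(parents_pool)))
        )
      }
    }
  }

  role_set <- function(prefix, n, role, root_role = role) {
    root <- paste0(prefix, "_ROOT")
    leaves <- sprintf("%s%02d", prefix, seq_len(n))
    list(
      codes = tibble::tibble(
        code = c(root, leaves), role = c(root_role, rep(role, n)),
        depth = c(1L, rep(2L, n))
      ),
      links = tibble::tibble(code = leaves, parent = root)
    )
  }

  roles <- list(
    role_set("SH", n_self_harm, "self_harm"),
    role_set("PX", n_proxy, "proxy_injury"),
    role_set("BD", n_bd, "bd_diagnosis"),
    role_set("MMI", n_exclusion, "exclusion_mmi"),
    role_set("CEN", n_censoring, "censoring_condition"),
    role_set("PSY", n_psychotherapy, "psychotherapy_procedure")
  )

  codes <- dplyr::bind_rows(
    tibble::tibble(code = bg, role = "background", depth = as.integer(depth)),
    purrr::map(roles, "codes")
  )
  # index-visit characteristics: alternate BD codes between mood polarities
  codes$subtype <- NA_character_
  bd_leaves <- grep("^BD\\d", codes$code)
  codes$subtype[bd_leaves] <- rep_len(c("depression", "mania", NA), length(bd_leaves))

  parent_links <- dplyr::bind_rows(links, purrr::map(roles, "links"))

  vocab <- structure(
    list(
      codes = codes,
      parent_links = parent_links,
      drugs = default_drug_table(),
      antidementia = tibble::tibble(drug_id = "D90", agent = "donepezil")
    ),
    class = "code_vocabulary"
  )
  stopifnot(!vocab_has_cycle(vocab))
  vocab
}

# seed handling without polluting the caller's RNG stream
withr_seed <- function(seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
}

vocab_has_cycle <- function(vocab) {
  pl <- vocab$parent_links
  # DAG check by repeated leaf-stripping on the parent relation
  nodes <- unique(c(pl$code, pl$parent))
  edges <- pl
  while (nrow(edges) > 0) {
    leaves <- setdiff(nodes, edges$parent)  # nodes that are no one's parent
    drop <- edges$code %in% leaves
    if (!any(drop)) return(TRUE)
    edges <- edges[!drop, , drop = FALSE]
    nodes <- unique(c(edges$code, edges$parent))
  }
  FALSE
}

#' Codes carrying a given role flag
#'
#' @param vocab A `code_vocabulary`.
#' @param role One of the role flags (e.g. `"self_harm"`, `"bd_diagnosis"`).
#' @return Character vector of codes.
#' @export
codes_with_role <- function(vocab, role) {
  stopifnot(inherits(vocab, "code_vocabulary"))
  vocab$codes$code[vocab$codes$role == role]
}

#' Ancestor closure of a set of codes
#'
#' Returns the given codes together with every ancestor reachable through the
#' child-to-parent links (the code itself is part of its closure).
#'
#' @param vocab A `code_vocabulary`.
#' @param codes Character vector of code identifiers.
#' @return Character vector: the transitive closure over parents.
#' @export
ancestor_closure <- function(vocab, codes) {
  stopifnot(inherits(vocab, "code_vocabulary"))
  pl <- vocab$parent_links
  out <- unique(codes)
  frontier <- out
  while (length(frontier) > 0) {
    nxt <- setdiff(unique(pl$parent[pl$code %in% frontier]), out)
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

# named list code -> closure, for every code in the vocabulary
ancestor_map <- function(vocab) {
  all_codes <- vocab$codes$code
  parents <- split(vocab$parent_links$parent, vocab$parent_links$code)
  memo <- new.env(parent = emptyenv())
  closure <- function(code) {
    hit <- get0(code, envir = memo)
    if (!is.null(hit)) return(hit)
    ps <- parents[[code]]
    res <- if (is.null(ps)) code else unique(c(code, unlist(lapply(ps, closure))))
    assign(code, res, envir = memo)
    res
  }
  stats::setNames(lapply(all_codes, closure), all_codes)
}

# ancestors reachable only from the self-harm code set; these leak the label
# and are excluded from classifier features together with the set itself
selfharm_exclusive_ancestors <- function(vocab) {
  sh <- codes_with_role(vocab, "self_harm")
  others <- setdiff(vocab$codes$code, sh)
  setdiff(ancestor_closure(vocab, sh), ancestor_closure(vocab, others))
}

#' @export
print.code_vocabulary <- function(x, ...) {
  cat("<code_vocabulary>\n")
  cat("  codes:", nrow(x$codes), "(",
      paste(names(table(x$codes$role)), table(x$codes$role), collapse = ", "),
      ")\n")
  cat("  parent links:", nrow(x$parent_links), "\n")
  cat("  drugs:", nrow(x$drugs), "agents across",
      length(unique(x$drugs$class)), "classes\n")
  invisible(x)
}

# vectorized "any code of each list element in `set`" over a list-column
codes_any_in <- function(codes_list, set) {
  lens <- lengths(codes_list)
  if (sum(lens) == 0) return(rep(FALSE, length(codes_list)))
  hit <- unlist(codes_list, use.names = FALSE) %in% set
  as.logical(rowsum(as.integer(hit), rep.int(seq_along(codes_list), lens),
                    reorder = FALSE)[, 1] > 0)
}

# vectorized count of codes of each list element in `set`
codes_count_in <- function(codes_list, set) {
  lens <- lengths(codes_list)
  if (sum(lens) == 0) return(rep(0L, length(codes_list)))
  hit <- unlist(codes_list, use.names = FALSE) %in% set
  as.integer(rowsum(as.integer(hit), rep.int(seq_along(codes_list), lens),
                    reorder = FALSE)[, 1])
}
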