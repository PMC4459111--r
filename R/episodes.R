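#' Date-window rule for merging adjacent claims into one episode
#'
#' Long hospitalizations are billed monthly, transfers produce one claim
#' per hospital, and early readmissions for the same event produce separate
#' claims, so one clinical AMI episode can generate several claims. Two
#' adjacent claims of the same patient (sorted by admission date) belong to
#' the same episode when at least one of three conditions holds:
#'
#' * **C1** -- the second admission is within `admission_window_days` of the
#'   first admission (default 28);
#' * **C2** -- the second admission is within `discharge_window_days` of the
#'   first discharge (default 3); negative gaps count, so overlapping
#'   claims from two hospitals merge via C2;
#' * **C3** -- the length of stay of the second claim is less than
#'   `short_stay_days` (default 3).
#'
#' All window comparisons are inclusive ("within N days" means `<= N`).
#' C3 is applied literally, as one branch of the disjunction: a
#' sufficiently short second claim merges regardless of the time gap.
#' This is deliberate but worth knowing -- it can merge arbitrarily
#' distant short claims of the same patient.
#'
#' `anchor` controls how condition C1 chains: `"rolling"` (default)
#' compares each claim with the immediately preceding claim, so merges
#' chain transitively; `"index"` re-anchors C1 to the episode's first
#' claim. `los_counts_both_ends` switches the length-of-stay convention
#' from `discharge - admission` (same-day stay = 0, the default) to
#' `discharge - admission + 1`.
#'
#' @param admission_window_days Non-negative integer, C1 threshold (days).
#' @param discharge_window_days Non-negative integer, C2 threshold (days).
#' @param short_stay_days Non-negative integer, C3 threshold (days).
#' @param anchor `"rolling"` or `"index"`; see Details.
#' @param los_counts_both_ends Logical; count both admission and discharge
#'   day in the length of stay.
#' @return An object of class `ami_merge_rule`.
#' @examples
#' merge_rule()
#' merge_rule(admission_window_days = 14)
#' @export
merge_rule <- function(admission_window_days = 28,
                       discharge_window_days = 3,
                       short_stay_days = 3,
                       anchor = c("rolling", "index"),
                       los_counts_both_ends = FALSE) {
  anchor <- match.arg(anchor)
  for (v in list(admission_window_days, discharge_window_days, short_stay_days)) {
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v != trunc(v)) {
      rlang::abort("merge-rule thresholds must be non-negative integers",
                   class = "ami_config_error")
    }
  }
  stopifnot(rlang::is_bool(los_counts_both_ends))
  structure(
    list(
      admission_window_days = as.integer(admission_window_days),
      discharge_window_days = as.integer(discharge_window_days),
      short_stay_days = as.integer(short_stay_days),
      anchor = anchor,
      los_counts_both_ends = los_counts_both_ends
    ),
    class = "ami_merge_rule"
  )
}

#' @export
print.ami_merge_rule <- function(x, ...) {
  cat("<ami_merge_rule>\n")
  cat("  C1 admission window:", x$admission_window_days, "days (anchor:", x$anchor, ")\n")
  cat("  C2 discharge window:", x$discharge_window_days, "days\n")
  cat("  C3 short stay:      LOS <", x$short_stay_days, "days\n")
  invisible(x)
}

#' Length of stay of each claim
#'
#' Days between admission and discharge of one claim. The default
#' convention is `discharge_date - admission_date`, so a same-day
#' discharge counts as 0 days; with `los_counts_both_ends` set in the
#' rule, both end days count and a same-day discharge is 1 day.
#'
#' @param claims A validated claims tibble.
#' @param rule An [merge_rule()] carrying the day-count convention.
#' @return Integer vector of lengths of stay, one per claim.
#' @examples
#' cl <- as_claims(data.frame(
#'   claim_id = "C1", patient_id = "P1", provider_id = NA,
#'   sex = "male", age_years = 60,
#'   admission_date = "2007-01-01", discharge_date = "2007-01-04",
#'   admission_route = "emergency", dx_primary = "I21.9",
#'   dx_secondary = "", proc_codes = ""
#' ))
#' compute_los(cl)  # 3
#' @export
compute_los <- function(claims, rule = merge_rule()) {
  los <- as.integer(claims$discharge_date - claims$admission_date)
  if (isTRUE(rule$los_counts_both_ends)) los <- los + 1L
  los
}

#' Evaluate the three merge conditions for a pair of adjacent claims
#'
#' Given two claims of the same patient with `second` admitted no earlier
#' than `first`, evaluates conditions C1--C3 of the merge rule (see
#' [merge_rule()]) and the resulting merge decision. Vectorized: `first`
#' and `second` may be aligned multi-row claims tibbles.
#'
#' @param first,second Claims tibbles with the same number of rows;
#'   row `i` of `second` is compared against row `i` of `first`.
#' @param rule An [merge_rule()].
#' @return A tibble with logical columns `merge`, `c1`, `c2`, `c3`.
#' @export
merge_condition <- function(first, second, rule = merge_rule()) {
  if (nrow(first) != nrow(second)) {
    rlang::abort("`first` and `second` must have the same number of rows",
                 class = "ami_contract_error")
  }
  if (any(first$patient_id != second$patient_id)) {
    rlang::abort("merge_condition compares claims of the same patient only",
                 class = "ami_contract_error")
  }
  if (any(second$admission_date < first$admission_date)) {
    rlang::abort("`second` must not be admitted before `first` (sort claims first)",
                 class = "ami_contract_error")
  }
  gap_admission <- as.integer(second$admission_date - first$admission_date)
  gap_discharge <- as.integer(second$admission_date - first$discharge_date)
  c1 <- gap_admission <= rule$admission_window_days
  c2 <- gap_discharge <= rule$discharge_window_days
  c3 <- compute_los(second, rule) < rule$short_stay_days
  tibble::tibble(merge = c1 | c2 | c3, c1 = c1, c2 = c2, c3 = c3)
}

# Canonical claim order within which the sequential scan runs: by patient,
# then admission date, earlier discharge first, claim_id as final tie-break.
sort_claims <- function(claims) {
  claims[order(claims$patient_id, claims$admission_date,
               claims$discharge_date, claims$claim_id), ]
}

#' Collapse qualifying claims into discrete AMI admission episodes
#'
#' Per patient, claims are sorted by admission date (ties: earlier
#' discharge, then `claim_id`) and scanned sequentially: each claim joins
#' the current episode when [merge_condition()] against the anchor claim
#' fires, otherwise it opens a new episode. With the default rolling
#' anchor the comparison is against the immediately preceding claim; with
#' `anchor = "index"` condition C1 is evaluated against the episode's
#' first claim while C2/C3 still use the preceding claim. Claims are never
#' merged across patients, and every claim belongs to exactly one episode.
#'
#' Episode attributes come from [attribute_episode()]: calendar year, sex
#' and age are taken from the index (earliest) claim; the
#' emergency-department flag follows `ed_policy`; the invasive-procedure
#' flag is true when any member claim carries a configured procedure code.
#'
#' @param claims A validated claims tibble, normally the output of
#'   [select_ami_claims()].
#' @param rule An [merge_rule()].
#' @param case_def An [case_definition()] supplying the procedure code sets.
#' @param ed_policy `"index"` (default): the episode counts as an
#'   emergency-department admission when its index claim's route is
#'   `emergency`; `"any"`: when any member claim's route is.
#' @return An episodes tibble with columns `episode_id`, `patient_id`,
#'   `n_claims`, `member_claim_ids` (list-column, ordered by admission),
#'   `index_admission_date`, `final_discharge_date`, `year`, `sex`,
#'   `age_years`, `ed_admission`, `has_invasive`.
#' @examples
#' sim <- simulate_claims(generator_config(n_patients = 20, seed = 3))
#' eps <- build_episodes(sim$claims)
#' sum(eps$n_claims) == nrow(sim$claims)
#' @export
build_episodes <- function(claims, rule = merge_rule(),
                           case_def = case_definition(),
                           ed_policy = c("index", "any")) {
  ed_policy <- match.arg(ed_policy)
  claims <- as_claims(claims)
  if (nrow(claims) == 0) return(empty_episodes())
  cl <- sort_claims(claims)
  n <- nrow(cl)

  same_patient <- c(FALSE, cl$patient_id[-1] == cl$patient_id[-n])
  prev_admission <- c(cl$admission_date[1], cl$admission_date[-n])
  prev_discharge <- c(cl$discharge_date[1], cl$discharge_date[-n])
  los <- compute_los(cl, rule)

  c2 <- as.integer(cl$admission_date - prev_discharge) <= rule$discharge_window_days
  c3 <- los < rule$short_stay_days

  if (rule$anchor == "rolling") {
    c1 <- as.integer(cl$admission_date - prev_admission) <= rule$admission_window_days
    new_episode <- !(same_patient & (c1 | c2 | c3))
  } else {
    # C1 against the current episode's first claim: the anchor depends on the
    # running assignment, so this path scans claim by claim.
    new_episode <- logical(n)
    anchor_admission <- cl$admission_date[1]
    for (i in seq_len(n)) {
      if (i == 1 || !same_patient[i]) {
        new_episode[i] <- TRUE
      } else {
        c1_i <- as.integer(cl$admission_date[i] - anchor_admission) <=
          rule$admission_window_days
        new_episode[i] <- !(c1_i || c2[i] || c3[i])
      }
      if (new_episode[i]) anchor_admission <- cl$admission_date[i]
    }
  }

  cl$.episode <- cumsum(new_episode)
  flags <- classify_procedures(cl, case_def)
  cl$.invasive <- flags$has_invasive

  warn_attribute_conflicts(cl)

  ep <- cl |>
    dplyr::group_by(.data$.episode) |>
    dplyr::summarise(
      patient_id = dplyr::first(.data$patient_id),
      n_claims = dplyr::n(),
      member_claim_ids = list(.data$claim_id),
      index_admission_date = dplyr::first(.data$admission_date),
      final_discharge_date = max(.data$discharge_date),
      year = as.integer(format(dplyr::first(.data$admission_date), "%Y")),
      sex = dplyr::first(.data$sex),
      age_years = dplyr::first(.data$age_years),
      ed_admission = if (ed_policy == "index") {
        dplyr::first(.data$admission_route) == "emergency"
      } else {
        any(.data$admission_route == "emergency")
      },
      has_invasive = any(.data$.invasive),
      .groups = "drop"
    ) |>
    dplyr::select(-".episode")

  ep <- ep |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(episode_id = paste0(.data$patient_id, "-E",
                                      sprintf("%02d", dplyr::row_number()))) |>
    dplyr::ungroup() |>
    dplyr::relocate("episode_id")
  ep
}

# One warning (not one per claim) when sex or age disagrees within an
# episode; the index claim's values win.
warn_attribute_conflicts <- function(cl) {
  conflicts <- cl |>
    dplyr::group_by(.data$.episode) |>
    dplyr::summarise(
      bad = dplyr::n_distinct(.data$sex) > 1 | dplyr::n_distinct(.data$age_years) > 1,
      .groups = "drop"
    )
  n_bad <- sum(conflicts$bad)
  if (n_bad > 0) {
    rlang::warn(paste0(
      n_bad, " episode(s) have member claims with conflicting sex or age; ",
      "the index claim's values were used"
    ), class = "ami_attribute_conflict")
  }
  invisible(NULL)
}

empty_episodes <- function() {
  tibble::tibble(
    episode_id = character(), patient_id = character(), n_claims = integer(),
    member_claim_ids = list(), index_admission_date = as.Date(character()),
    final_discharge_date = as.Date(character()), year = integer(),
    sex = character(), age_years = integer(), ed_admission = logical(),
    has_invasive = logical()
  )
}

#' Attribute episode-level characteristics from member claims
#'
#' Builds one episode row from the member claims of a single episode
#' (same patient, sorted by admission date). Year, sex and age come from
#' the index claim; `ed_admission` follows the chosen policy;
#' `has_invasive` is true when any member claim carries a configured
#' procedure code.
#'
#' @param member_claims Non-empty claims tibble: the member claims of one
#'   episode, same patient, sorted by admission date.
#' @inheritParams build_episodes
#' @return A one-row episodes tibble (without `episode_id`, which is
#'   assigned by the builder).
#' @export
attribute_episode <- function(member_claims, case_def = case_definition(),
                              ed_policy = c("index", "any")) {
  ed_policy <- match.arg(ed_policy)
  if (nrow(member_claims) == 0) {
    rlang::abort("an episode must have at least one member claim",
                 class = "ami_contract_error")
  }
  if (length(unique(member_claims$patient_id)) != 1) {
    rlang::abort("member claims of one episode must share patient_id",
                 class = "ami_contract_error")
  }
  flags <- classify_procedures(member_claims, case_def)
  tibble::tibble(
    patient_id = member_claims$patient_id[1],
    n_claims = nrow(member_claims),
    member_claim_ids = list(member_claims$claim_id),
    index_admission_date = member_claims$admission_date[1],
    final_discharge_date = max(member_claims$discharge_date),
    year = as.integer(format(member_claims$admission_date[1], "%Y")),
    sex = member_claims$sex[1],
    age_years = member_claims$age_years[1],
    ed_admission = if (ed_policy == "index") {
      member_claims$admission_route[1] == "emergency"
    } else {
      any(member_claims$admission_route == "emergency")
    },
    has_invasive = any(flags$has_invasive)
  )
}

#' Reference episode builder via connected components
#'
#' Independent construction of the same partition as [build_episodes()]
#' under the rolling anchor: per patient, sorted claims become vertices of
#' a graph with an edge between each consecutive pair for which
#' [merge_condition()] fires; connected components (via \pkg{igraph}) are
#' the episodes. Intended as a verification oracle for testing the
#' sequential scan, not for production use.
#'
#' @inheritParams build_episodes
#' @return An episodes tibble with the same columns as [build_episodes()].
#' @export
oracle_build_episodes <- function(claims, rule = merge_rule(),
                                  case_def = case_definition(),
                                  ed_policy = c("index", "any")) {
  ed_policy <- match.arg(ed_policy)
  if (rule$anchor != "rolling") {
    rlang::abort("the component oracle is defined for the rolling anchor only",
                 class = "ami_contract_error")
  }
  claims <- as_claims(claims)
  if (nrow(claims) == 0) return(empty_episodes())
  cl <- sort_claims(claims)

  pieces <- lapply(split(cl, cl$patient_id), function(pcl) {
    n <- nrow(pcl)
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    if (n > 1) {
      dec <- merge_condition(pcl[-n, ], pcl[-1, ], rule)
      idx <- which(dec$merge)
      if (length(idx) > 0) {
        g <- igraph::add_edges(g, rbind(idx, idx + 1))
      }
    }
    membership <- igraph::components(g)$membership
    eps <- lapply(sort(unique(membership)), function(m) {
      attribute_episode(pcl[membership == m, ], case_def, ed_policy)
    })
    dplyr::bind_rows(eps)
  })

  ep <- dplyr::bind_rows(pieces)
  ep <- ep[order(ep$patient_id, ep$index_admission_date), ]
  ep |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(episode_id = paste0(.data$patient_id, "-E",
                                      sprintf("%02d", dplyr::row_number()))) |>
    dplyr::ungroup() |>
    dplyr::relocate("episode_id")
}

#' Read and write episode tables
#'
#' Episodes serialize to CSV with `member_claim_ids` semicolon-joined and
#' ISO-8601 dates; `read_episodes()` inverts `write_episodes()`.
#'
#' @param episodes An episodes tibble from [build_episodes()].
#' @param path File path.
#' @return `write_episodes()` returns `path` invisibly; `read_episodes()`
#'   returns an episodes tibble.
#' @export
write_episodes <- function(episodes, path) {
  flat <- episodes
  flat$member_claim_ids <- collapse_code_list(episodes$member_claim_ids)
  readr::write_csv(flat, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_episodes
#' @export
read_episodes <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      episode_id = readr::col_character(),
      patient_id = readr::col_character(),
      n_claims = readr::col_integer(),
      member_claim_ids = readr::col_character(),
      index_admission_date = readr::col_date(),
      final_discharge_date = readr::col_date(),
      year = readr::col_integer(),
      sex = readr::col_character(),
      age_years = readr::col_integer(),
      ed_admission = readr::col_logical(),
      has_invasive = readr::col_logical()
    ),
    progress = FALSE
  )
  raw$member_claim_ids <- as_code_list(raw$member_claim_ids)
  raw
}
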