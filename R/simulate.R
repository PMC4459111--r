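# Default stratum probabilities, taken from published national margins for
# AMI admission episodes (Korea, 2007-2011): age-band episode counts, sex
# split 56.3% male, ED-route and invasive-procedure proportions by sex, and
# ~2.4% of admissions with no recorded route.
AGE_BANDS <- c("0-9", "10-19", "20-29", "30-39", "40-49",
               "50-59", "60-69", "70-79", "≥80")
DEFAULT_AGE_WEIGHTS <- c(341, 2053, 4710, 11503, 31631,
                         50333, 64707, 80912, 48791)

#' Configuration for the synthetic claims generator
#'
#' Bundles and validates all parameters of [simulate_claims()]. The
#' defaults emulate the structure of a national health-insurance claims
#' extract for AMI admissions: a five-year study window, roughly one
#' admission episode per patient (categorical over 1--3), sex and age-band
#' margins and per-sex emergency-route and invasive-procedure
#' probabilities matching published national tabulations, and a 2.4%
#' rate of unrecorded admission route.
#'
#' `fragmentation_mix` gives the probability that a planted episode is
#' billed as a single claim (`none`) or fragmented by one of the three
#' mechanisms that produce multiple claims per episode: `monthly_split`
#' (long stays billed once per calendar month, claims abutting at month
#' boundaries), `transfer` (two claims from distinct providers, the second
#' admitted on the first's discharge day), and `early_readmission` (a
#' second claim admitted within the 28-day admission window).
#'
#' With `guarantee_separation = TRUE` (default), distinct planted episodes
#' of one patient are kept far enough apart that no merge condition fires
#' across an episode boundary -- admissions more than
#' `admission_window_days` apart, more than `discharge_window_days` after
#' the prior discharge, and index stays at least `short_stay_days` long --
#' so [build_episodes()] provably recovers the planted partition exactly.
#' Setting it to `FALSE` drops those constraints: close-together episodes
#' may then be merged (undercount), which is the intended tool for
#' quantifying the merge rule's bias.
#'
#' @param n_patients Number of patients to simulate.
#' @param seed Integer seed; the full output is reproducible from it.
#' @param study_start,study_end Date bounds of the study window.
#' @param episodes_per_patient Named numeric vector of probabilities; names
#'   are episode counts (e.g. `c("1" = .92, "2" = .07, "3" = .01)`).
#' @param los_sampler Function `n -> integer vector` drawing lengths of
#'   stay (days, non-negative). Default: negative binomial, mean 7.
#' @param fragmentation_mix Named probabilities over
#'   `none`, `monthly_split`, `transfer`, `early_readmission`; must sum to 1.
#' @param p_male Probability a patient is male.
#' @param age_weights Sampling weights over the nine ten-year age bands
#'   `0-9` ... `>=80`.
#' @param p_ed_route Named per-sex probability that an episode's index
#'   claim is an emergency-department admission.
#' @param p_invasive Named per-sex probability that an episode involves an
#'   invasive coronary procedure.
#' @param p_route_missing Probability that a claim's admission route is
#'   unrecorded (default 0.024).
#' @param guarantee_separation Logical; see Details.
#' @param rule The [merge_rule()] whose windows the generator respects
#'   when `guarantee_separation` is on (and whose windows the fragments
#'   are built to satisfy).
#' @return An object of class `ami_generator_config`.
#' @examples
#' generator_config(n_patients = 100, seed = 42)
#' @export
generator_config <- function(n_patients,
                             seed = NULL,
                             study_start = as.Date("2007-01-01"),
                             study_end = as.Date("2011-12-31"),
                             episodes_per_patient = c("1" = 0.92, "2" = 0.07, "3" = 0.01),
                             los_sampler = function(n) stats::rnbinom(n, mu = 7, size = 2),
                             fragmentation_mix = c(none = 0.45, monthly_split = 0.20,
                                                   transfer = 0.15, early_readmission = 0.20),
                             p_male = 0.563,
                             age_weights = DEFAULT_AGE_WEIGHTS,
                             p_ed_route = c(male = 0.567, female = 0.492),
                             p_invasive = c(male = 0.351, female = 0.179),
                             p_route_missing = 0.024,
                             guarantee_separation = TRUE,
                             rule = merge_rule()) {
  stopifnot(
    is.numeric(n_patients), length(n_patients) == 1, n_patients >= 0,
    inherits(study_start, "Date"), inherits(study_end, "Date"),
    is.function(los_sampler),
    length(age_weights) == length(AGE_BANDS), all(age_weights >= 0),
    all(c("male", "female") %in% names(p_ed_route)),
    all(c("male", "female") %in% names(p_invasive)),
    inherits(rule, "ami_merge_rule")
  )
  check_probs <- function(p, what) {
    if (any(p < 0 | p > 1)) {
      rlang::abort(paste0(what, " must be probabilities in [0, 1]"),
                   class = "ami_config_error")
    }
  }
  check_probs(c(p_male, p_ed_route, p_invasive, p_route_missing), "probabilities")
  check_probs(episodes_per_patient, "episodes_per_patient")
  check_probs(fragmentation_mix, "fragmentation_mix")
  if (abs(sum(fragmentation_mix) - 1) > 1e-8) {
    rlang::abort("fragmentation_mix must sum to 1", class = "ami_config_error")
  }
  if (abs(sum(episodes_per_patient) - 1) > 1e-8) {
    rlang::abort("episodes_per_patient must sum to 1", class = "ami_config_error")
  }
  if (is.null(names(episodes_per_patient)) ||
      anyNA(suppressWarnings(as.integer(names(episodes_per_patient))))) {
    rlang::abort("episodes_per_patient must be named by integer episode counts",
                 class = "ami_config_error")
  }
  needed <- c("none", "monthly_split", "transfer", "early_readmission")
  if (!setequal(names(fragmentation_mix), needed)) {
    rlang::abort(paste0("fragmentation_mix must be named: ",
                        paste(needed, collapse = ", ")),
                 class = "ami_config_error")
  }
  if (study_end < study_start) {
    rlang::abort("study_end must not precede study_start", class = "ami_config_error")
  }
  # A patient needs room for all requested episodes plus separation gaps.
  max_eps <- max(as.integer(names(episodes_per_patient)))
  span_needed <- max_eps * (rule$admission_window_days + 130)
  if (guarantee_separation &&
      as.integer(study_end - study_start) < span_needed) {
    rlang::abort(
      paste0("study window too small for up to ", max_eps,
             " separated episodes per patient (need >= ", span_needed, " days)"),
      class = "ami_generation_error"
    )
  }
  structure(
    list(
      n_patients = as.integer(n_patients), seed = seed,
      study_start = study_start, study_end = study_end,
      episodes_per_patient = episodes_per_patient,
      los_sampler = los_sampler,
      fragmentation_mix = fragmentation_mix[needed],
      p_male = p_male, age_weights = age_weights,
      p_ed_route = p_ed_route, p_invasive = p_invasive,
      p_route_missing = p_route_missing,
      guarantee_separation = isTRUE(guarantee_separation),
      rule = rule
    ),
    class = "ami_generator_config"
  )
}

#' Generate synthetic claims with planted ground-truth episodes
#'
#' Simulates a claims table whose structure mimics a national insurer's
#' extract: each patient gets one or more planted AMI admission episodes,
#' and each episode is billed as one claim or fragmented into several by
#' monthly billing splits, inter-hospital transfers, or early
#' readmissions (see [generator_config()]). Ground truth -- which claim
#' belongs to which planted episode, and the planted emergency-route and
#' invasive-procedure flags -- is returned separately so the analysis
#' pipeline stays blind to it.
#'
#' The planted route is recorded on the index claim (later claims of an
#' episode are routed `other`), procedures are attached to a randomly
#' chosen member claim, and every claim's route is independently blanked
#' to `unknown` with probability `p_route_missing`. The ground-truth ED
#' flag is the *recorded* index route, so attribution is recoverable even
#' in the presence of missingness.
#'
#' @param config An [generator_config()].
#' @return A list with elements `claims` (validated claims tibble),
#'   `truth` (tibble: `claim_id`, `patient_id`, `true_episode_id`,
#'   `true_ed`, `true_invasive`), and `planted_episodes` (one row per
#'   planted episode: `patient_id`, `true_episode_id`,
#'   `index_admission_date`, `true_ed`, `true_invasive`, `n_claims`).
#' @examples
#' sim <- simulate_claims(generator_config(n_patients = 50, seed = 42))
#' eps <- build_episodes(sim$claims)
#' nrow(eps) == nrow(sim$planted_episodes)
#' @export
simulate_claims <- function(config) {
  stopifnot(inherits(config, "ami_generator_config"))
  run <- function() generate_all(config)
  if (!is.null(config$seed)) {
    withr::with_seed(config$seed, run())
  } else {
    run()
  }
}

generate_all <- function(config) {
  if (config$n_patients == 0) {
    return(list(
      claims = as_claims(empty_claims_flat()),
      truth = tibble::tibble(claim_id = character(), patient_id = character(),
                             true_episode_id = character(), true_ed = logical(),
                             true_invasive = logical()),
      planted_episodes = tibble::tibble(patient_id = character(),
                                        true_episode_id = character(),
                                        index_admission_date = as.Date(character()),
                                        true_ed = logical(), true_invasive = logical(),
                                        n_claims = integer())
    ))
  }
  pieces <- lapply(seq_len(config$n_patients), function(i) {
    generate_patient(sprintf("P%06d", i), config)
  })
  # patients emit plain field vectors (one chunk per episode); assemble the
  # tibbles once, which is far cheaper than row-binding thousands of pieces
  claim_chunks <- unlist(lapply(pieces, `[[`, "claims"), recursive = FALSE)
  truth_chunks <- unlist(lapply(pieces, `[[`, "truth"), recursive = FALSE)
  field <- function(chunks, nm) do.call(c, lapply(chunks, `[[`, nm))
  claims <- tibble::tibble(
    claim_id = field(claim_chunks, "claim_id"),
    patient_id = field(claim_chunks, "patient_id"),
    provider_id = field(claim_chunks, "provider_id"),
    sex = field(claim_chunks, "sex"),
    age_years = field(claim_chunks, "age_years"),
    admission_date = field(claim_chunks, "admission_date"),
    discharge_date = field(claim_chunks, "discharge_date"),
    admission_route = field(claim_chunks, "admission_route"),
    dx_primary = field(claim_chunks, "dx_primary"),
    dx_secondary = field(claim_chunks, "dx_secondary"),
    proc_codes = field(claim_chunks, "proc_codes")
  )
  truth <- tibble::tibble(
    claim_id = field(truth_chunks, "claim_id"),
    patient_id = field(truth_chunks, "patient_id"),
    true_episode_id = field(truth_chunks, "true_episode_id"),
    true_ed = field(truth_chunks, "true_ed"),
    true_invasive = field(truth_chunks, "true_invasive")
  )
  planted <- truth |>
    dplyr::group_by(.data$patient_id, .data$true_episode_id) |>
    dplyr::summarise(
      true_ed = dplyr::first(.data$true_ed),
      true_invasive = dplyr::first(.data$true_invasive),
      n_claims = dplyr::n(),
      .groups = "drop"
    )
  # index admission of each planted episode, from the emitted claims
  idx <- truth |>
    dplyr::select("claim_id", "true_episode_id") |>
    dplyr::inner_join(
      dplyr::select(claims, "claim_id", "admission_date"),
      by = "claim_id"
    ) |>
    dplyr::group_by(.data$true_episode_id) |>
    dplyr::summarise(index_admission_date = min(.data$admission_date),
                     .groups = "drop")
  planted <- dplyr::left_join(planted, idx, by = "true_episode_id") |>
    dplyr::select("patient_id", "true_episode_id", "index_admission_date",
                  "true_ed", "true_invasive", "n_claims") |>
    dplyr::arrange(.data$patient_id, .data$index_admission_date)
  list(claims = as_claims(claims), truth = truth, planted_episodes = planted)
}

empty_claims_flat <- function() {
  tibble::tibble(
    claim_id = character(), patient_id = character(), provider_id = character(),
    sex = character(), age_years = integer(),
    admission_date = as.Date(character()), discharge_date = as.Date(character()),
    admission_route = character(), dx_primary = character(),
    dx_secondary = character(), proc_codes = character()
  )
}

sample_one <- function(x, prob = NULL) {
  x[sample.int(length(x), 1, prob = prob)]
}

generate_patient <- function(patient_id, config) {
  rule <- config$rule
  sex <- if (stats::runif(1) < config$p_male) "male" else "female"
  band <- sample_one(seq_along(AGE_BANDS), prob = config$age_weights)
  age <- if (band == length(AGE_BANDS)) {
    80L + sample.int(16, 1) - 1L                    # >=80 band: 80..95
  } else {
    (band - 1L) * 10L + sample.int(10, 1) - 1L
  }
  n_episodes <- as.integer(sample_one(names(config$episodes_per_patient),
                                      prob = config$episodes_per_patient))

  claims <- list()
  truth <- list()
  prev_last_admission <- NULL
  prev_final_discharge <- NULL
  claim_counter <- 0L

  for (e in seq_len(n_episodes)) {
    if (e == 1) {
      offset <- sample.int(as.integer(config$study_end - config$study_start) + 1L, 1) - 1L
      admission <- config$study_start + offset
    } else if (config$guarantee_separation) {
      earliest <- max(prev_last_admission + rule$admission_window_days + 1L,
                      prev_final_discharge + rule$discharge_window_days + 1L)
      admission <- earliest + sample.int(61, 1) - 1L
    } else {
      # stress mode: readmission gaps short enough that merge conditions can
      # fire across planted episode boundaries
      admission <- prev_final_discharge + sample.int(45, 1)
    }
    if (admission > config$study_end) break  # no room left in the window

    los <- max(0L, as.integer(config$los_sampler(1)))
    if (e > 1 && config$guarantee_separation) {
      los <- max(los, rule$short_stay_days)  # index stay must not fire C3
    }

    mechanism <- sample_one(names(config$fragmentation_mix),
                            prob = config$fragmentation_mix)
    if (mechanism == "monthly_split") {
      los <- los + sample.int(51, 1) + 19L  # monthly billing targets long stays
    }
    # keep the whole episode inside the study window
    los <- min(los, as.integer(config$study_end - admission))
    if (e > 1 && config$guarantee_separation) los <- max(los, rule$short_stay_days)

    # For non-first episodes under the separation guarantee, the episode's
    # first *claim* must not be a short stay, or C3 would merge it backward
    # into the previous episode.
    min_first_los <- if (e > 1 && config$guarantee_separation) {
      rule$short_stay_days
    } else {
      0L
    }
    frag <- fragment_episode(admission, los, mechanism, rule, config$study_end,
                             min_first_los)

    ep_id <- paste0(patient_id, "-T", sprintf("%02d", e))
    n_frag <- length(frag$admission)

    p_ed <- unname(config$p_ed_route[[sex]])
    route <- character(n_frag)
    for (k in seq_len(n_frag)) {
      if (stats::runif(1) < config$p_route_missing) {
        route[k] <- "unknown"
      } else if (k == 1) {
        route[k] <- if (stats::runif(1) < p_ed) "emergency" else "other"
      } else {
        route[k] <- "other"
      }
    }
    true_ed <- route[1] == "emergency"

    p_inv <- unname(config$p_invasive[[sex]])
    true_invasive <- stats::runif(1) < p_inv
    proc <- rep("", n_frag)
    if (true_invasive) {
      carrier <- sample.int(n_frag, 1)
      codes <- "CAG01"
      if (stats::runif(1) < 0.6) {
        codes <- c(codes, if (stats::runif(1) < 0.9) "PCI01" else "CABG1")
      }
      proc[carrier] <- paste(codes, collapse = ";")
    }

    dx_secondary <- vapply(seq_len(n_frag), function(k) {
      extra <- character(0)
      if (stats::runif(1) < 0.3) extra <- c(extra, "E11.9")
      if (stats::runif(1) < 0.2) extra <- c(extra, "I10")
      if (stats::runif(1) < 0.1) extra <- c(extra, "I25.1")  # co-occurring chronic IHD
      paste(extra, collapse = ";")
    }, character(1))
    # occasionally AMI appears only as a secondary diagnosis
    dx_primary <- rep("I21.9", n_frag)
    for (k in seq_len(n_frag)) {
      if (stats::runif(1) < 0.15) {
        dx_primary[k] <- "I50.0"
        dx_secondary[k] <- paste(c("I21.9", dx_secondary[k][nzchar(dx_secondary[k])]),
                                 collapse = ";")
      } else {
        dx_primary[k] <- sample_one(c("I21.0", "I21.1", "I21.4", "I21.9"))
      }
    }

    ids <- sprintf("%s-C%03d", patient_id, claim_counter + seq_len(n_frag))
    claim_counter <- claim_counter + n_frag

    claims[[e]] <- list(
      claim_id = ids,
      patient_id = rep(patient_id, n_frag),
      provider_id = frag$provider,
      sex = rep(sex, n_frag),
      age_years = rep(age, n_frag),
      admission_date = frag$admission,
      discharge_date = frag$discharge,
      admission_route = route,
      dx_primary = dx_primary,
      dx_secondary = dx_secondary,
      proc_codes = proc
    )
    truth[[e]] <- list(
      claim_id = ids, patient_id = rep(patient_id, n_frag),
      true_episode_id = rep(ep_id, n_frag),
      true_ed = rep(true_ed, n_frag), true_invasive = rep(true_invasive, n_frag)
    )
    prev_last_admission <- max(frag$admission)
    prev_final_discharge <- max(frag$discharge)
  }

  list(claims = claims[lengths(claims) > 0], truth = truth[lengths(truth) > 0])
}

# Split one planted stay [admission, admission + los] into claims according
# to the fragmentation mechanism. Every consecutive pair of fragments
# satisfies at least one merge condition by construction: monthly splits
# and transfers abut (C2), early readmissions stay inside the admission
# window (C1) or readmit right after discharge (C2).
fragment_episode <- function(admission, los, mechanism, rule, study_end,
                             min_first_los = 0L) {
  discharge <- admission + los
  one <- list(admission = admission, discharge = discharge, provider = "H001")
  if (mechanism == "none" || los == 0) return(one)

  if (mechanism == "monthly_split") {
    cuts <- seq(as.Date(format(admission, "%Y-%m-01")), discharge + 31, by = "month")
    # a cut right after admission would make the first claim a short stay
    cuts <- cuts[cuts > admission + min_first_los & cuts <= discharge]
    if (length(cuts) == 0) return(one)
    starts <- c(admission, cuts)
    ends <- c(cuts - 1L, discharge)
    return(list(admission = starts, discharge = ends,
                provider = rep("H001", length(starts))))
  }

  if (mechanism == "transfer") {
    lo <- max(1L, min_first_los)
    if (lo > los) return(one)  # no room for a long-enough first claim
    t <- admission + lo + sample.int(los - lo + 1L, 1) - 1L
    return(list(
      admission = c(admission, t),
      discharge = c(t, discharge),
      provider = c("H001", "H002")
    ))
  }

  # early_readmission: the stay is billed, then the patient bounces back.
  d1 <- discharge
  a2 <- max(d1 + 1L, admission + sample.int(rule$admission_window_days, 1))
  if (as.integer(a2 - admission) > rule$admission_window_days) {
    a2 <- d1 + 1L  # long first stay: readmit right after discharge (C2)
  }
  los2 <- sample.int(6, 1) - 1L
  d2 <- a2 + los2
  if (d2 > study_end || a2 > study_end) return(one)
  list(
    admission = c(admission, a2),
    discharge = c(d1, d2),
    provider = c("H001", "H001")
  )
}

#' Compare built episodes with the planted ground truth
#'
#' Per patient, checks whether the partition of claims into episodes
#' produced by [build_episodes()] coincides exactly with the planted
#' partition in the generator's ground truth (every built episode is one
#' planted episode and vice versa).
#'
#' @param episodes Episodes tibble from [build_episodes()].
#' @param truth Ground-truth tibble from [simulate_claims()].
#' @return A tibble with one row per patient: `patient_id`, `n_planted`,
#'   `n_built`, `exact` (logical: partitions identical).
#' @examples
#' sim <- simulate_claims(generator_config(n_patients = 30, seed = 9))
#' rec <- evaluate_recovery(build_episodes(sim$claims), sim$truth)
#' all(rec$exact)
#' @export
evaluate_recovery <- function(episodes, truth) {
  built <- tibble::tibble(
    claim_id = unlist(episodes$member_claim_ids),
    built_episode_id = rep(episodes$episode_id, episodes$n_claims)
  )
  merged <- dplyr::inner_join(truth, built, by = "claim_id")
  if (nrow(merged) != nrow(truth)) {
    rlang::abort("episodes do not cover the ground-truth claims",
                 class = "ami_contract_error")
  }
  merged |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_planted = dplyr::n_distinct(.data$true_episode_id),
      n_built = dplyr::n_distinct(.data$built_episode_id),
      exact = dplyr::n_distinct(paste(.data$true_episode_id,
                                      .data$built_episode_id)) ==
        dplyr::n_distinct(.data$true_episode_id) &&
        dplyr::n_distinct(.data$true_episode_id) ==
        dplyr::n_distinct(.data$built_episode_id),
      .groups = "drop"
    )
}
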