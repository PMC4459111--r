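#' @importFrom rlang .data
NULL

# Canonical claims-table column order, shared by reader and writer.
CLAIMS_COLUMNS <- c(
  "claim_id", "patient_id", "provider_id", "sex", "age_years",
  "admission_date", "discharge_date", "admission_route",
  "dx_primary", "dx_secondary", "proc_codes"
)

SEX_LEVELS <- c("male", "female", "unknown")
ROUTE_LEVELS <- c("emergency", "other", "unknown")

#' Coerce a data frame to a validated claims table
#'
#' The in-memory claims representation is a tibble with one row per
#' hospitalization claim: `claim_id`, `patient_id`, `provider_id` (`NA` when
#' absent), `sex` (`male`/`female`/`unknown`), `age_years`, `admission_date`
#' and `discharge_date` (`Date`), `admission_route`
#' (`emergency`/`other`/`unknown`), `dx_primary` (ICD-10 code), and two
#' list-columns `dx_secondary` and `proc_codes` holding zero or more codes
#' per claim.
#'
#' `as_claims()` accepts the flat serialized form (dates as ISO-8601
#' strings, list fields as semicolon-joined strings, blanks for empty) and
#' the in-memory form interchangeably, then validates: required columns
#' present, unique `claim_id`, parseable dates, `discharge_date >=
#' admission_date`, non-negative integer age, and `sex`/`admission_route`
#' restricted to their enumerations (blank or missing route and sex map to
#' `"unknown"`).
#'
#' @param x A data frame with the claims columns.
#' @return A validated claims tibble.
#' @seealso [read_claims()], [write_claims()]
#' @examples
#' as_claims(data.frame(
#'   claim_id = "C1", patient_id = "P1", provider_id = "H1",
#'   sex = "male", age_years = 62,
#'   admission_date = "2007-03-01", discharge_date = "2007-03-08",
#'   admission_route = "emergency",
#'   dx_primary = "I21.0", dx_secondary = "E11.9;I10", proc_codes = "CAG01"
#' ))
#' @export
as_claims <- function(x) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(CLAIMS_COLUMNS, names(x))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("claims table is missing mandatory column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "ami_schema_error"
    )
  }
  x <- x[CLAIMS_COLUMNS]

  for (col in c("claim_id", "patient_id", "dx_primary")) {
    x[[col]] <- as.character(x[[col]])
  }
  x$provider_id <- as.character(x$provider_id)
  x$provider_id[!is.na(x$provider_id) & x$provider_id == ""] <- NA_character_

  x$sex <- map_enum(x$sex, SEX_LEVELS, "sex", x$claim_id)
  x$admission_route <- map_enum(x$admission_route, ROUTE_LEVELS,
                                "admission_route", x$claim_id)

  x$admission_date <- parse_claim_date(x$admission_date, "admission_date", x$claim_id)
  x$discharge_date <- parse_claim_date(x$discharge_date, "discharge_date", x$claim_id)

  age <- suppressWarnings(as.integer(x$age_years))
  bad_age <- is.na(age) | age < 0
  if (any(bad_age)) {
    rlang::abort(
      paste0("age_years must be a non-negative integer; offending claim_id: ",
             paste(x$claim_id[bad_age], collapse = ", ")),
      class = "ami_validation_error"
    )
  }
  x$age_years <- age

  x$dx_secondary <- as_code_list(x$dx_secondary)
  x$proc_codes <- as_code_list(x$proc_codes)

  dup <- duplicated(x$claim_id)
  if (any(dup)) {
    rlang::abort(
      paste0("duplicate claim_id value(s): ",
             paste(unique(x$claim_id[dup]), collapse = ", ")),
      class = "ami_validation_error"
    )
  }
  bad_order <- x$discharge_date < x$admission_date
  if (any(bad_order)) {
    rlang::abort(
      paste0("discharge_date before admission_date for claim_id: ",
             paste(x$claim_id[bad_order], collapse = ", ")),
      class = "ami_validation_error"
    )
  }
  x
}

map_enum <- function(values, levels, field, claim_id) {
  values <- as.character(values)
  values[is.na(values) | values == ""] <- "unknown"
  bad <- !(values %in% levels)
  if (any(bad)) {
    rlang::abort(
      paste0(field, " must be one of {", paste(levels, collapse = ", "),
             "}; offending claim_id: ",
             paste(claim_id[bad], collapse = ", ")),
      class = "ami_validation_error"
    )
  }
  values
}

parse_claim_date <- function(values, field, claim_id) {
  if (inherits(values, "Date")) {
    parsed <- values
  } else {
    parsed <- as.Date(as.character(values), format = "%Y-%m-%d")
  }
  bad <- is.na(parsed)
  if (any(bad)) {
    rlang::abort(
      paste0("unparseable ", field, " (expected YYYY-MM-DD) for claim_id: ",
             paste(claim_id[bad], collapse = ", ")),
      class = "ami_validation_error"
    )
  }
  parsed
}

# Semicolon-joined string <-> character-vector list-column.
as_code_list <- function(x) {
  if (is.list(x)) {
    return(lapply(x, function(v) as.character(v[!is.na(v) & nzchar(v)])))
  }
  x <- as.character(x)
  lapply(x, function(v) {
    if (is.na(v) || v == "") character(0) else strsplit(v, ";", fixed = TRUE)[[1]]
  })
}

collapse_code_list <- function(x) {
  vapply(x, paste, character(1), collapse = ";")
}

#' Read a claims table from CSV
#'
#' Reads a flat claims CSV (one row per hospitalization claim) and returns a
#' validated claims tibble. The expected columns, in order, are
#' `claim_id, patient_id, provider_id, sex, age_years, admission_date,
#' discharge_date, admission_route, dx_primary, dx_secondary, proc_codes`;
#' dates are ISO-8601 and the two list fields are semicolon-separated.
#' Blank or missing `admission_route`/`sex` map to `"unknown"`; a blank
#' `provider_id` becomes `NA`.
#'
#' @param path Path to a claims CSV file.
#' @return A validated claims tibble (see [as_claims()]).
#' @examples
#' path <- tempfile(fileext = ".csv")
#' sim <- simulate_claims(generator_config(n_patients = 5, seed = 1))
#' write_claims(sim$claims, path)
#' claims <- read_claims(path)
#' nrow(claims) == nrow(sim$claims)
#' @export
read_claims <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("claims file not found: ", path), class = "ami_io_error")
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(),
    progress = FALSE
  )
  if (nrow(raw) > 0) {
    raw[raw == ""] <- NA_character_  # uniform blank handling before coercion
  }
  as_claims(raw)
}

#' Write a claims table to CSV
#'
#' Serializes a validated claims tibble to the canonical CSV layout:
#' columns in the documented order, ISO-8601 dates, list fields joined with
#' semicolons (empty list -> empty cell), missing `provider_id` -> empty
#' cell, UTF-8. [read_claims()] inverts this exactly, so write-then-read is
#' the identity on validated claims.
#'
#' @param claims A validated claims tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_claims <- function(claims, path) {
  claims <- as_claims(claims)
  flat <- claims
  flat$dx_secondary <- collapse_code_list(claims$dx_secondary)
  flat$proc_codes <- collapse_code_list(claims$proc_codes)
  readr::write_csv(flat, path, na = "", progress = FALSE)
  invisible(path)
}

#' Classify claims against the AMI case definition
#'
#' `classify_ami_claims()` labels every claim with the predicate that
#' decides its fate, so the selection partitions the input with no silent
#' drops: `"selected"` (carries a qualifying I21-prefix code as primary or
#' secondary diagnosis), `"excluded_code_present"` (qualifying code present
#' but dropped because an excluded-prefix code co-occurs and
#' `strict_exclusion` is on), or `"no_qualifying_code"`.
#'
#' `select_ami_claims()` returns the selected claims in input order. It is
#' idempotent: re-applying it to its own output is a no-op.
#'
#' @param claims A validated claims tibble.
#' @param case_def An [case_definition()] object.
#' @return For `classify_ami_claims()`, a character vector (one status per
#'   claim); for `select_ami_claims()`, the qualifying subset of `claims`.
#' @examples
#' cfg <- generator_config(n_patients = 10, seed = 7)
#' claims <- simulate_claims(cfg)$claims
#' table(classify_ami_claims(claims))
#' @export
classify_ami_claims <- function(claims, case_def = case_definition()) {
  claims <- as_claims(claims)
  vapply(seq_len(nrow(claims)), function(i) {
    codes <- c(claims$dx_primary[i], claims$dx_secondary[[i]])
    if (!matches_prefix(codes, case_def$qualifying_dx_prefixes)) {
      "no_qualifying_code"
    } else if (case_def$strict_exclusion &&
               matches_prefix(codes, case_def$excluded_dx_prefixes)) {
      "excluded_code_present"
    } else {
      "selected"
    }
  }, character(1))
}

#' @rdname classify_ami_claims
#' @export
select_ami_claims <- function(claims, case_def = case_definition()) {
  claims <- as_claims(claims)
  claims[classify_ami_claims(claims, case_def) == "selected", ]
}

#' Flag invasive coronary procedures on claims
#'
#' For each claim, checks the procedure code list against the case
#' definition's angiography and revascularization code sets. A claim is
#' `has_invasive` when it carries either kind of code: coronary angiography
#' is diagnostic but counts as invasive alongside angioplasty and bypass
#' surgery.
#'
#' @inheritParams classify_ami_claims
#' @return A tibble with one row per claim and logical columns
#'   `has_angiography`, `has_revascularization`, `has_invasive`.
#' @export
classify_procedures <- function(claims, case_def = case_definition()) {
  claims <- as_claims(claims)
  has_angio <- vapply(claims$proc_codes, function(p) {
    any(p %in% case_def$angiography_codes)
  }, logical(1))
  has_revasc <- vapply(claims$proc_codes, function(p) {
    any(p %in% case_def$revascularization_codes)
  }, logical(1))
  tibble::tibble(
    has_angiography = has_angio,
    has_revascularization = has_revasc,
    has_invasive = has_angio | has_revasc
  )
}
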