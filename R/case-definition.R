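#' Case definition for AMI claims and invasive coronary procedures
#'
#' A case definition bundles the ICD-10 prefix sets that decide whether a
#' hospitalization claim qualifies as an acute myocardial infarction (AMI)
#' admission, together with the procedure code sets used to flag invasive
#' coronary procedures on a claim.
#'
#' A claim qualifies when its primary diagnosis or any secondary diagnosis
#' starts with a qualifying prefix (default `"I21"`, the ICD-10 block for
#' acute myocardial infarction). Codes starting with an excluded prefix
#' (default `I22`--`I25`: subsequent MI, complications after MI, other acute
#' and chronic ischaemic heart disease) never qualify a claim; they describe
#' sequelae or other ischaemic disease rather than a fresh AMI event. By
#' default a claim carrying both an I21 code and an excluded code is kept --
#' the qualifying code wins. Setting `strict_exclusion = TRUE` drops such
#' claims instead, for sensitivity analyses.
#'
#' Prefix matching ignores dots and case, so `"I210"` and `"i21.0"` both
#' match the prefix `"I21"`; both dialects occur in claims extracts.
#'
#' Procedure code values are configuration, not a fixed nomenclature:
#' national claims systems each use their own fee schedules. The defaults
#' are the documented synthetic codes emitted by [simulate_claims()]:
#' `CAG01` (coronary angiography, diagnostic), `PCI01` (percutaneous
#' transluminal coronary angioplasty) and `CABG1` (coronary artery bypass
#' surgery). Angiography counts as invasive alongside revascularization
#' because it is routinely performed to evaluate coronary occlusion and
#' frequently accompanies therapeutic procedures.
#'
#' @param qualifying_dx_prefixes Character vector of ICD-10 code prefixes
#'   that qualify a claim as an AMI admission.
#' @param excluded_dx_prefixes Character vector of prefixes that never
#'   qualify a claim (and, under `strict_exclusion`, disqualify it).
#' @param angiography_codes Character vector of diagnostic procedure codes
#'   (coronary angiography).
#' @param revascularization_codes Character vector of therapeutic procedure
#'   codes (angioplasty, bypass surgery).
#' @param strict_exclusion Logical; drop claims that carry any excluded-prefix
#'   code even when a qualifying code is present. Default `FALSE`.
#'
#' @return An object of class `ami_case_definition` (a named list).
#'
#' @examples
#' case_definition()
#' case_definition(strict_exclusion = TRUE)
#' @export
case_definition <- function(qualifying_dx_prefixes = "I21",
                            excluded_dx_prefixes = c("I22", "I23", "I24", "I25"),
                            angiography_codes = "CAG01",
                            revascularization_codes = c("PCI01", "CABG1"),
                            strict_exclusion = FALSE) {
  qual <- normalize_code(qualifying_dx_prefixes)
  excl <- normalize_code(excluded_dx_prefixes)
  if (length(intersect(qual, excl)) > 0) {
    rlang::abort("qualifying and excluded diagnosis prefixes must be disjoint",
                 class = "ami_config_error")
  }
  if (length(intersect(angiography_codes, revascularization_codes)) > 0) {
    rlang::abort("angiography and revascularization code sets must be disjoint",
                 class = "ami_config_error")
  }
  stopifnot(rlang::is_bool(strict_exclusion))
  structure(
    list(
      qualifying_dx_prefixes = qualifying_dx_prefixes,
      excluded_dx_prefixes = excluded_dx_prefixes,
      angiography_codes = angiography_codes,
      revascularization_codes = revascularization_codes,
      strict_exclusion = strict_exclusion
    ),
    class = "ami_case_definition"
  )
}

#' @export
print.ami_case_definition <- function(x, ...) {
  cat("<ami_case_definition>\n")
  cat("  qualifying dx prefixes:", paste(x$qualifying_dx_prefixes, collapse = ", "), "\n")
  cat("  excluded dx prefixes:  ", paste(x$excluded_dx_prefixes, collapse = ", "), "\n")
  cat("  angiography codes:     ", paste(x$angiography_codes, collapse = ", "), "\n")
  cat("  revascularization:     ", paste(x$revascularization_codes, collapse = ", "), "\n")
  cat("  strict exclusion:      ", x$strict_exclusion, "\n")
  invisible(x)
}

# Canonical form for code comparison: uppercase, dots stripped.
normalize_code <- function(x) {
  toupper(gsub(".", "", x, fixed = TRUE))
}

# Does any code in `codes` start with any prefix in `prefixes`? Both sides
# are normalized first. `codes` may contain NA/empty entries (ignored).
matches_prefix <- function(codes, prefixes) {
  codes <- normalize_code(codes[!is.na(codes) & nzchar(codes)])
  if (length(codes) == 0 || length(prefixes) == 0) return(FALSE)
  prefixes <- normalize_code(prefixes)
  any(vapply(
    prefixes,
    function(p) any(startsWith(codes, p)),
    logical(1)
  ))
}
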