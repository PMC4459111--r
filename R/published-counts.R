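#' Published reference counts for AMI admissions (Korean NHI, 2007-2011)
#'
#' Aggregate counts transcribed from a published national tabulation of
#' acute-myocardial-infarction admission episodes built from Korean
#' National Health Insurance claims, 2007--2011. The raw claims are not
#' public, so these printed counts are the replay inputs for validating
#' the tabulation arithmetic: feeding the numerators and denominators
#' through [wald_ci()] and [trend_series()] must reproduce the printed
#' percentages and confidence intervals.
#'
#' Three tables are shipped:
#' * `"headline"` -- key/value pairs: total claims (513,886), total
#'   patients (269,843), single-claim patients (180,597), multi-claim
#'   patients (89,246) and their claims (333,289), episodes identified
#'   among them (114,404), and total episodes (295,001).
#' * `"year_sex"` -- per year and sex group: total admissions,
#'   emergency-department admissions and invasive-procedure admissions
#'   with the printed percentages and 95% CIs.
#' * `"characteristics"` -- totals by sex and ten-year age band with the
#'   printed row percentages.
#'
#' @param which Which table to load.
#' @return A tibble.
#' @examples
#' published_ami_counts("headline")
#' @export
published_ami_counts <- function(which = c("headline", "year_sex", "characteristics")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0("ami_published_", which, ".csv"),
                      package = "amiepisodes", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  locale = readr::locale(encoding = "UTF-8"))
}
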