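# Round half away from zero on the given number of decimals -- the
# convention of printed epidemiological tables. base::round() rounds half
# to even, which disagrees on exact .x5 boundaries; the small epsilon
# absorbs binary representation error (e.g. 56.65 stored as 56.64999...).
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Ten-year age bands
#'
#' Maps age in years onto the ten-year bands used for stratified
#' reporting: `0-9`, `10-19`, ..., `70-79`, with `≥ 80` terminal.
#'
#' @param age_years Non-negative integer vector.
#' @return Factor with the nine band levels in order.
#' @examples
#' assign_age_band(c(0, 45, 85))
#' @export
assign_age_band <- function(age_years) {
  if (any(is.na(age_years)) || any(age_years < 0)) {
    rlang::abort("age_years must be non-negative", class = "ami_contract_error")
  }
  idx <- pmin(age_years %/% 10, 8) + 1
  factor(AGE_BANDS[idx], levels = AGE_BANDS)
}

#' Binomial proportion with confidence interval
#'
#' Computes the proportion `numerator / denominator` with a two-sided
#' confidence interval. The default is the Wald normal approximation,
#' `p +/- z * sqrt(p (1 - p) / n)` with `z` the standard-normal quantile at
#' `(1 + level) / 2`, bounds clipped to `[0, 1]` -- the method that
#' reproduces the intervals printed in national claims tabulations at this
#' sample size. `method = "wilson"` substitutes the Wilson score interval
#' (via [stats::prop.test()] without continuity correction), which behaves
#' better at small `n` or extreme proportions.
#'
#' Internal values (`estimate`, `lower`, `upper`) keep full precision;
#' the display columns (`percent`, `ci_low`, `ci_high`) are on the
#' percentage scale, rounded half-up to one decimal.
#'
#' @param numerator,denominator Non-negative integer vectors (recycled),
#'   `numerator <= denominator`, `denominator > 0`.
#' @param level Confidence level, default 0.95.
#' @param method `"wald"` (default) or `"wilson"`.
#' @return A tibble with columns `numerator`, `denominator`, `estimate`,
#'   `lower`, `upper`, `percent`, `ci_low`, `ci_high`, `conf_level`.
#' @examples
#' wald_ci(38118, 66883)  # 57.0 (56.6, 57.4)
#' @export
wald_ci <- function(numerator, denominator, level = 0.95,
                    method = c("wald", "wilson")) {
  method <- match.arg(method)
  n <- pmax(length(numerator), length(denominator))
  numerator <- rep_len(numerator, n)
  denominator <- rep_len(denominator, n)
  if (any(denominator <= 0)) {
    rlang::abort("denominator must be positive", class = "ami_contract_error")
  }
  if (any(numerator < 0 | numerator > denominator)) {
    rlang::abort("numerator must lie in [0, denominator]",
                 class = "ami_contract_error")
  }
  p <- numerator / denominator
  if (method == "wald") {
    z <- stats::qnorm((1 + level) / 2)
    half <- z * sqrt(p * (1 - p) / denominator)
    lower <- pmax(0, p - half)
    upper <- pmin(1, p + half)
  } else {
    ci <- vapply(seq_len(n), function(i) {
      stats::prop.test(numerator[i], denominator[i], conf.level = level,
                       correct = FALSE)$conf.int
    }, numeric(2))
    lower <- ci[1, ]
    upper <- ci[2, ]
  }
  tibble::tibble(
    numerator = as.integer(numerator),
    denominator = as.integer(denominator),
    estimate = p,
    lower = lower,
    upper = upper,
    percent = round_half_up(100 * p),
    ci_low = round_half_up(100 * lower),
    ci_high = round_half_up(100 * upper),
    conf_level = level
  )
}

#' Stratified episode counts with route and procedure proportions
#'
#' The analogue of a published claims tabulation: episode counts per
#' stratum, with the proportion admitted through the emergency department
#' and the proportion involving an invasive coronary procedure, each with
#' its confidence interval. Episodes with unknown admission route stay in
#' the denominator and count as non-ED in the numerator, matching the
#' convention of keeping unrecorded routes in the totals.
#'
#' One row is produced per observed stratum combination, plus a `Total`
#' row over all episodes. Stratum columns are returned as character so the
#' `Total` label can sit alongside year numbers.
#'
#' @param episodes Episodes tibble from [build_episodes()].
#' @param by Character vector of stratum dimensions, a subset of
#'   `c("year", "sex", "age_band")` (the age band is derived from
#'   `age_years` via [assign_age_band()]). May be empty for totals only.
#' @param level Confidence level for the intervals.
#' @param method CI method, see [wald_ci()].
#' @return A tibble with the `by` columns, then `n_episodes`, `n_ed`,
#'   `ed_percent`, `ed_ci_low`, `ed_ci_high`, `n_invasive`,
#'   `invasive_percent`, `invasive_ci_low`, `invasive_ci_high`. With no
#'   episodes, a single `Total` row with `n_episodes = 0` and `NA`
#'   proportions.
#' @examples
#' sim <- simulate_claims(generator_config(n_patients = 200, seed = 11))
#' eps <- build_episodes(sim$claims)
#' tabulate_by(eps, by = c("year", "sex"))
#' @export
tabulate_by <- function(episodes, by = "year", level = 0.95,
                        method = c("wald", "wilson")) {
  method <- match.arg(method)
  allowed <- c("year", "sex", "age_band")
  if (!all(by %in% allowed)) {
    rlang::abort(paste0("`by` must be a subset of: ",
                        paste(allowed, collapse = ", ")),
                 class = "ami_config_error")
  }
  df <- tibble::as_tibble(episodes)
  if ("age_band" %in% by) {
    df$age_band <- as.character(assign_age_band(df$age_years))
  }
  if ("year" %in% by) df$year <- as.character(df$year)

  if (nrow(df) == 0) {
    counts <- tibble::tibble(n_episodes = 0L, n_ed = 0L, n_invasive = 0L)
    for (b in by) counts[[b]] <- "Total"
    return(finish_table(counts, by, level, method))
  }

  strata <- if (length(by) > 0) {
    df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::summarise(
        n_episodes = dplyr::n(),
        n_ed = sum(.data$ed_admission),
        n_invasive = sum(.data$has_invasive),
        .groups = "drop"
      ) |>
      dplyr::arrange(dplyr::across(dplyr::all_of(by)))
  } else {
    NULL
  }
  total <- tibble::tibble(
    n_episodes = nrow(df),
    n_ed = sum(df$ed_admission),
    n_invasive = sum(df$has_invasive)
  )
  for (b in by) total[[b]] <- "Total"
  finish_table(dplyr::bind_rows(strata, total), by, level, method)
}

finish_table <- function(counts, by, level, method) {
  ok <- counts$n_episodes > 0
  ed <- inv <- tibble::tibble(percent = rep(NA_real_, nrow(counts)),
                              ci_low = NA_real_, ci_high = NA_real_)
  if (any(ok)) {
    ed[ok, ] <- wald_ci(counts$n_ed[ok], counts$n_episodes[ok], level, method)[
      c("percent", "ci_low", "ci_high")]
    inv[ok, ] <- wald_ci(counts$n_invasive[ok], counts$n_episodes[ok], level, method)[
      c("percent", "ci_low", "ci_high")]
  }
  out <- counts
  out$ed_percent <- ed$percent
  out$ed_ci_low <- ed$ci_low
  out$ed_ci_high <- ed$ci_high
  out$invasive_percent <- inv$percent
  out$invasive_ci_low <- inv$ci_low
  out$invasive_ci_high <- inv$ci_high
  dplyr::relocate(out, dplyr::all_of(by), "n_episodes", "n_ed", "ed_percent",
                  "ed_ci_low", "ed_ci_high", "n_invasive", "invasive_percent",
                  "invasive_ci_low", "invasive_ci_high")
}

#' Per-year trend series of counts and proportions
#'
#' Extracts from a year-stratified table the ordered series used for
#' trend plotting: total admissions, emergency-department admissions and
#' invasive-procedure admissions per year, with their percentages.
#'
#' @param table A [tabulate_by()] result stratified by (at least) `year`.
#' @return A tibble ordered by year: `year`, `n_total`, `n_ed`,
#'   `n_invasive`, `pct_ed`, `pct_invasive`.
#' @export
trend_series <- function(table) {
  if (!"year" %in% names(table)) {
    rlang::abort("`table` must be stratified by year", class = "ami_config_error")
  }
  rows <- table[table$year != "Total", ]
  for (col in intersect(names(rows), c("sex", "age_band"))) {
    rows <- rows[rows[[col]] == "Total", ]
  }
  if (nrow(rows) == 0) {
    rlang::abort("no per-year rows found; pass a table stratified by year only",
                 class = "ami_config_error")
  }
  out <- tibble::tibble(
    year = as.integer(rows$year),
    n_total = rows$n_episodes,
    n_ed = rows$n_ed,
    n_invasive = rows$n_invasive,
    pct_ed = rows$ed_percent,
    pct_invasive = rows$invasive_percent
  )
  dplyr::arrange(out, .data$year)
}

#' Plot admission trends
#'
#' Two-panel trend figure: yearly counts of total, emergency-department
#' and invasive-procedure admissions, and the two proportions over time.
#'
#' @param series A [trend_series()] result.
#' @return A ggplot object.
#' @export
plot_trends <- function(series) {
  counts <- series |>
    tidyr::pivot_longer(c("n_total", "n_ed", "n_invasive"),
                        names_to = "measure", values_to = "value") |>
    dplyr::mutate(panel = "Admissions (n)")
  pcts <- series |>
    tidyr::pivot_longer(c("pct_ed", "pct_invasive"),
                        names_to = "measure", values_to = "value") |>
    dplyr::mutate(panel = "Proportion of admissions (%)")
  labels <- c(n_total = "Total", n_ed = "Through ED", n_invasive = "With invasive procedure",
              pct_ed = "Through ED", pct_invasive = "With invasive procedure")
  dat <- dplyr::bind_rows(counts, pcts) |>
    dplyr::mutate(measure = labels[.data$measure])
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$year, y = .data$value,
                                    colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "Year", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
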