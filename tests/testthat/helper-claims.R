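# Compact constructors for hand-built claims fixtures.

claim_row <- function(claim_id, admission, discharge,
                      patient_id = "P1", provider = "H001",
                      sex = "male", age = 60, route = "other",
                      dx = "I21.9", dx2 = "", proc = "") {
  tibble::tibble(
    claim_id = claim_id, patient_id = patient_id, provider_id = provider,
    sex = sex, age_years = age,
    admission_date = admission, discharge_date = discharge,  # parsed by as_claims()
    admission_route = route, dx_primary = dx, dx_secondary = dx2,
    proc_codes = proc
  )
}

claims_of <- function(...) {
  as_claims(dplyr::bind_rows(...))
}

# Random per-patient claim sets on a day grid, for oracle-equivalence and
# monotonicity properties. Dates are offsets from a fixed origin.
random_claims <- function(n_patients, max_claims = 6, span_days = 120,
                          max_los = 40, origin = as.Date("2008-01-01")) {
  rows <- lapply(seq_len(n_patients), function(i) {
    k <- sample.int(max_claims, 1)
    adm <- origin + sort(sample.int(span_days, k, replace = TRUE))
    los <- sample.int(max_los + 1, k, replace = TRUE) - 1L
    claim_row(
      claim_id = sprintf("R%04d-C%02d", i, seq_len(k)),
      patient_id = sprintf("R%04d", i),
      admission = adm, discharge = adm + los
    )
  })
  as_claims(dplyr::bind_rows(rows))
}

# Episode partition in canonical form (sorted member sets, ordered by first
# member), for comparing two builders independent of episode labels.
partition_of <- function(episodes) {
  groups <- lapply(episodes$member_claim_ids, sort)
  unname(groups[order(vapply(groups, `[`, character(1), 1))])
}
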