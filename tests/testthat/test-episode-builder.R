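test_that("length of stay is the calendar-day difference", {
  claims <- claims_of(
    claim_row("A", "2007-01-01", "2007-01-01"),
    claim_row("B", "2007-01-01", "2007-01-04"),
    claim_row("C", "2008-02-28", "2008-03-01")  # across a leap day
  )
  expect_identical(compute_los(claims), c(0L, 3L, 2L))
  expect_identical(compute_los(claims, merge_rule(los_counts_both_ends = TRUE)),
                   c(1L, 4L, 3L))
})

test_that("the three merge conditions fire exactly as specified", {
  pair <- function(a1, d1, a2, d2) {
    list(claims_of(claim_row("F", a1, d1)), claims_of(claim_row("S", a2, d2)))
  }
  cases <- list(
    # admission gap 24 <= 28: C1 only
    list(pair("2007-03-01", "2007-03-10", "2007-03-25", "2007-04-02"),
         c(c1 = TRUE, c2 = FALSE, c3 = FALSE)),
    # admission gap 31 > 28 but discharge gap 2 <= 3: C2
    list(pair("2007-03-01", "2007-03-30", "2007-04-01", "2007-04-20"),
         c(c1 = FALSE, c2 = TRUE, c3 = FALSE)),
    # both gaps huge, but the second stay lasts 1 day < 3: C3 (literal)
    list(pair("2007-01-01", "2007-01-05", "2007-06-01", "2007-06-02"),
         c(c1 = FALSE, c2 = FALSE, c3 = TRUE)),
    # nothing fires
    list(pair("2007-03-01", "2007-03-05", "2007-04-15", "2007-04-25"),
         c(c1 = FALSE, c2 = FALSE, c3 = FALSE))
  )
  for (case in cases) {
    dec <- merge_condition(case[[1]][[1]], case[[1]][[2]])
    expect_equal(c(c1 = dec$c1, c2 = dec$c2, c3 = dec$c3), case[[2]])
    expect_equal(dec$merge, any(case[[2]]))
  }
})

test_that("window comparisons are inclusive and C2 allows overlap", {
  first <- claims_of(claim_row("F", "2007-01-01", "2007-01-10"))
  # admission gap exactly 28 days
  at28 <- claims_of(claim_row("S", "2007-01-29", "2007-02-10"))
  expect_true(merge_condition(first, at28)$c1)
  at29 <- claims_of(claim_row("S", "2007-01-30", "2007-02-10"))
  expect_false(merge_condition(first, at29)$c1)
  # discharge gap exactly 3 days
  d3 <- claims_of(claim_row("S", "2007-01-13", "2007-02-20"))
  expect_true(merge_condition(first, d3)$c2)
  d4 <- claims_of(claim_row("S", "2007-01-14", "2007-02-20"))
  expect_false(merge_condition(first, d4)$c2)
  # overlapping stay from a second hospital: negative discharge gap
  overlap <- claims_of(claim_row("S", "2007-01-08", "2007-02-20"))
  expect_true(merge_condition(first, overlap)$c2)
})

test_that("merge_condition enforces its contract", {
  a <- claims_of(claim_row("A", "2007-01-01", "2007-01-05"))
  b <- claims_of(claim_row("B", "2007-01-03", "2007-01-08", patient_id = "P2"))
  expect_error(merge_condition(a, b), class = "ami_contract_error")
  c1 <- claims_of(claim_row("C", "2006-12-01", "2007-01-08"))
  expect_error(merge_condition(a, c1), class = "ami_contract_error")
})

test_that("the sequential scan groups claims as in the worked chain example", {
  claims <- claims_of(
    claim_row("C1", "2007-01-01", "2007-01-31"),
    claim_row("C2", "2007-02-01", "2007-02-20"),   # C2: 1 day after discharge
    claim_row("C3", "2007-03-25", "2007-03-28")    # 52/33-day gaps, LOS 3: new
  )
  eps <- build_episodes(claims)
  expect_equal(nrow(eps), 2)
  expect_equal(eps$n_claims, c(2L, 1L))
  expect_equal(eps$member_claim_ids[[1]], c("C1", "C2"))
  expect_equal(eps$index_admission_date, as.Date(c("2007-01-01", "2007-03-25")))
  expect_equal(eps$final_discharge_date, as.Date(c("2007-02-20", "2007-03-28")))
})

test_that("pairwise non-mergeable claims become one episode each", {
  claims <- claims_of(
    claim_row(sprintf("C%d", 1:4),
              admission = as.Date("2007-01-01") + c(0, 60, 120, 180),
              discharge = as.Date("2007-01-01") + c(10, 70, 130, 190))
  )
  expect_equal(nrow(build_episodes(claims)), 4)
})

test_that("claims are never merged across patients", {
  claims <- claims_of(
    claim_row("C1", "2007-01-01", "2007-01-10", patient_id = "P1"),
    claim_row("C2", "2007-01-01", "2007-01-10", patient_id = "P2")
  )
  eps <- build_episodes(claims)
  expect_equal(nrow(eps), 2)
  expect_setequal(eps$patient_id, c("P1", "P2"))
})

test_that("episode construction conserves claims and ignores row order", {
  withr::local_seed(101)
  claims <- random_claims(150)
  eps <- build_episodes(claims)
  expect_equal(sum(eps$n_claims), nrow(claims))
  expect_setequal(unlist(eps$member_claim_ids), claims$claim_id)
  expect_true(all(eps$n_claims >= 1))
  expect_true(all(eps$index_admission_date <= eps$final_discharge_date))

  shuffled <- claims[sample(nrow(claims)), ]
  expect_equal(build_episodes(shuffled), eps)
})

test_that("episode counts stay within 1..claims per patient", {
  withr::local_seed(77)
  claims <- random_claims(80)
  eps <- build_episodes(claims)
  per_patient <- table(claims$patient_id)
  per_ep <- table(eps$patient_id)
  expect_true(all(per_ep >= 1))
  expect_true(all(per_ep <= per_patient[names(per_ep)]))
})

test_that("index anchoring stops C1 chains that rolling anchoring allows", {
  claims <- claims_of(
    claim_row("C1", "2007-01-01", "2007-01-06"),
    claim_row("C2", "2007-01-26", "2007-02-05"),
    claim_row("C3", "2007-02-20", "2007-03-02")
  )
  rolling <- build_episodes(claims, merge_rule(anchor = "rolling"))
  expect_equal(nrow(rolling), 1)
  indexed <- build_episodes(claims, merge_rule(anchor = "index"))
  expect_equal(nrow(indexed), 2)
  expect_equal(indexed$n_claims, c(2L, 1L))
})

test_that("episode attribution follows the index claim and the ED policy", {
  claims <- claims_of(
    claim_row("C1", "2007-12-20", "2007-12-31", route = "other",
              sex = "female", age = 72),
    claim_row("C2", "2008-01-01", "2008-01-05", route = "emergency",
              sex = "female", age = 72, proc = "PCI01")
  )
  idx <- build_episodes(claims)
  expect_equal(nrow(idx), 1)
  expect_false(idx$ed_admission)          # index claim's route wins
  expect_true(idx$has_invasive)           # any member claim counts
  expect_equal(idx$year, 2007L)           # year of the index admission
  expect_equal(idx$sex, "female")
  expect_equal(idx$age_years, 72L)

  any_pol <- build_episodes(claims, ed_policy = "any")
  expect_true(any_pol$ed_admission)

  one <- attribute_episode(claims)  # already sorted by admission
  expect_false(one$ed_admission)
  expect_true(one$has_invasive)
  expect_error(attribute_episode(claims[0, ]), class = "ami_contract_error")
})

test_that("single-claim attribution covers the trivial case", {
  claims <- claims_of(claim_row("C1", "2007-05-01", "2007-05-06",
                                route = "emergency"))
  ep <- attribute_episode(claims)
  expect_true(ep$ed_admission)
  expect_false(ep$has_invasive)
  expect_equal(ep$n_claims, 1L)
})

test_that("ties on admission date break by discharge then claim id", {
  claims <- claims_of(
    claim_row("B", "2007-01-01", "2007-03-01"),
    claim_row("A", "2007-01-01", "2007-01-02")
  )
  eps <- build_episodes(claims)
  expect_equal(eps$member_claim_ids[[1]], c("A", "B"))
})

test_that("component oracle and sequential scan agree on random inputs", {
  withr::local_seed(2024)
  claims <- random_claims(120)
  eps <- build_episodes(claims)
  orc <- oracle_build_episodes(claims)
  expect_equal(orc, eps)
})

test_that("widening any window never increases the episode count", {
  withr::local_seed(55)
  claims <- random_claims(100)
  n_eps <- function(rule) nrow(build_episodes(claims, rule))
  for (sweep in list(
    lapply(c(0, 7, 14, 28, 56), function(w) merge_rule(admission_window_days = w)),
    lapply(c(0, 1, 3, 10), function(w) merge_rule(discharge_window_days = w)),
    lapply(c(0, 3, 10, 30), function(w) merge_rule(short_stay_days = w))
  )) {
    counts <- vapply(sweep, n_eps, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("episode tables round-trip through CSV", {
  withr::local_seed(8)
  eps <- build_episodes(random_claims(30))
  path <- withr::local_tempfile(fileext = ".csv")
  write_episodes(eps, path)
  expect_equal(read_episodes(path), eps)
})
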