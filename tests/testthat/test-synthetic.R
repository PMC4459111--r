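test_that("the generator is fully reproducible from its seed", {
  cfg <- generator_config(n_patients = 40, seed = 123)
  a <- simulate_claims(cfg)
  b <- simulate_claims(cfg)
  expect_identical(a, b)

  other <- simulate_claims(generator_config(n_patients = 40, seed = 124))
  expect_false(identical(a$claims, other$claims))
})

test_that("zero patients yield empty, well-typed outputs", {
  sim <- simulate_claims(generator_config(n_patients = 0, seed = 1))
  expect_equal(nrow(sim$claims), 0)
  expect_equal(nrow(sim$truth), 0)
  expect_equal(nrow(sim$planted_episodes), 0)
  expect_equal(nrow(build_episodes(sim$claims)), 0)
})

test_that("every generated claim maps to exactly one planted episode", {
  sim <- simulate_claims(generator_config(n_patients = 100, seed = 5))
  expect_setequal(sim$truth$claim_id, sim$claims$claim_id)
  expect_false(any(duplicated(sim$truth$claim_id)))
  expect_equal(sum(sim$planted_episodes$n_claims), nrow(sim$claims))
})

test_that("under the separation guarantee the builder recovers the planted partition", {
  sim <- simulate_claims(generator_config(n_patients = 200, seed = 42))
  eps <- build_episodes(select_ami_claims(sim$claims))
  expect_equal(nrow(eps), nrow(sim$planted_episodes))
  rec <- evaluate_recovery(eps, sim$truth)
  expect_true(all(rec$exact))
})

test_that("planted route and procedure flags survive attribution", {
  sim <- simulate_claims(generator_config(n_patients = 150, seed = 33))
  eps <- build_episodes(select_ami_claims(sim$claims))
  built <- tibble::tibble(
    claim_id = unlist(eps$member_claim_ids),
    ed_admission = rep(eps$ed_admission, eps$n_claims),
    has_invasive = rep(eps$has_invasive, eps$n_claims)
  )
  joined <- dplyr::inner_join(sim$truth, built, by = "claim_id")
  expect_equal(joined$ed_admission, joined$true_ed)
  expect_equal(joined$has_invasive, joined$true_invasive)
})

test_that("route missingness matches its configured rate at large n", {
  sim <- simulate_claims(generator_config(n_patients = 3000, seed = 7))
  p_hat <- mean(sim$claims$admission_route == "unknown")
  se <- sqrt(0.024 * 0.976 / nrow(sim$claims))
  expect_lt(abs(p_hat - 0.024), 4 * se)
})

test_that("generated margins follow the configured distributions", {
  sim <- simulate_claims(generator_config(n_patients = 2000, seed = 19))
  patients <- sim$claims[!duplicated(sim$claims$patient_id), ]
  expect_lt(abs(mean(patients$sex == "male") - 0.563), 0.05)
  expect_true(all(patients$age_years >= 0 & patients$age_years <= 95))
  # episodes per patient concentrated on 1, as configured
  per_patient <- table(sim$planted_episodes$patient_id)
  expect_gt(mean(per_patient == 1), 0.85)
  expect_true(all(per_patient <= 3))
})

test_that("without the separation guarantee close episodes are undercounted", {
  cfg <- generator_config(n_patients = 150, seed = 11,
                          episodes_per_patient = c("1" = 0, "2" = 0.5, "3" = 0.5),
                          guarantee_separation = FALSE)
  sim <- simulate_claims(cfg)
  eps <- build_episodes(select_ami_claims(sim$claims))
  rec <- evaluate_recovery(eps, sim$truth)
  expect_lt(sum(rec$n_built), sum(rec$n_planted))   # merged across boundaries
  expect_gt(sum(!rec$exact), 0)
  expect_equal(sum(eps$n_claims), nrow(sim$claims)) # conservation still holds
})

test_that("a distant readmission fragment splits a planted episode", {
  # readmission 40 days after index, 20 days after discharge, LOS 5:
  # no condition fires, so the builder overcounts this planted episode
  claims <- claims_of(
    claim_row("C1", "2007-05-01", "2007-05-21"),
    claim_row("C2", "2007-06-10", "2007-06-15")
  )
  expect_equal(nrow(build_episodes(claims)), 2)
})

test_that("two planted episodes 10 days apart collapse into one", {
  claims <- claims_of(
    claim_row("C1", "2007-05-01", "2007-05-05"),
    claim_row("C2", "2007-05-11", "2007-05-20")
  )
  expect_equal(nrow(build_episodes(claims)), 1)
})

test_that("infeasible generator configurations are rejected", {
  expect_error(
    generator_config(n_patients = 10, seed = 1,
                     study_start = as.Date("2007-01-01"),
                     study_end = as.Date("2007-03-01")),
    class = "ami_generation_error"
  )
  expect_error(
    generator_config(n_patients = 10, seed = 1,
                     fragmentation_mix = c(none = 0.5, monthly_split = 0.5,
                                           transfer = 0.5, early_readmission = 0)),
    class = "ami_config_error"
  )
  expect_error(
    generator_config(n_patients = 10, p_route_missing = 1.5),
    class = "ami_config_error"
  )
})

test_that("fragmentation mechanisms produce the documented claim structure", {
  cfg <- generator_config(n_patients = 400, seed = 60)
  sim <- simulate_claims(cfg)
  cl <- sim$claims
  # transfers: overlapping claims from distinct providers exist
  expect_true(any(cl$provider_id == "H002"))
  multi <- sim$planted_episodes[sim$planted_episodes$n_claims > 1, ]
  expect_gt(nrow(multi), 0)
  # every within-episode consecutive pair satisfies a merge condition
  per_ep <- dplyr::inner_join(sim$truth, cl, by = c("claim_id", "patient_id"))
  for (ep in split(per_ep, per_ep$true_episode_id)) {
    if (nrow(ep) < 2) next
    ep <- ep[order(ep$admission_date, ep$discharge_date), ]
    dec <- merge_condition(as_claims(ep[-nrow(ep), names(cl)]),
                           as_claims(ep[-1, names(cl)]))
    expect_true(all(dec$merge))
  }
})
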