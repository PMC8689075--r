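test_that("sampled weights match the target distribution and bounds", {
  set.seed(11)
  d <- cohort_design(n_subjects = 1e4)
  subs <- sample_subjects(d)
  w <- vapply(subs, `[[`, 0, "weight")
  expect_true(all(w >= 5.5 & w <= 155.5))
  expect_equal(median(w), 23.9, tolerance = 0.1)
  expect_error(cohort_design(weight_min = 30, weight_median = 24), "median")
})

test_that("inhibitor co-treatment covers the intended fraction of
           observations as subject-level contiguous blocks", {
  set.seed(12)
  ds <- simulate_trial(sample_subjects(cohort_design(n_subjects = 600)),
                       pop_parameters(), cohort_design(n_subjects = 600))
  obs <- ds[ds$EVID == 0, ]
  expect_lt(abs(mean(obs$INH) - 0.117), 0.025)
  # contiguity: within a subject, days with INH = 1 form one block
  for (id in unique(obs$ID)[1:50]) {
    v <- obs$INH[obs$ID == id]
    expect_lte(sum(diff(v) != 0), 2)
  }
})

test_that("the generator is deterministic under a fixed seed", {
  d <- cohort_design(n_subjects = 8, n_days = 5, seed = 33)
  a <- simulate_cohort(d)
  b <- simulate_cohort(d)
  expect_identical(a, b)
})

test_that("with all variances at zero and titration off the simulated DV
           equals the noise-free model prediction", {
  pop0 <- pop_novar()
  d <- cohort_design(n_subjects = 4, n_days = 14, titrate = FALSE,
                     inhibitor_sample_fraction = 0, seed = 5)
  ds <- simulate_cohort(d, pop0)
  obs <- ds[ds$EVID == 0, ]
  for (id in unique(ds$ID)) {
    o <- obs[obs$ID == id, ]
    w <- o$WT[1]
    rate <- ds$RATE[ds$ID == id & ds$EVID == 1][1]
    sub <- subject_profile(id, w, data.frame(start = 0, duration = 24 * 14,
                                             rate = rate))
    expect_equal(o$DV, simulate_profile(sub, pop0, o$TIME),
                 tolerance = 1e-10)
  }
  # near steady state the day-14 trough approaches rate/CL
  id <- obs$ID[1]
  o <- obs[obs$ID == id, ]
  cl <- 4.2 * (o$WT[1] / 70)^0.75
  rate <- ds$RATE[ds$ID == id & ds$EVID == 1][1]
  expect_equal(o$DV[14], rate / cl, tolerance = 5e-3)
})

test_that("the default design produces the study-scale dataset", {
  ds <- simulate_cohort(cohort_design(seed = 99))
  expect_equal(length(unique(ds$ID)), 111)
  n_obs <- sum(ds$EVID == 0)
  expect_gte(n_obs, 1500)
  expect_lte(n_obs, 1650)
  expect_true(all(ds$TIME[ds$EVID == 0] %% 24 == 23.75))
})

test_that("latent effect draws have the designed dispersion", {
  set.seed(21)
  d <- cohort_design(n_subjects = 2000, n_days = 6)
  ds <- simulate_trial(sample_subjects(d), pop_parameters(), d)
  lat <- attr(ds, "latent")
  expect_lt(abs(sd(lat$effects$eta_cl) - 0.261), 0.015)
  expect_lt(abs(sd(lat$effects$eta_v1) - 0.30), 0.015)
  kap <- unlist(lat$kappa)
  expect_lt(abs(sd(kap) - 0.287), 0.01)
  # per-subject across-occasion spread of exp(kappa) ~ pi_cl
  per_sub <- vapply(lat$kappa, sd, 0)
  expect_equal(mean(per_sub), 0.287 * sqrt(1 - 1 / (2 * 6)), # E[s] bias
               tolerance = 0.02)
})

test_that("fixed weight-based starting doses are frequently
           supratherapeutic on day 1", {
  ds <- simulate_cohort(cohort_design(seed = 77))
  first <- ds[ds$EVID == 0 & ds$OCC == 1, "DV"]
  expect_gt(mean(first > 10), 0.25)
  expect_gt(median(first), 8)
  # titration decays the average per-kg rate from the fixed start toward a
  # plateau (the rule reacts to the typically supratherapeutic first days)
  rate_kg <- ds$RATE[ds$EVID == 1] / ds$WT[ds$EVID == 1]
  occ <- ds$OCC[ds$EVID == 1]
  expect_equal(mean(rate_kg[occ == 1]), 1.25)
  expect_lt(mean(rate_kg[occ >= 8]), 1.1)
  expect_gt(mean(rate_kg[occ >= 8]), 0.3)
})
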