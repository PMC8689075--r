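test_that("typical starting rates follow the steady-state relation
           rate = target x CL", {
  pop <- pop_parameters()
  rec <- initial_rate(pop, weight = 70, target_trough = 8.5)
  expect_equal(rec$rate, 35.7)
  expect_equal(rec$rate_per_kg, 0.51)
  expect_equal(rec$rate_per_kg_rounded, 0.51)
  expect_equal(rec$predicted_trough, 8.5)
  rec_inh <- initial_rate(pop, 70, inhibitor = 1, target_trough = 8.5)
  expect_equal(rec_inh$rate, 0.8 * rec$rate)
  expect_equal(initial_rate(pop, 70, target_trough = 0)$rate, 0)
  # linear in the target
  expect_equal(initial_rate(pop, 23.9, target_trough = 17)$rate,
               2 * initial_rate(pop, 23.9, target_trough = 8.5)$rate)
  expect_error(initial_rate(pop, -5), "positive")
})

test_that("MAP forecasting at steady state rescales the running rate by
           target/trough", {
  # noise-free subject with low clearance on a fixed rate, long history
  pop <- pop_parameters(sigma_prop = 0.02, pi_cl = 0)
  eta_cl <- 0.2
  ds <- mk_subject(rates = rep(50, 20), pop = pop, eta_cl = eta_cl)
  trough <- ds$DV[ds$EVID == 0][20]
  rec <- adaptive_rate(ds, pop, target_trough = 8.5, horizon = 500)
  expect_equal(rec$rate, 50 * 8.5 / trough, tolerance = 5e-3)
  expect_equal(rec$predicted_trough, 8.5, tolerance = 1e-9)
})

test_that("a low-clearance subject receives less than the typical
           recommendation", {
  pop <- pop_parameters(pi_cl = 0)
  ds <- mk_subject(rates = rep(40, 8), pop = pop, eta_cl = -0.5)
  rec <- adaptive_rate(ds, pop, target_trough = 8.5)
  typ <- initial_rate(pop, 70, target_trough = 8.5)
  expect_lt(rec$rate, typ$rate)
  expect_error(adaptive_rate(ds[ds$EVID == 1, ], pop), "trough")
  expect_error(adaptive_rate(ds, pop, horizon = -2), "> 0")
})

test_that("simulating forward at the recommended rate reproduces the
           target at the horizon", {
  pop <- pop_parameters()
  set.seed(91)
  d <- cohort_design(n_subjects = 4, n_days = 5, seed = 91)
  ds <- simulate_cohort(d, pop)
  for (id in unique(ds$ID)) {
    sub_rows <- ds[ds$ID == id, ]
    rec <- adaptive_rate(sub_rows, pop, target_trough = 8.5, horizon = 24)
    mp <- attr(rec, "map")
    w <- sub_rows$WT[1]
    n_days <- max(sub_rows$OCC)
    doses <- sub_rows[sub_rows$EVID == 1, ]
    t_anchor <- max(sub_rows$TIME)
    # independent forward path: closed-form profile over the recorded
    # regimen extended by the recommended rate, at the MAP effects
    reg <- data.frame(start = c(doses$TIME, t_anchor),
                      duration = c(doses$AMT / doses$RATE,
                                   24 + 0.26),
                      rate = c(doses$RATE, rec$rate))
    # truncate running bags at the anchor so the future rate replaces them
    reg$duration[seq_len(nrow(doses))] <-
      pmin(reg$duration[seq_len(nrow(doses))],
           pmax(t_anchor - doses$TIME, 1e-9))
    kap <- rep(0, n_days + 2)
    kap[as.integer(sub("occ", "", names(mp$kappa)))] <- mp$kappa
    prof <- subject_profile(id, w, reg,
                            inhibitor_schedule = data.frame(
                              time = sub_rows$TIME, inh = sub_rows$INH),
                            occasion_breaks = 24 * seq_len(n_days + 2))
    cc <- simulate_profile(prof, pop, t_anchor + 24,
                           eta_cl = mp$eta_cl, eta_v1 = mp$eta_v1,
                           kappa = kap)
    expect_equal(cc, 8.5, tolerance = 1e-3)
  }
})

test_that("adaptive recommendations are affine in the target", {
  pop <- pop_parameters(pi_cl = 0)
  ds <- mk_subject(rates = rep(45, 6), pop = pop, eta_cl = 0.1)
  r <- vapply(c(6, 8.5, 11), function(tt)
    adaptive_rate(ds, pop, target_trough = tt)$rate, numeric(1))
  expect_equal(r[1] + r[3], 2 * r[2], tolerance = 1e-8)
  expect_true(all(diff(r) > 0))
})
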