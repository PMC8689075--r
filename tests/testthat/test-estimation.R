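test_that("MAP returns the prior mode without observations and infers the
           direction of a single deviation", {
  pop <- pop_parameters()
  dose_only <- mk_subject(rates = rep(30, 3))[rep(c(TRUE, FALSE), 3), ]
  mp <- map_estimate(dose_only, pop)
  expect_equal(mp$eta_cl, 0)
  expect_equal(mp$eta_v1, 0)
  expect_length(mp$kappa, 0)
  # a trough above the typical prediction implies lower clearance
  typ <- mk_subject(rates = rep(30, 3), pop = pop_novar())
  high <- typ
  high$DV[high$EVID == 0] <- high$DV[high$EVID == 0] * 1.6
  mp2 <- map_estimate(high, pop)
  expect_lt(mp2$eta_cl, 0)
  expect_lt(mp2$grad_norm, 1e-6)
})

test_that("MAP recovers known effects from rich low-noise data", {
  # rich sampling identifies both clearance and volume; with a small
  # residual SD the posterior mode sits at the generating effects
  pop <- pop_parameters(sigma_prop = 0.01, pi_cl = 0)
  times <- c(2, 4, 8, 16, 26, 40, 60, 90, 130, 180, 240, 300, 330, 335.75)
  ds <- mk_subject(rates = rep(35, 14), pop = pop, eta_cl = 0.3,
                   eta_v1 = -0.2, obs_times = times)
  mp <- map_estimate(ds, pop)
  expect_lt(abs(mp$eta_cl - 0.3), 1e-3)
  expect_lt(abs(mp$eta_v1 + 0.2), 1e-3)
  expect_lt(mp$grad_norm, 1e-6)
})

test_that("with all random effects off the OFV is the extended
           least-squares objective of the typical-value model", {
  pop <- pop_novar(sigma_prop = 0.15)
  set.seed(8)
  ds <- mk_subject(rates = rep(40, 4))
  ds$DV[ds$EVID == 0] <- ds$DV[ds$EVID == 0] * (1 + rnorm(4, 0, 0.15))
  obs <- ds[ds$EVID == 0, ]
  sub <- subject_profile("S1", 70, data.frame(start = 0, duration = 96,
                                              rate = 40))
  f <- simulate_profile(sub, pop, obs$TIME)
  els <- sum((obs$DV - f)^2 / (0.15^2 * f^2) + log(2 * pi * 0.15^2 * f^2))
  expect_equal(as.numeric(marginal_ofv(ds, pop)), els, tolerance = 1e-8)
})

test_that("the Laplace OFV matches adaptive Gauss-Hermite quadrature on
           small two-effect instances", {
  skip_if_not_installed("deSolve")
  pop <- pop_parameters(pi_cl = 0)  # eta_cl, eta_v1 only
  set.seed(14)
  ds <- rbind(
    mk_subject("A", 70, rates = rep(40, 2), pop = pop_novar(),
               obs_times = c(23.75, 47.75)),
    mk_subject("B", 20, rates = rep(15, 2), pop = pop_novar(),
               obs_times = c(23.75, 47.75)))
  ds$DV[ds$EVID == 0] <- ds$DV[ds$EVID == 0] *
    exp(rnorm(4, 0, 0.25))  # displace the data off the typical curve
  ofv_q <- quad_ofv(ds, pop)
  ofv_l <- marginal_ofv(ds, pop, method = "laplace")
  expect_lt(abs(as.numeric(ofv_l) - ofv_q), 0.1)
  # the FOCE-I linearization is coarser on strongly displaced data but
  # stays within an OFV unit here
  ofv_f <- marginal_ofv(ds, pop, method = "foce")
  expect_lt(abs(as.numeric(ofv_f) - ofv_q), 1.0)
})

test_that("OFV is additive over subjects and invariant to subject order
           and occasion relabeling", {
  pop <- pop_parameters()
  set.seed(15)
  ds <- simulate_cohort(cohort_design(n_subjects = 4, n_days = 5, seed = 15))
  o1 <- as.numeric(marginal_ofv(ds, pop))
  dup <- ds
  dup$ID <- paste0(dup$ID, "dup")
  o2 <- as.numeric(marginal_ofv(rbind(ds, dup), pop))
  expect_equal(o2, 2 * o1, tolerance = 1e-10)
  ids <- unique(ds$ID)
  perm <- do.call(rbind, lapply(rev(ids), function(i) ds[ds$ID == i, ]))
  expect_equal(as.numeric(marginal_ofv(perm, pop)), o1, tolerance = 1e-10)
  relab <- ds
  relab$OCC <- relab$OCC * 3L + 1L  # order-preserving relabeling
  expect_equal(as.numeric(marginal_ofv(relab, pop)), o1, tolerance = 1e-10)
})

test_that("fixed-effect-only fitting recovers the generating parameters on
           noise-free data", {
  # a tiny residual SD keeps the extended-least-squares log-variance term
  # from shifting the optimum (its bias is O(sigma^2))
  d <- cohort_design(n_subjects = 8, n_days = 8, titrate = FALSE, seed = 44)
  ds <- simulate_cohort(d, pop_novar())  # exactly noise-free observations
  init <- pop_novar(theta_cl = 3, theta_v1 = 45, sigma_prop = 0.005)
  fit <- fit_population(ds, init = init, free = c("theta_cl", "theta_v1"))
  expect_equal(fit$estimates$theta_cl, 4.2, tolerance = 1e-3)
  expect_equal(fit$estimates$theta_v1, 61.9, tolerance = 1e-3)
})

test_that("standard errors are produced and scale sensibly", {
  set.seed(31)
  ds <- simulate_cohort(cohort_design(n_subjects = 12, n_days = 6,
                                      seed = 31))
  fit <- fit_population(ds, free = c("theta_cl", "sigma_prop"), se = TRUE)
  expect_s3_class(fit, "pk_fit")
  expect_true(all(is.finite(fit$se_table$se)))
  expect_true(all(fit$se_table$rse_pct > 0))
  expect_equal(fit$se_table$rse_pct,
               100 * fit$se_table$se / abs(fit$se_table$estimate))
})

test_that("a null inhibitor effect is not spuriously retained and its
           estimate stays near 1", {
  # data generated WITHOUT an inhibitor effect; refitting with the
  # inhibitor parameter free should find ~1 and no significant OFV gain
  pop1 <- pop_parameters(theta_inh = 1)
  ds <- simulate_cohort(cohort_design(n_subjects = 25, n_days = 6,
                                      seed = 52), pop1)
  free_base <- c("theta_cl", "omega_cl", "pi_cl", "sigma_prop")
  fit_fix <- fit_population(ds, init = pop1, free = free_base)
  fit_inh <- fit_population(ds, init = pop1,
                            free = c(free_base, "theta_inh"))
  expect_equal(fit_inh$estimates$theta_inh, 1, tolerance = 0.15)
  dofv <- fit_fix$ofv - fit_inh$ofv
  expect_gte(dofv, -1e-6)
  expect_lt(dofv, qchisq(0.99, 1))  # null inclusion rarely significant
})

test_that("covariate_step retains a genuine clearance covariate", {
  # data carry a true inhibitor effect (0.8); search it as a candidate
  # column starting from a model without the effect
  # short inhibitor blocks inside a longer record give within-subject
  # contrast, so the effect is not confounded with eta_cl
  ds <- simulate_cohort(cohort_design(n_subjects = 16, n_days = 10,
                                      inhibitor_sample_fraction = 0.3,
                                      inhibitor_block_days = 4,
                                      seed = 71), pop_parameters())
  init <- pop_parameters(theta_inh = 1)  # built-in effect switched off
  cs <- covariate_step(ds, init = init,
                       free = c("theta_cl", "sigma_prop"),
                       candidates = c(INH = "binary"))
  expect_true("INH" %in% cs$selected)
  expect_equal(unname(exp(cs$fit$beta_cov["INH"])), 0.8, tolerance = 0.15)
  expect_true(any(cs$steps$action == "included"))
  expect_true(any(cs$steps$phase == "backward" &
                    cs$steps$action == "retained"))
})

test_that("covariate_step with no candidates returns the base model", {
  ds <- simulate_cohort(cohort_design(n_subjects = 6, n_days = 4, seed = 9))
  cs <- covariate_step(ds, free = c("theta_cl", "sigma_prop"),
                       candidates = character())
  expect_length(cs$selected, 0)
  expect_s3_class(cs$fit, "pk_fit")
})
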