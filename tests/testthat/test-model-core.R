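test_that("covariate model reproduces the published typical values", {
  pop <- pop_parameters()
  ref <- individual_parameters(pop, weight = 70, inhibitor = 0)
  expect_equal(ref$cl, 4.2)
  expect_equal(ref$v1, 61.9)
  expect_equal(ref$q, 8.4)
  expect_equal(ref$v2, 123.8)
  expect_equal(individual_parameters(pop, 70, 1)$cl, 4.2 * 0.8)
  small <- individual_parameters(pop, 7, 0)
  expect_equal(small$cl, 4.2 * 0.1^0.75, tolerance = 1e-10)
  expect_equal(small$v1, 6.19)
})

test_that("clearance is monotone in weight and scales exactly with the
           inhibitor fraction and the random effects", {
  pop <- pop_parameters()
  w <- c(5.5, 10, 23.9, 70, 155.5)
  cls <- vapply(w, function(x) individual_parameters(pop, x, 0)$cl,
                numeric(1))
  expect_true(all(diff(cls) > 0))
  v1s <- vapply(w, function(x) individual_parameters(pop, x, 0)$v1,
                numeric(1))
  expect_equal(v1s, pop$theta_v1 * w / 70)
  for (wt in c(8, 40, 120)) {
    expect_equal(individual_parameters(pop, wt, 1)$cl,
                 pop$theta_inh * individual_parameters(pop, wt, 0)$cl)
    expect_equal(individual_parameters(pop, wt, 0, eta_cl = 0.3,
                                       kappa = -0.1)$cl,
                 exp(0.2) * individual_parameters(pop, wt, 0)$cl)
  }
  expect_error(individual_parameters(pop, -1, 0), "positive")
  expect_error(individual_parameters(pop, 70, 2), "0 or 1")
})

test_that("propagation is exact: trivial states and the steady-state limit
           independent of Fact", {
  pop <- pop_parameters()
  ip <- individual_parameters(pop, 70, 0)
  s0 <- pk_state()
  expect_equal(propagate_state(s0, ip, rate = 0, dt = 500)$a1, 0)
  expect_equal(propagate_state(s0, ip, rate = 0, dt = 500)$a2, 0)
  expect_error(propagate_state(s0, ip, rate = 10, dt = -1), ">= 0")
  # steady state: a1 -> R V1 / CL, a2 -> R V2 / CL; trough = R/CL
  # regardless of Fact (assert at Fact 1, 2, 4)
  for (fact in c(1, 2, 4)) {
    popf <- pop_parameters(fact = fact)
    ipf <- individual_parameters(popf, 70, 0)
    st <- propagate_state(pk_state(), ipf, rate = 42, dt = 5000)
    expect_equal(st$a1, 42 * ipf$v1 / ipf$cl, tolerance = 1e-9)
    expect_equal(st$a2, 42 * ipf$v2 / ipf$cl, tolerance = 1e-9)
    expect_equal(concentration(st, ipf), 42 / ipf$cl, tolerance = 1e-9)
  }
})

test_that("closed-form propagation matches adaptive ODE integration to
           relative tolerance 1e-6 over randomized parameters", {
  skip_if_not_installed("deSolve")
  set.seed(101)
  pop <- pop_parameters()
  for (rep in 1:10) {
    wt <- exp(runif(1, log(6), log(150)))
    eta <- rnorm(2, 0, 0.3)
    ip <- individual_parameters(pop, wt, rbinom(1, 1, 0.3), eta[1], eta[2])
    rate <- runif(1, 5, 150)
    dts <- runif(3, 0.5, 60)
    st <- pk_state()
    segs <- data.frame(start = 0, duration = sum(dts) + 1, rate = rate)
    for (i in seq_along(dts)) {
      st <- propagate_state(st, ip, rate, dts[i])
      oracle <- ode_conc(cumsum(dts)[i], segs, ip$cl, ip$v1, ip$q, ip$v2)
      expect_equal(concentration(st, ip), oracle, tolerance = 1e-6)
    }
  }
})

test_that("profiles superpose and are invariant to segment splitting", {
  pop <- pop_parameters()
  times <- c(1, 5, 23.75, 24, 36, 47.75, 60)
  one <- subject_profile("a", 25, data.frame(start = 0, duration = 72,
                                             rate = 30))
  two <- subject_profile("a", 25,
                         data.frame(start = c(0, 0), duration = c(72, 72),
                                    rate = c(15, 15)))
  split24 <- subject_profile("a", 25,
                             data.frame(start = c(0, 24, 48),
                                        duration = c(24, 24, 24),
                                        rate = c(30, 30, 30)))
  p1 <- simulate_profile(one, pop, times)
  expect_equal(simulate_profile(two, pop, times), p1, tolerance = 1e-12)
  expect_equal(simulate_profile(split24, pop, times), p1, tolerance = 1e-12)
  # half-day split of a single 24-h bag changes nothing either
  split12 <- subject_profile("a", 25,
                             data.frame(start = c(0, 12), duration = c(12, 60),
                                        rate = c(30, 30)))
  expect_equal(simulate_profile(split12, pop, times), p1, tolerance = 1e-12)
})

test_that("profile reaches rate/CL at steady state and is 0 before dosing", {
  pop <- pop_parameters()
  ip <- individual_parameters(pop, 70, 0)
  sub <- subject_profile("a", 70, data.frame(start = 48, duration = 2000,
                                             rate = 40))
  cc <- simulate_profile(sub, pop, c(0, 10, 47.9, 48 + 1500))
  expect_equal(cc[1:3], c(0, 0, 0))
  expect_equal(cc[4], 40 / ip$cl, tolerance = 1e-3)
  expect_error(simulate_profile(sub, pop, c(5, 3)), "non-decreasing")
})

test_that("a rate change mid-course matches the piecewise ODE oracle", {
  skip_if_not_installed("deSolve")
  pop <- pop_parameters()
  ip <- individual_parameters(pop, 23.9, 0)
  segs <- data.frame(start = c(0, 72), duration = c(72, 100),
                     rate = c(29.9, 59.8))
  sub <- subject_profile("a", 23.9, segs)
  times <- c(23.75, 71.75, 75, 95.75, 150)
  got <- simulate_profile(sub, pop, times)
  oracle <- ode_conc(times, segs, ip$cl, ip$v1, ip$q, ip$v2)
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("proportional residual error has the stated moments and floors
           at zero", {
  expect_equal(apply_residual_error(10, 0), 10)
  expect_equal(apply_residual_error(0, 0.5), 0)
  set.seed(7)
  dv <- apply_residual_error(rep(10, 1e5), 0.179)
  expect_true(all(dv >= 0))
  expect_equal(sd(dv / 10 - 1), 0.179, tolerance = 0.02)
  expect_equal(mean(dv / 10 - 1), 0, tolerance = 0.003)
  expect_error(apply_residual_error(-1, 0.1), ">= 0")
})
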