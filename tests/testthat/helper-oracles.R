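# Independent numerical oracles used to cross-check the closed-form
# kinetics (adaptive ODE integration via deSolve) and the Laplace/FOCE
# marginal objective (adaptive Gauss-Hermite quadrature).

# concentration profile by adaptive ODE integration over a piecewise
# regimen; `cl` may be a function of time (occasion/inhibitor effects)
ode_conc <- function(times, segments, cl, v1, q, v2, rtol = 1e-10) {
  cl_fun <- if (is.function(cl)) cl else function(t) cl
  rate_fun <- function(t) {
    sum(segments$rate[segments$start <= t &
                        segments$start + segments$duration > t])
  }
  deriv <- function(t, y, p) {
    clt <- cl_fun(t)
    list(c(rate_fun(t) - (clt / v1 + q / v1) * y[1] + (q / v2) * y[2],
           (q / v1) * y[1] - (q / v2) * y[2]))
  }
  knots <- sort(unique(c(0, segments$start,
                         segments$start + segments$duration, times)))
  knots <- knots[knots <= max(times)]
  y <- c(0, 0)
  conc <- setNames(numeric(length(knots)), NULL)
  for (k in seq_along(knots)[-1]) {
    # integrate inside the interval where the rate is constant
    mid_rate <- rate_fun((knots[k - 1] + knots[k]) / 2)
    seg_deriv <- function(t, y, p) {
      clt <- cl_fun(t)
      list(c(mid_rate - (clt / v1 + q / v1) * y[1] + (q / v2) * y[2],
             (q / v1) * y[1] - (q / v2) * y[2]))
    }
    out <- deSolve::ode(y, c(knots[k - 1], knots[k]), seg_deriv, NULL,
                        rtol = rtol, atol = 1e-12)
    y <- out[nrow(out), 2:3]
    conc[k] <- y[1] / v1
  }
  conc[match(times, knots)]
}

# Gauss-Hermite nodes/weights for E[f(Z)], Z ~ N(0,1) (Golub-Welsch on the
# probabilists' Hermite recurrence)
gh_rule <- function(n) {
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1))
  J[cbind(seq_len(n - 1), 2:n)] <- off
  J[cbind(2:n, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = e$vectors[1, ]^2)
}

# -2 log marginal likelihood of subjects with (eta_cl, eta_v1) effects only
# (pi_cl = 0), by tensor-product Gauss-Hermite over the prior, with the
# concentration model evaluated through the ODE oracle
quad_ofv <- function(dataset, pop, n_nodes = 31) {
  stopifnot(pop$pi_cl == 0)
  gh <- gh_rule(n_nodes)
  total <- 0
  for (sub in split(as.data.frame(dataset), dataset$ID)) {
    doses <- sub[sub$EVID == 1, ]
    obs <- sub[sub$EVID == 0, ]
    segs <- data.frame(start = doses$TIME, duration = doses$AMT / doses$RATE,
                       rate = doses$RATE)
    w <- sub$WT[1]
    inh <- obs$INH[1]
    lik <- 0
    for (i in seq_len(n_nodes)) {
      eta_cl <- pop$omega_cl * gh$nodes[i]
      cl <- pop$theta_cl * (w / pop$ref_weight)^pop$exp_cl *
        pop$theta_inh^inh * exp(eta_cl)
      for (j in seq_len(n_nodes)) {
        eta_v1 <- pop$omega_v1 * gh$nodes[j]
        v1 <- pop$theta_v1 * (w / pop$ref_weight)^pop$exp_v * exp(eta_v1)
        f <- ode_conc(obs$TIME, segs, cl, v1, cl * pop$fact, v1 * pop$fact)
        ll <- sum(stats::dnorm(obs$DV, f, pop$sigma_prop * f, log = TRUE))
        lik <- lik + gh$weights[i] * gh$weights[j] * exp(ll)
      }
    }
    total <- total - 2 * log(lik)
  }
  total
}
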