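# Model-evaluation surfaces: goodness-of-fit records (PRED/IPRED/CWRES)
# and the confidence-interval visual predictive check.

# rebuild a subject's effect vector in grid layout from an eb entry
eb_to_b <- function(grid, eb) {
  b <- numeric(0)
  if (grid$has_eta_cl) b <- c(b, eb$eta_cl)
  if (grid$has_eta_v1) b <- c(b, eb$eta_v1)
  if (grid$n_kappa) {
    want <- paste0("occ", grid$occ_labels)
    miss <- setdiff(want, names(eb$kappa))
    if (length(miss))
      stop("EB estimates lack occasion effect(s) ", paste(miss, collapse = ", "),
           " for subject ", grid$id, call. = FALSE)
    b <- c(b, unname(eb$kappa[want]))
  }
  b
}

grid_prior_sd <- function(grid, pop) {
  c(if (grid$has_eta_cl) pop$omega_cl,
    if (grid$has_eta_v1) pop$omega_v1,
    rep(pop$pi_cl, grid$n_kappa))
}

#' Goodness-of-fit table with conditional weighted residuals
#'
#' For every observation computes the population prediction `PRED` (all
#' random effects at 0), the individual prediction `IPRED` (at the
#' empirical Bayes modes) and `CWRES`, the conditional weighted residual
#' under the first-order-conditional linearization with interaction:
#' with `J` the sensitivity of the prediction to the subject's effects at
#' the mode `b`, residuals `y - f(b) + J b` are whitened by the Cholesky
#' factor of `V = J Omega J' + diag(sigma^2 IPRED^2)`. For data simulated
#' from the model, CWRES are approximately standard normal.
#'
#' @param dataset A `pk_dataset`.
#' @param pop A [pop_parameters()].
#' @param eb Optional list of per-subject EB estimates (as produced by
#'   [fit_population()], field `eb_estimates`, or [map_estimate()] results
#'   named by subject). Missing subjects raise an error naming them; if
#'   `NULL`, MAP modes are computed here.
#' @inheritParams map_estimate
#' @return `data.frame` of class `gof_table` with columns `id`, `time`,
#'   `dv`, `pred`, `ipred`, `cwres`.
#' @export
gof_table <- function(dataset, pop, eb = NULL, covariates = character(),
                      beta_cov = numeric(0)) {
  stopifnot(inherits(pop, "pop_parameters"))
  dataset <- validate_pk_dataset(dataset)
  grids <- build_grids(dataset, pop, covariates)
  pars <- pars_vec(pop)
  beta <- c(log(pop$theta_inh), beta_cov)
  if (!is.null(eb)) {
    miss <- setdiff(names(grids), names(eb))
    if (length(miss))
      stop("no EB estimates for subject(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  out <- lapply(names(grids), function(id) {
    g <- grids[[id]]
    if (!length(g$dv)) return(NULL)
    b <- if (is.null(eb)) {
      cpp_sub_map(g, pars, beta, numeric(0), 200L, 1e-6)$b
    } else eb_to_b(g, eb[[id]])
    f0 <- as.vector(cpp_sub_ipred(g, pars, beta, numeric(length(b))))
    fb <- as.vector(cpp_sub_ipred(g, pars, beta, b))
    fe <- pmax(fb, 1e-9)
    nb <- length(b)
    if (nb > 0) {
      J <- cpp_sub_jac(g, pars, beta, b)
      sdb <- grid_prior_sd(g, pop)
      V <- J %*% (sdb^2 * t(J)) + diag(pop$sigma_prop^2 * fe^2,
                                       length(fe))
      r <- g$dv - fb + as.vector(J %*% b)
    } else {
      V <- diag(pop$sigma_prop^2 * fe^2, length(fe))
      r <- g$dv - fb
    }
    L <- t(chol(V))
    cwres <- as.vector(forwardsolve(L, r))
    data.frame(id = g$id, time = g$obs_time, dv = g$dv, pred = f0,
               ipred = fb, cwres = cwres)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("gof_table", "data.frame")
  res
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicate datasets from the model, keeping every
#' subject's actual regimen, covariates and sampling times, and compares
#' the observed concentration percentiles per time bin with the simulated
#' confidence band of each percentile. Bins default to study day (24-h
#' wide). Uses R's global random number stream.
#'
#' @param dataset A `pk_dataset`.
#' @param pop A [pop_parameters()] (typically the fit estimates).
#' @param n_sim Number of simulation replicates (>= 100).
#' @param bin_width Bin width in days.
#' @param band_level Confidence level of the simulated percentile bands.
#' @param pi_levels Percentiles tracked (default 5th/50th/95th).
#' @inheritParams map_estimate
#' @return `data.frame` of class `pk_vpc` with one row per bin and
#'   percentile: observed value and simulated band (`sim_lo`, `sim_md`,
#'   `sim_hi`); bins without observations are dropped with a warning.
#' @export
vpc <- function(dataset, pop, n_sim = 500, bin_width = 1, band_level = 0.9,
                pi_levels = c(0.05, 0.5, 0.95), covariates = character(),
                beta_cov = numeric(0)) {
  stopifnot(inherits(pop, "pop_parameters"))
  if (n_sim < 100) stop("'n_sim' must be >= 100", call. = FALSE)
  dataset <- validate_pk_dataset(dataset)
  grids <- build_grids(dataset, pop, covariates, kappa_all = TRUE)
  grids <- Filter(function(g) length(g$dv) > 0, grids)
  pars <- pars_vec(pop)
  beta <- c(log(pop$theta_inh), beta_cov)
  obs_time <- unlist(lapply(grids, `[[`, "obs_time"))
  obs_dv <- unlist(lapply(grids, `[[`, "dv"))
  bin <- floor(obs_time / (24 * bin_width)) + 1L
  all_bins <- seq_len(max(bin))
  empty <- setdiff(all_bins, unique(bin))
  if (length(empty))
    warning("dropping empty bin(s): ", paste(empty, collapse = ", "))
  bins <- sort(unique(bin))
  qs <- function(x) quantile(x, probs = pi_levels, names = FALSE, type = 7)
  obs_q <- t(vapply(bins, function(bn) qs(obs_dv[bin == bn]),
                    numeric(length(pi_levels))))
  sim_q <- array(NA_real_, c(n_sim, length(bins), length(pi_levels)))
  for (r in seq_len(n_sim)) {
    sim_dv <- unlist(lapply(grids, function(g) {
      nb <- g$has_eta_cl + g$has_eta_v1 + g$n_kappa
      b <- rnorm(nb, 0, grid_prior_sd(g, pop))
      f <- as.vector(cpp_sub_ipred(g, pars, beta, b))
      pmax(0, f * (1 + rnorm(length(f), 0, pop$sigma_prop)))
    }))
    for (k in seq_along(bins))
      sim_q[r, k, ] <- qs(sim_dv[bin == bins[k]])
  }
  lo <- (1 - band_level) / 2
  out <- do.call(rbind, lapply(seq_along(bins), function(k) {
    data.frame(bin = bins[k],
               t_lo = 24 * bin_width * (bins[k] - 1),
               t_hi = 24 * bin_width * bins[k],
               n_obs = sum(bin == bins[k]),
               percentile = 100 * pi_levels,
               observed = obs_q[k, ],
               sim_lo = apply(sim_q[, k, , drop = FALSE], 3,
                              quantile, probs = lo, names = FALSE),
               sim_md = apply(sim_q[, k, , drop = FALSE], 3,
                              quantile, probs = 0.5, names = FALSE),
               sim_hi = apply(sim_q[, k, , drop = FALSE], 3,
                              quantile, probs = 1 - lo, names = FALSE))
  }))
  rownames(out) <- NULL
  attr(out, "n_sim") <- n_sim
  attr(out, "band_level") <- band_level
  class(out) <- c("pk_vpc", "data.frame")
  out
}

#' Plot a visual predictive check
#'
#' Observed percentiles (lines) against the simulated confidence bands
#' (ribbons), per time bin. Needs ggplot2.
#'
#' @param v A [vpc()] result.
#' @return A ggplot object.
#' @export
plot_vpc <- function(v) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  v$day <- (v$t_lo + v$t_hi) / 48
  ggplot2::ggplot(v, ggplot2::aes(x = day,
                                  group = factor(percentile))) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = sim_lo,
                                      ymax = sim_hi),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = observed,
                                    linetype = factor(percentile))) +
    ggplot2::labs(x = "Time (days)", y = "Tacrolimus (ng/ml)",
                  linetype = "Observed percentile") +
    ggplot2::theme_minimal()
}

#' Plot goodness-of-fit panels
#'
#' DV vs PRED/IPRED and CWRES vs PRED/time. Needs ggplot2 (and patchwork is
#' not required; four separate plots are returned in a list).
#'
#' @param g A [gof_table()] result.
#' @return A list of ggplot objects (`dv_pred`, `dv_ipred`, `cwres_pred`,
#'   `cwres_time`).
#' @export
plot_gof <- function(g) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  base <- ggplot2::theme_minimal()
  list(
    dv_pred = ggplot2::ggplot(g, ggplot2::aes(pred, dv)) +
      ggplot2::geom_point(alpha = 0.4) +
      ggplot2::geom_abline(slope = 1, intercept = 0) +
      ggplot2::labs(x = "PRED (ng/ml)", y = "DV (ng/ml)") + base,
    dv_ipred = ggplot2::ggplot(g, ggplot2::aes(ipred, dv)) +
      ggplot2::geom_point(alpha = 0.4) +
      ggplot2::geom_abline(slope = 1, intercept = 0) +
      ggplot2::labs(x = "IPRED (ng/ml)", y = "DV (ng/ml)") + base,
    cwres_pred = ggplot2::ggplot(g, ggplot2::aes(pred, cwres)) +
      ggplot2::geom_point(alpha = 0.4) +
      ggplot2::geom_hline(yintercept = 0) +
      ggplot2::labs(x = "PRED (ng/ml)", y = "CWRES") + base,
    cwres_time = ggplot2::ggplot(g, ggplot2::aes(time, cwres)) +
      ggplot2::geom_point(alpha = 0.4) +
      ggplot2::geom_hline(yintercept = 0) +
      ggplot2::labs(x = "Time (h)", y = "CWRES") + base)
}
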