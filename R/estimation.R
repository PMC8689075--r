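# Marginal-likelihood population estimation (Laplace / FOCE-I), empirical
# Bayes (MAP) individual estimation, and stepwise covariate search.

# positions must match src/pk_core.cpp
pars_vec <- function(pop) {
  c(pop$theta_cl, pop$theta_v1, pop$fact, pop$exp_cl, pop$exp_v,
    pop$ref_weight, pop$sigma_prop, pop$omega_cl, pop$omega_v1, pop$pi_cl)
}

effects_of <- function(pop) {
  c(eta_cl = unname(pop$omega_cl > 0), eta_v1 = unname(pop$omega_v1 > 0),
    kappa = unname(pop$pi_cl > 0))
}

split_subjects <- function(dataset) {
  ds <- as.data.frame(dataset)
  split(ds, factor(ds$ID, levels = unique(ds$ID)))
}

cov_refs <- function(dataset, covariates) {
  if (!length(covariates)) return(NULL)
  refs <- list()
  for (col in names(covariates)) {
    if (!col %in% names(dataset))
      stop("covariate column '", col, "' not in dataset", call. = FALSE)
    if (covariates[[col]] == "continuous") {
      per_sub <- vapply(split_subjects(dataset),
                        function(s) s[[col]][1], numeric(1))
      refs[[col]] <- median(per_sub)
    }
  }
  refs
}

build_grids <- function(dataset, pop, covariates = character(),
                        kappa_all = FALSE) {
  refs <- cov_refs(dataset, covariates)
  lapply(split_subjects(dataset), build_subject_grid,
         covariates = covariates, effects = effects_of(pop),
         kappa_all = kappa_all, cov_ref = refs)
}

# parameter transforms for the outer optimization
.log_pars <- c("theta_cl", "theta_v1", "theta_inh", "fact", "omega_cl",
               "omega_v1", "pi_cl", "sigma_prop")
.id_pars <- c("exp_cl", "exp_v", "ref_weight")

to_t <- function(name, value) {
  if (name %in% .log_pars) log(value) else value
}
from_t <- function(name, value) {
  if (name %in% .log_pars) exp(value) else value
}

new_pop_unchecked <- function(p) structure(p, class = "pop_parameters")

#' Empirical Bayes (MAP) estimate of a subject's random effects
#'
#' Finds the joint posterior mode of `(eta_cl, eta_v1, kappa_1..J)` given
#' one subject's observations and the population model, by minimizing the
#' penalized deviance
#' `sum[(DV - IPRED)^2 / (sigma^2 IPRED^2) + log(sigma^2 IPRED^2)] +
#' eta' Omega^-1 eta + sum_j kappa_j^2 / pi^2` (damped Gauss-Newton with the
#' proportional-error interaction term in the gradient). Effects whose
#' population SD is 0 are fixed at 0; occasions without observations carry
#' no `kappa` (their mode is 0). With no observations at all, the prior mode
#' (all zeros) is returned.
#'
#' @param subject_data Event rows of a single subject (the dataset dialect
#'   of [read_pk_dataset()]).
#' @param pop A [pop_parameters()] object.
#' @param covariates Optional extra clearance covariates as a named vector
#'   `c(COLUMN = "binary"|"continuous")`.
#' @param beta_cov Coefficients for `covariates` (log CL multipliers).
#' @param maxit,gtol Inner optimizer controls (max iterations; infinity-norm
#'   gradient tolerance at the mode).
#' @return A list with `eta_cl`, `eta_v1`, `kappa` (named by occasion),
#'   `objective`, `grad_norm`, `converged`.
#' @export
map_estimate <- function(subject_data, pop, covariates = character(),
                         beta_cov = numeric(0), maxit = 200, gtol = 1e-6) {
  stopifnot(inherits(pop, "pop_parameters"))
  if (length(unique(subject_data$ID)) > 1)
    stop("'subject_data' must contain a single subject", call. = FALSE)
  grid <- build_subject_grid(subject_data, covariates = covariates,
                             effects = effects_of(pop),
                             cov_ref = cov_refs(subject_data, covariates))
  beta <- c(log(pop$theta_inh), beta_cov)
  res <- cpp_sub_map(grid, pars_vec(pop), beta, numeric(0), maxit, gtol)
  if (!is.finite(res$g))
    stop("MAP estimation failed: non-finite objective", call. = FALSE)
  b <- res$b
  j <- 0
  eta_cl <- if (grid$has_eta_cl) b[j <- j + 1] else 0
  eta_v1 <- if (grid$has_eta_v1) b[j <- j + 1] else 0
  kappa <- if (grid$n_kappa) setNames(b[j + seq_len(grid$n_kappa)],
                                      paste0("occ", grid$occ_labels))
           else setNames(numeric(0), character(0))
  structure(list(eta_cl = eta_cl, eta_v1 = eta_v1, kappa = kappa,
                 objective = res$g, grad_norm = res$grad_norm,
                 converged = res$converged),
            class = "map_estimate")
}

#' Marginal objective function value (-2 log likelihood)
#'
#' Approximates `-2 sum_i log integral L_i(b) p(b) db`, each subject
#' integral by an expansion at the joint MAP mode: method `"foce"` uses the
#' first-order-conditional linearization with interaction (marginal
#' covariance `J Omega J' + diag(sigma^2 IPRED^2)` at the mode), method
#' `"laplace"` the full Laplace approximation (numerical Hessian of the
#' penalized deviance), and method `"agq"` adaptive Gauss-Hermite
#' quadrature over the subject-level effects combined with a
#' Gauss-Hermite/Kalman filter over the occasion effects (exact adaptive
#' quadrature when inter-occasion variability is off; the most accurate of
#' the three on sparse trough designs, see the methods vignette).
#'
#' @param dataset A `pk_dataset` with at least one observation.
#' @param pop A [pop_parameters()]; `sigma_prop` must be > 0.
#' @param method `"foce"` (default), `"laplace"`, or `"agq"`.
#' @inheritParams map_estimate
#' @return The OFV (numeric scalar) with per-subject contributions in
#'   attribute `"ofv_i"`.
#' @export
marginal_ofv <- function(dataset, pop, method = c("foce", "laplace", "agq"),
                         covariates = character(), beta_cov = numeric(0)) {
  method <- match.arg(method)
  stopifnot(inherits(pop, "pop_parameters"))
  if (pop$sigma_prop <= 0)
    stop("'sigma_prop' must be > 0 for a marginal likelihood", call. = FALSE)
  if (!any(dataset$EVID == 0))
    stop("dataset has no observations", call. = FALSE)
  grids <- build_grids(dataset, pop, covariates)
  beta <- c(log(pop$theta_inh), beta_cov)
  res <- cpp_cohort_eval(grids, pars_vec(pop), beta,
                         vector("list", length(grids)),
                         method = match(method,
                                        c("foce", "laplace", "agq")) - 1L)
  structure(res$ofv, ofv_i = setNames(res$ofv_i, names(grids)))
}

#' Fit the population model by marginal-likelihood minimization
#'
#' Minimizes the Laplace/FOCE-I objective of [marginal_ofv()] over the free
#' population parameters (positive parameters on the log scale; allometric
#' exponents on the natural scale), with per-subject MAP modes warm-started
#' across outer iterations. The structural constants `fact`, `exp_cl`,
#' `exp_v` and `ref_weight` are fixed unless explicitly freed.
#'
#' @param dataset A `pk_dataset` event table.
#' @param init A [pop_parameters()] object giving initial values (and the
#'   values of all fixed parameters). Random-effect SDs that are 0 in
#'   `init` switch the corresponding effect off entirely.
#' @param free Character vector of parameter names to estimate, from
#'   `theta_cl`, `theta_v1`, `theta_inh`, `fact`, `exp_cl`, `exp_v`,
#'   `omega_cl`, `omega_v1`, `pi_cl`, `sigma_prop`.
#' @param covariates Optional extra clearance covariates, named vector
#'   `c(COLUMN = "binary"|"continuous")`; their coefficients (log CL
#'   multipliers, initialized at 0) are always estimated.
#' @param method Subject-level marginal approximation, see [marginal_ofv()].
#' @param se Compute standard errors from the numerical Hessian of OFV/2
#'   (slower; off by default).
#' @param control List of optimizer controls: `outer_iter` (150),
#'   `outer_eval` (1500), `rel_tol` (1e-8), `inner_maxit` (200),
#'   `inner_gtol` (1e-6), `trace` (0).
#' @return An object of class `pk_fit`: `estimates` (a `pop_parameters`),
#'   `beta_cov`, `ofv`, `eb_estimates` (per-subject MAP modes),
#'   `se_table` (if requested), `convergence`, bookkeeping fields.
#' @export
fit_population <- function(dataset,
                           init = pop_parameters(),
                           free = c("theta_cl", "theta_v1", "theta_inh",
                                    "omega_cl", "omega_v1", "pi_cl",
                                    "sigma_prop"),
                           covariates = NULL,
                           method = c("foce", "laplace", "agq"),
                           se = FALSE, control = list()) {
  method <- match.arg(method)
  stopifnot(inherits(init, "pop_parameters"))
  ctl <- modifyList(list(outer_iter = 150, outer_eval = 1500,
                         rel_tol = 1e-8, inner_maxit = 200,
                         inner_gtol = 1e-6, trace = 0), control)
  allowed <- c("theta_cl", "theta_v1", "theta_inh", "fact", "exp_cl",
               "exp_v", "omega_cl", "omega_v1", "pi_cl", "sigma_prop")
  bad <- setdiff(free, allowed)
  if (length(bad))
    stop("unknown free parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (init$sigma_prop <= 0)
    stop("'sigma_prop' must be > 0", call. = FALSE)
  for (nm in intersect(free, c("omega_cl", "omega_v1", "pi_cl")))
    if (init[[nm]] <= 0)
      stop("free variance parameter '", nm, "' needs a positive initial ",
           "value", call. = FALSE)
  covariates <- if (is.null(covariates)) character() else covariates
  dataset <- validate_pk_dataset(dataset)
  grids <- build_grids(dataset, init, covariates)
  n_sub <- length(grids)
  n_obs <- sum(dataset$EVID == 0)
  beta_names <- if (length(covariates)) paste0("beta_", names(covariates))
                else character(0)
  par_names <- c(free, beta_names)
  start <- c(vapply(free, function(nm) to_t(nm, init[[nm]]), numeric(1)),
             setNames(rep(0, length(beta_names)), beta_names))
  method_int <- match(method, c("foce", "laplace", "agq")) - 1L

  decode <- function(tp) {
    p <- unclass(init)
    for (k in seq_along(free))
      p[[free[k]]] <- unname(from_t(free[k], tp[k]))
    beta_cov <- if (length(beta_names)) tp[length(free) + seq_along(beta_names)]
                else numeric(0)
    list(pop = p, pars = pars_vec(p),
         beta = c(log(p$theta_inh), beta_cov), beta_cov = beta_cov)
  }

  env <- new.env()
  env$modes <- vector("list", n_sub)
  env$evals <- 0L
  objective <- function(tp) {
    d <- decode(tp)
    res <- cpp_cohort_eval(grids, d$pars, d$beta, env$modes, method_int,
                           ctl$inner_maxit, ctl$inner_gtol)
    env$evals <- env$evals + 1L
    if (!is.finite(res$ofv)) return(1e10)
    env$modes <- res$modes
    if (ctl$trace > 0 && env$evals %% ctl$trace == 0)
      message(sprintf("eval %d: OFV %.4f", env$evals, res$ofv))
    res$ofv
  }

  # explicit central-difference gradient: far more robust than the
  # optimizer's internal differencing against the small evaluation noise
  # left by warm-started inner modes
  gradient <- function(tp) {
    h <- 1e-4
    vapply(seq_along(tp), function(i) {
      tp_p <- tp; tp_p[i] <- tp[i] + h
      tp_m <- tp; tp_m[i] <- tp[i] - h
      (objective(tp_p) - objective(tp_m)) / (2 * h)
    }, numeric(1))
  }
  opt <- nlminb(start, objective, gradient = gradient,
                control = list(iter.max = ctl$outer_iter,
                               eval.max = ctl$outer_eval,
                               rel.tol = ctl$rel_tol))
  d <- decode(opt$par)
  final <- cpp_cohort_eval(grids, d$pars, d$beta, env$modes, method_int,
                           ctl$inner_maxit, ctl$inner_gtol)
  eb <- lapply(seq_len(n_sub), function(i) {
    g <- grids[[i]]
    b <- final$modes[[i]]
    j <- 0
    list(id = g$id,
         eta_cl = if (g$has_eta_cl) b[j <- j + 1] else 0,
         eta_v1 = if (g$has_eta_v1) b[j <- j + 1] else 0,
         kappa = if (g$n_kappa) setNames(b[j + seq_len(g$n_kappa)],
                                         paste0("occ", g$occ_labels))
                 else setNames(numeric(0), character(0)))
  })
  names(eb) <- names(grids)

  se_table <- NULL
  if (se) {
    se_table <- tryCatch(
      fit_se(objective, opt$par, par_names, free, d),
      error = function(e) {
        warning("SE computation failed: ", conditionMessage(e))
        NULL
      })
  }

  structure(list(estimates = new_pop_unchecked(d$pop),
                 beta_cov = setNames(d$beta_cov, names(covariates)),
                 covariates = covariates,
                 ofv = final$ofv,
                 eb_estimates = eb,
                 se_table = se_table,
                 convergence = list(code = opt$convergence,
                                    message = opt$message,
                                    iterations = opt$iterations,
                                    evaluations = env$evals,
                                    inner_converged = mean(final$converged),
                                    max_inner_grad = max(final$grad_norm)),
                 free = free, method = method,
                 n_subjects = n_sub, n_obs = n_obs),
            class = "pk_fit")
}

# standard errors from the numerical Hessian of OFV/2 (transformed scale),
# delta-method back to the natural scale for log-parameterized entries
fit_se <- function(objective, par, par_names, free, d) {
  np <- length(par)
  h <- 1e-4 * pmax(1, abs(par))
  H <- matrix(NA_real_, np, np)
  f0 <- objective(par) / 2
  fp <- fm <- numeric(np)
  for (i in seq_len(np)) {
    xp <- par; xp[i] <- par[i] + h[i]
    xm <- par; xm[i] <- par[i] - h[i]
    fp[i] <- objective(xp) / 2
    fm[i] <- objective(xm) / 2
    H[i, i] <- (fp[i] + fm[i] - 2 * f0) / h[i]^2
  }
  if (np > 1) {
    for (i in 2:np) for (j in 1:(i - 1)) {
      xpp <- par; xpp[c(i, j)] <- par[c(i, j)] + h[c(i, j)]
      xmm <- par; xmm[c(i, j)] <- par[c(i, j)] - h[c(i, j)]
      H[i, j] <- H[j, i] <-
        ((objective(xpp) / 2 - fp[i] - fp[j] + f0) +
         (objective(xmm) / 2 - fm[i] - fm[j] + f0)) / (2 * h[i] * h[j])
    }
  }
  cov_t <- solve(H)
  se_t <- sqrt(pmax(diag(cov_t), 0))
  est <- vapply(seq_along(par_names), function(k) {
    nm <- par_names[k]
    if (k <= length(free)) from_t(nm, par[k]) else par[k]
  }, numeric(1))
  se_nat <- vapply(seq_along(par_names), function(k) {
    nm <- par_names[k]
    if (k <= length(free) && nm %in% .log_pars) est[k] * se_t[k] else se_t[k]
  }, numeric(1))
  data.frame(parameter = par_names, estimate = est, se = se_nat,
             rse_pct = 100 * se_nat / abs(est), row.names = NULL)
}

#' @export
print.pk_fit <- function(x, ...) {
  e <- x$estimates
  rse <- function(nm) {
    if (is.null(x$se_table)) return(if (nm %in% x$free) "-" else "fixed")
    i <- match(nm, x$se_table$parameter)
    if (is.na(i)) return(if (nm %in% x$free) "-" else "fixed")
    sprintf("%.3g%%", x$se_table$rse_pct[i])
  }
  cat(sprintf("Population PK fit (%s), OFV = %.3f\n",
              toupper(x$method), x$ofv))
  cat(sprintf("%d subjects, %d observations; %d outer evaluations\n\n",
              x$n_subjects, x$n_obs, x$convergence$evaluations))
  cat(sprintf("%-11s %-9s %-8s %-5s %-8s %-8s\n",
              "Parameter", "Value", "RSE", "Unit", "IIV", "IOV"))
  cat(sprintf("%-11s %-9.4g %-8s %-5s %-8s %-8s\n", "theta_CL", e$theta_cl,
              rse("theta_cl"), "L/h", sprintf("%.1f%%", 100 * e$omega_cl),
              sprintf("%.1f%%", 100 * e$pi_cl)))
  cat(sprintf("%-11s %-9.4g %-8s %-5s %-8s %-8s\n", "theta_V1", e$theta_v1,
              rse("theta_v1"), "L",
              if (e$omega_v1 > 0) sprintf("%.1f%%", 100 * e$omega_v1) else "-",
              "-"))
  cat(sprintf("%-11s %-9.4g %-8s\n", "theta_INH", e$theta_inh,
              rse("theta_inh")))
  cat(sprintf("%-11s %-9.4g %-8s\n", "Fact", e$fact, rse("fact")))
  cat(sprintf("%-11s %-9s %-8s (proportional residual error)\n",
              "sigma_prop", sprintf("%.1f%%", 100 * e$sigma_prop),
              rse("sigma_prop")))
  if (length(x$beta_cov))
    for (k in seq_along(x$beta_cov))
      cat(sprintf("%-11s %-9.4g (log CL multiplier)\n",
                  names(x$beta_cov)[k], x$beta_cov[k]))
  invisible(x)
}

#' Stepwise covariate search on clearance
#'
#' Forward inclusion followed by backward elimination of candidate
#' clearance covariates, judged by the change in the marginal objective:
#' a candidate enters while its inclusion improves the OFV by at least
#' `forward_dofv` (default 3.58, the published forward threshold), and is
#' retained only if its removal worsens the OFV by at least `backward_dofv`
#' (default the chi-square(1) 0.01 quantile, 6.63).
#'
#' @inheritParams fit_population
#' @param candidates Named vector `c(COLUMN = "binary"|"continuous")` of
#'   candidate clearance covariates.
#' @param forward_dofv,backward_dofv OFV-change thresholds (> 0).
#' @return A list of class `covariate_search`: `selected`, `steps` (the
#'   ΔOFV bookkeeping table), and `fit` (the final model fit).
#' @export
covariate_step <- function(dataset, init = pop_parameters(),
                           free = c("theta_cl", "theta_v1", "omega_cl",
                                    "omega_v1", "pi_cl", "sigma_prop"),
                           candidates = character(),
                           forward_dofv = 3.58,
                           backward_dofv = qchisq(0.99, 1),
                           method = "foce", control = list()) {
  refit <- function(sel) {
    fit_population(dataset, init = init, free = free,
                   covariates = if (length(sel)) candidates[sel] else NULL,
                   method = method, control = control)
  }
  current <- refit(character(0))
  selected <- character(0)
  steps <- list()
  if (length(candidates)) {
    repeat {
      pool <- setdiff(names(candidates), selected)
      if (!length(pool)) break
      fits <- lapply(pool, function(cd) refit(c(selected, cd)))
      dofv <- vapply(fits, function(f) f$ofv - current$ofv, numeric(1))
      for (k in seq_along(pool))
        steps[[length(steps) + 1L]] <-
          data.frame(phase = "forward", candidate = pool[k],
                     ofv = fits[[k]]$ofv, dofv = dofv[k],
                     action = "tested")
      best <- which.min(dofv)
      if (dofv[best] <= -forward_dofv) {
        selected <- c(selected, pool[best])
        current <- fits[[best]]
        steps[[length(steps)]]$action <- "tested"
        steps[[length(steps) + 1L]] <-
          data.frame(phase = "forward", candidate = pool[best],
                     ofv = current$ofv, dofv = dofv[best],
                     action = "included")
      } else break
    }
    repeat {
      dropped <- FALSE
      for (cd in selected) {
        without <- refit(setdiff(selected, cd))
        worsens <- without$ofv - current$ofv
        act <- if (worsens < backward_dofv) "removed" else "retained"
        steps[[length(steps) + 1L]] <-
          data.frame(phase = "backward", candidate = cd,
                     ofv = without$ofv, dofv = worsens, action = act)
        if (act == "removed") {
          selected <- setdiff(selected, cd)
          current <- without
          dropped <- TRUE
          break
        }
      }
      if (!dropped || !length(selected)) break
    }
  }
  structure(list(selected = selected,
                 steps = if (length(steps)) do.call(rbind, steps)
                         else data.frame(),
                 fit = current),
            class = "covariate_search")
}

#' @export
print.covariate_search <- function(x, ...) {
  cat("Stepwise covariate search on CL\n")
  cat("Selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
                   else "(none)", "\n")
  if (nrow(x$steps)) print(x$steps)
  invisible(x)
}
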