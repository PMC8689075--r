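#' Population parameters of the tacrolimus infusion model
#'
#' Container for the fixed effects, variance components and structural
#' constants of the final population model. Defaults are the published
#' estimates for pediatric/young-adult HCT patients on continuous IV
#' tacrolimus: typical clearance 4.2 L/h and central volume 61.9 L at the
#' 70-kg reference weight, a 0.8 fractional multiplier on clearance under
#' CYP3A4/5-inhibitor co-treatment, and peripheral-compartment constants
#' tied to the central ones by a fixed factor of 2
#' (`Q = CL * fact`, `V2 = V1 * fact`).
#'
#' Variability terms are standard deviations of log-scale (log-normal)
#' effects, reported throughout as percent CV via `100 * omega`:
#' inter-individual variability (IIV) on clearance 26.1% and on central
#' volume 30% (the latter an assumption, not an estimate), inter-occasion
#' variability (IOV) on clearance 28.7% with one occasion per 24-h infusion
#' bag, and proportional residual error 17.9%.
#'
#' @param theta_cl Typical clearance at the reference weight (L/h).
#' @param theta_v1 Typical central volume at the reference weight (L).
#' @param theta_inh Fractional multiplier on clearance under CYP3A4/5
#'   inhibitor co-treatment; must lie in (0, 1].
#' @param fact Fixed multiplier linking `q = cl * fact` and `v2 = v1 * fact`.
#' @param exp_cl Allometric weight exponent on clearance (theoretic 0.75).
#' @param exp_v Allometric weight exponent on central volume (theoretic 1).
#' @param ref_weight Reference body weight (kg).
#' @param omega_cl SD of the subject-level log-normal effect on clearance.
#' @param omega_v1 SD of the subject-level log-normal effect on volume.
#' @param pi_cl SD of the occasion-level log-normal effect on clearance.
#' @param sigma_prop Proportional residual error SD (fraction).
#' @return An object of class `pop_parameters` (a validated named list).
#' @examples
#' pop <- pop_parameters()
#' pop$theta_cl # 4.2 L/h
#' @export
pop_parameters <- function(theta_cl = 4.2, theta_v1 = 61.9, theta_inh = 0.8,
                           fact = 2, exp_cl = 0.75, exp_v = 1,
                           ref_weight = 70, omega_cl = 0.261,
                           omega_v1 = 0.30, pi_cl = 0.287,
                           sigma_prop = 0.179) {
  p <- list(theta_cl = theta_cl, theta_v1 = theta_v1, theta_inh = theta_inh,
            fact = fact, exp_cl = exp_cl, exp_v = exp_v,
            ref_weight = ref_weight, omega_cl = omega_cl,
            omega_v1 = omega_v1, pi_cl = pi_cl, sigma_prop = sigma_prop)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  strict <- c("theta_cl", "theta_v1", "theta_inh", "fact", "exp_cl", "exp_v",
              "ref_weight")
  for (nm in strict)
    if (p[[nm]] <= 0) stop("'", nm, "' must be > 0", call. = FALSE)
  for (nm in c("omega_cl", "omega_v1", "pi_cl", "sigma_prop"))
    if (p[[nm]] < 0) stop("'", nm, "' must be >= 0", call. = FALSE)
  if (p$theta_inh > 1)
    stop("'theta_inh' must lie in (0, 1]", call. = FALSE)
  structure(p, class = "pop_parameters")
}

#' @export
print.pop_parameters <- function(x, ...) {
  cat("Population PK parameters (2-cmt continuous-infusion tacrolimus)\n")
  fmt <- function(v) formatC(v, digits = 4, format = "g")
  cat(sprintf("  theta_CL  %-8s L/h   (IIV %s%%, IOV %s%%)\n",
              fmt(x$theta_cl), fmt(100 * x$omega_cl), fmt(100 * x$pi_cl)))
  cat(sprintf("  theta_V1  %-8s L     (IIV %s%%)\n",
              fmt(x$theta_v1), fmt(100 * x$omega_v1)))
  cat(sprintf("  theta_INH %-8s (CL multiplier under CYP3A4/5 inhibitor)\n",
              fmt(x$theta_inh)))
  cat(sprintf("  Fact      %-8s (Q = CL*Fact, V2 = V1*Fact)\n", fmt(x$fact)))
  cat(sprintf("  allometry CL ~ (WT/%g)^%g, V1 ~ (WT/%g)^%g\n",
              x$ref_weight, x$exp_cl, x$ref_weight, x$exp_v))
  cat(sprintf("  sigma_prop %s%% (proportional residual error)\n",
              fmt(100 * x$sigma_prop)))
  invisible(x)
}

#' Realized individual parameters
#'
#' Applies the covariate model and the (log-normal) random effects to obtain
#' a subject's parameters for one occasion:
#' `cl = theta_cl * (weight/ref)^exp_cl * theta_inh^inhibitor *
#' exp(eta_cl + kappa)`, `v1 = theta_v1 * (weight/ref)^exp_v * exp(eta_v1)`,
#' `q = cl * fact`, `v2 = v1 * fact`.
#'
#' @param pop A [pop_parameters()] object.
#' @param weight Total body weight (kg), > 0.
#' @param inhibitor 0/1 CYP3A4/5-inhibitor co-treatment indicator.
#' @param eta_cl,eta_v1 Subject-level random effects (log scale).
#' @param kappa Occasion-level random effect on clearance (log scale).
#' @return An object of class `individual_parameters` with elements
#'   `cl`, `v1`, `q`, `v2` (L/h, L, L/h, L).
#' @examples
#' individual_parameters(pop_parameters(), weight = 70, inhibitor = 0)$cl # 4.2
#' @export
individual_parameters <- function(pop, weight, inhibitor = 0, eta_cl = 0,
                                  eta_v1 = 0, kappa = 0) {
  stopifnot(inherits(pop, "pop_parameters"))
  if (!is.numeric(weight) || length(weight) != 1L || !is.finite(weight) ||
      weight <= 0)
    stop("'weight' must be a single positive number", call. = FALSE)
  if (!inhibitor %in% c(0, 1))
    stop("'inhibitor' must be 0 or 1", call. = FALSE)
  cl <- pop$theta_cl * (weight / pop$ref_weight)^pop$exp_cl *
    pop$theta_inh^inhibitor * exp(eta_cl + kappa)
  v1 <- pop$theta_v1 * (weight / pop$ref_weight)^pop$exp_v * exp(eta_v1)
  structure(list(cl = cl, v1 = v1, q = cl * pop$fact, v2 = v1 * pop$fact,
                 weight = weight, inhibitor = inhibitor,
                 eta_cl = eta_cl, eta_v1 = eta_v1, kappa = kappa),
            class = "individual_parameters")
}

#' @export
print.individual_parameters <- function(x, ...) {
  cat(sprintf(
    "Individual PK parameters: CL %.4g L/h, V1 %.4g L, Q %.4g L/h, V2 %.4g L\n",
    x$cl, x$v1, x$q, x$v2))
  invisible(x)
}

#' Drug-amount state of the two-compartment system
#'
#' @param a1,a2 Drug amounts (ug) in the central and peripheral compartment.
#' @param t Clock time (h).
#' @return An object of class `pk_state`.
#' @export
pk_state <- function(a1 = 0, a2 = 0, t = 0) {
  if (a1 < 0 || a2 < 0) stop("amounts must be >= 0", call. = FALSE)
  structure(list(a1 = a1, a2 = a2, t = t), class = "pk_state")
}
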