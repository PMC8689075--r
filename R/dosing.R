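# Model-based dose individualization: typical-value starting rates and
# MAP-forecast rate recommendations targeting a trough window.

new_dose_rec <- function(rate, weight, predicted, target_window, basis) {
  structure(list(rate = rate, rate_per_kg = rate / weight,
                 rate_per_kg_rounded = round(rate / weight, 2),
                 predicted_trough = predicted,
                 target = target_window, basis = basis),
            class = "dose_recommendation")
}

#' @export
print.dose_recommendation <- function(x, ...) {
  cat(sprintf(
    "Dose recommendation (%s): %.4g ug/h = %.4g ug/kg/h (rounded %.2f)\n",
    x$basis, x$rate, x$rate_per_kg, x$rate_per_kg_rounded))
  cat(sprintf("predicted trough %.4g ng/ml (target %.3g-%.3g ng/ml)\n",
              x$predicted_trough, x$target[1], x$target[2]))
  invisible(x)
}

#' Model-based starting infusion rate
#'
#' Steady-state basis: the trough of a continuous infusion equals
#' `rate / CL`, so the rate targeting `target_trough` is
#' `target_trough * CL_typical(weight, inhibitor)`.
#'
#' @param pop A [pop_parameters()].
#' @param weight Body weight (kg), > 0.
#' @param inhibitor 0/1 CYP3A4/5-inhibitor co-treatment.
#' @param target_trough Target trough (ng/ml), >= 0; default the midpoint
#'   of the 7-10 ng/ml window.
#' @param target_window Therapeutic window (ng/ml), used for reporting.
#' @return A `dose_recommendation` (rate in ug/h; also per-kg, raw and
#'   rounded to 0.01 ug/kg/h pump granularity).
#' @examples
#' initial_rate(pop_parameters(), weight = 70)  # 35.7 ug/h = 0.51 ug/kg/h
#' @export
initial_rate <- function(pop, weight, inhibitor = 0, target_trough = 8.5,
                         target_window = c(7, 10)) {
  stopifnot(inherits(pop, "pop_parameters"))
  if (!is.numeric(weight) || length(weight) != 1 || weight <= 0)
    stop("'weight' must be a single positive number", call. = FALSE)
  if (target_trough < 0) stop("'target_trough' must be >= 0", call. = FALSE)
  cl <- individual_parameters(pop, weight, inhibitor)$cl
  new_dose_rec(target_trough * cl, weight, target_trough, target_window,
               basis = "typical")
}

#' MAP-forecast individualized infusion rate
#'
#' Bayesian forecasting: estimates the subject's random effects by
#' [map_estimate()], propagates the drug amounts through the recorded
#' dosing history to the time of the last record, and solves for the
#' constant future rate whose predicted concentration at `horizon` hours
#' later equals `target_trough`. For the linear kinetics the predicted
#' concentration is affine in the future rate, so the solve is exact; a
#' negative solution (target unreachable while concentrations decay) is
#' floored at rate 0. Occasion effects for future occasions are set to 0
#' (the prior mode), and the inhibitor status of the last record is
#' carried forward.
#'
#' @param subject_data Event rows of a single subject with >= 1 observation.
#' @param pop A [pop_parameters()].
#' @param target_trough Target concentration (ng/ml) at the horizon.
#' @param horizon Forecast horizon (h) after the last record, > 0; default
#'   the next daily trough.
#' @param target_window Reported therapeutic window (ng/ml).
#' @inheritParams map_estimate
#' @return A `dose_recommendation` with `basis = "MAP"` and the MAP
#'   estimates in attribute `"map"`.
#' @export
adaptive_rate <- function(subject_data, pop, target_trough = 8.5,
                          horizon = 24, target_window = c(7, 10),
                          covariates = character(),
                          beta_cov = numeric(0)) {
  stopifnot(inherits(pop, "pop_parameters"))
  if (horizon <= 0) stop("'horizon' must be > 0", call. = FALSE)
  if (!any(subject_data$EVID == 0))
    stop("need at least one observed trough", call. = FALSE)
  mp <- map_estimate(subject_data, pop, covariates, beta_cov)
  t_anchor <- max(subject_data$TIME)
  grid <- build_subject_grid(subject_data, covariates = covariates,
                             effects = effects_of(pop), t_end = t_anchor,
                             cov_ref = cov_refs(subject_data, covariates))
  pars <- pars_vec(pop)
  beta <- c(log(pop$theta_inh), beta_cov)
  b <- eb_to_b(grid, mp)
  st <- cpp_sub_state(grid, pars, beta, b)
  a1 <- st[1]; a2 <- st[2]; v1 <- st[3]
  w <- grid$weight
  covm <- if (nrow(grid$z)) sum(grid$z[nrow(grid$z), ] * beta) else 0
  # the running occasion keeps its estimated kappa until its bag ends;
  # occasions beyond that use the prior mode (kappa = 0)
  doses <- subject_data[subject_data$EVID == 1, , drop = FALSE]
  t_occ_end <- if (nrow(doses))
    max(doses$TIME + doses$AMT / doses$RATE) else t_anchor
  occ_last <- subject_data$OCC[which.max(subject_data$TIME)]
  kap_cur <- unname(mp$kappa[paste0("occ", occ_last)])
  if (is.na(kap_cur) || !length(kap_cur)) kap_cur <- 0
  base_cl <- pop$theta_cl * (w / pop$ref_weight)^pop$exp_cl *
    exp(covm + mp$eta_cl)
  cl_cur <- base_cl * exp(kap_cur)
  fut <- function(rate) {
    a <- c(a1, a2)
    d1 <- min(max(t_occ_end - t_anchor, 0), horizon)
    if (d1 > 0)
      a <- cpp_propagate(a[1], a[2], cl_cur, v1, cl_cur * pop$fact,
                         v1 * pop$fact, rate, d1)
    if (horizon - d1 > 0)
      a <- cpp_propagate(a[1], a[2], base_cl, v1, base_cl * pop$fact,
                         v1 * pop$fact, rate, horizon - d1)
    a[1] / v1
  }
  c0 <- fut(0)
  slope <- fut(1) - c0
  rate <- max(0, (target_trough - c0) / slope)
  rec <- new_dose_rec(rate, w, c0 + slope * rate, target_window,
                      basis = "MAP")
  attr(rec, "map") <- mp
  rec
}
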