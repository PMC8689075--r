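#' Advance the two-compartment state under a constant infusion rate
#'
#' Exact (closed-form) solution of the linear system
#' `dA1/dt = R - (CL/V1 + Q/V1) A1 + (Q/V2) A2`,
#' `dA2/dt = (Q/V1) A1 - (Q/V2) A2`
#' over a step of length `dt`, via the eigendecomposition of the 2x2 rate
#' matrix. Concentration is `a1 / v1` in ng/ml (= ug/L).
#'
#' @param state A [pk_state()] object.
#' @param params An [individual_parameters()] object.
#' @param rate Zero-order input rate (ug/h), >= 0.
#' @param dt Step length (h), >= 0.
#' @return The advanced [pk_state()].
#' @export
propagate_state <- function(state, params, rate, dt) {
  stopifnot(inherits(state, "pk_state"),
            inherits(params, "individual_parameters"))
  if (dt < 0) stop("'dt' must be >= 0", call. = FALSE)
  if (rate < 0) stop("'rate' must be >= 0", call. = FALSE)
  a <- cpp_propagate(state$a1, state$a2, params$cl, params$v1, params$q,
                     params$v2, rate, dt)
  pk_state(a[1], a[2], state$t + dt)
}

#' Concentration of a state
#' @param state A [pk_state()].
#' @param params An [individual_parameters()].
#' @return Central concentration in ng/ml.
#' @export
concentration <- function(state, params) state$a1 / params$v1

#' Subject covariate/regimen profile
#'
#' Bundles the inputs needed to simulate one subject: body weight, the
#' piecewise-constant CYP3A4/5-inhibitor schedule, the infusion regimen
#' (possibly overlapping zero-order segments; overlaps superpose), and the
#' occasion boundaries that partition the record for the occasion-level
#' clearance effect. By default occasions are the 24-h infusion bags.
#'
#' @param id Subject identifier.
#' @param weight Total body weight (kg), > 0.
#' @param regimen `data.frame` with columns `start`, `duration` (h) and
#'   `rate` (ug/h); segments may overlap.
#' @param inhibitor_schedule `data.frame` with columns `time` (h) and `inh`
#'   (0/1); `inh` applies from `time` until the next entry. Default: never.
#' @param occasion_breaks Strictly increasing interior break points (h);
#'   occasion `j` covers `[breaks[j-1], breaks[j])` with an implicit 0 at the
#'   start. Default: every 24 h out to the end of the regimen.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(id, weight, regimen,
                            inhibitor_schedule = NULL,
                            occasion_breaks = NULL) {
  if (weight <= 0) stop("'weight' must be > 0", call. = FALSE)
  regimen <- as.data.frame(regimen)
  stopifnot(all(c("start", "duration", "rate") %in% names(regimen)))
  if (any(regimen$duration <= 0)) stop("durations must be > 0", call. = FALSE)
  if (any(regimen$rate < 0)) stop("rates must be >= 0", call. = FALSE)
  if (any(regimen$start < 0)) stop("start times must be >= 0", call. = FALSE)
  regimen <- regimen[order(regimen$start), , drop = FALSE]
  if (is.null(inhibitor_schedule))
    inhibitor_schedule <- data.frame(time = 0, inh = 0)
  inhibitor_schedule <- as.data.frame(inhibitor_schedule)
  stopifnot(all(c("time", "inh") %in% names(inhibitor_schedule)))
  end <- max(regimen$start + regimen$duration)
  if (is.null(occasion_breaks))
    occasion_breaks <- seq(24, by = 24,
                           length.out = max(1, ceiling(end / 24)))
  if (is.unsorted(occasion_breaks, strictly = TRUE))
    stop("'occasion_breaks' must be strictly increasing", call. = FALSE)
  structure(list(id = id, weight = weight, regimen = regimen,
                 inhibitor_schedule = inhibitor_schedule,
                 occasion_breaks = occasion_breaks),
            class = "subject_profile")
}

# occasion index (1-based) of time points, given interior breaks
occasion_of <- function(t, breaks) findInterval(t, breaks) + 1L

# 0/1 inhibitor status at time points from a step schedule
inhibitor_at <- function(t, schedule) {
  i <- findInterval(t, schedule$time)
  ifelse(i == 0, 0, schedule$inh[pmax(i, 1L)])
}

#' Simulate a noise-free concentration profile
#'
#' Chains the closed-form propagation across infusion-segment, occasion and
#' inhibitor-status boundaries and returns the individual-predicted (IPRED)
#' concentrations at the requested times. Overlapping infusion segments
#' superpose (the system is linear). Times before the first dose yield 0.
#'
#' @param subject A [subject_profile()].
#' @param pop A [pop_parameters()].
#' @param times Non-decreasing sampling times (h).
#' @param eta_cl,eta_v1 Subject-level random effects (log scale).
#' @param kappa Occasion-level effects: either a single value applied to all
#'   occasions or a vector indexed by occasion number (recycled with 0 for
#'   occasions beyond its length).
#' @return Numeric vector of concentrations (ng/ml) at `times`.
#' @examples
#' sub <- subject_profile("a", 70,
#'                        data.frame(start = 0, duration = 480, rate = 35.7))
#' simulate_profile(sub, pop_parameters(), times = c(24, 240, 480))
#' @export
simulate_profile <- function(subject, pop, times, eta_cl = 0, eta_v1 = 0,
                             kappa = 0) {
  stopifnot(inherits(subject, "subject_profile"),
            inherits(pop, "pop_parameters"))
  if (length(times) == 0) return(numeric(0))
  if (is.unsorted(times)) stop("'times' must be non-decreasing", call. = FALSE)
  if (any(times < 0)) stop("'times' must be >= 0", call. = FALSE)
  reg <- subject$regimen
  kap_of <- function(j) {
    if (length(kappa) == 1L) return(rep(kappa, length(j)))
    out <- rep(0, length(j))
    ok <- j <= length(kappa)
    out[ok] <- kappa[j[ok]]
    out
  }
  tmax <- max(times)
  knots <- sort(unique(c(0, reg$start, reg$start + reg$duration,
                         subject$occasion_breaks,
                         subject$inhibitor_schedule$time, times)))
  knots <- knots[knots <= tmax]
  v1 <- pop$theta_v1 * (subject$weight / pop$ref_weight)^pop$exp_v *
    exp(eta_v1)
  v2 <- v1 * pop$fact
  wcl <- pop$theta_cl * (subject$weight / pop$ref_weight)^pop$exp_cl *
    exp(eta_cl)
  a1 <- 0; a2 <- 0
  conc_at <- setNames(rep(0, length(knots)), NULL)
  conc_at[1] <- a1 / v1
  if (length(knots) > 1) {
    for (k in seq_len(length(knots) - 1L)) {
      t0 <- knots[k]; t1 <- knots[k + 1L]; tm <- (t0 + t1) / 2
      rate <- sum(reg$rate[reg$start <= t0 + 1e-12 &
                             reg$start + reg$duration >= t1 - 1e-12])
      j <- occasion_of(tm, subject$occasion_breaks)
      inh <- inhibitor_at(tm, subject$inhibitor_schedule)
      cl <- wcl * pop$theta_inh^inh * exp(kap_of(j))
      a <- cpp_propagate(a1, a2, cl, v1, cl * pop$fact, v2, rate, t1 - t0)
      a1 <- a[1]; a2 <- a[2]
      conc_at[k + 1L] <- a1 / v1
    }
  }
  conc_at[match(times, knots)]
}

#' Apply proportional residual error
#'
#' Observed concentration `DV = ipred * (1 + eps)` with
#' `eps ~ Normal(0, sigma_prop^2)`; draws are floored at 0 (negative
#' concentrations cannot be observed). Uses R's global random number stream.
#'
#' @param ipred Noise-free concentrations (ng/ml), >= 0.
#' @param sigma_prop Proportional residual SD (fraction), >= 0.
#' @return Vector of observed concentrations.
#' @export
apply_residual_error <- function(ipred, sigma_prop) {
  if (any(ipred < 0)) stop("'ipred' must be >= 0", call. = FALSE)
  if (sigma_prop < 0) stop("'sigma_prop' must be >= 0", call. = FALSE)
  pmax(0, ipred * (1 + rnorm(length(ipred), 0, sigma_prop)))
}
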