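#' Design of a synthetic continuous-infusion trough-monitoring trial
#'
#' Describes the virtual study that the generator emulates: a cohort of
#' pediatric/young-adult HCT patients started on weight-based continuous IV
#' tacrolimus (1.25 ug/kg/h), with a steady-state trough drawn 15 min before
#' each next 24-h bag, daily titration toward the 7-10 ng/ml window, and a
#' fraction of samples taken under CYP3A4/5-inhibitor (azole) co-treatment.
#' Defaults reproduce the published study design: 111 subjects, weights with
#' median 23.9 kg spanning 5.5-155.5 kg, 14 monitored days, and 11.7% of
#' observations under inhibitor.
#'
#' Weights are drawn from a truncated log-normal (median at `weight_median`,
#' `weight_sdlog` chosen so that a cohort of ~111 spans the published range);
#' inhibitor co-treatment is assigned as a subject-level contiguous block of
#' `inhibitor_block_days` days, with the subject-level probability set so
#' that the expected fraction of observation records under inhibitor equals
#' `inhibitor_sample_fraction`.
#'
#' @param n_subjects Number of subjects.
#' @param weight_median,weight_min,weight_max Weight distribution (kg).
#' @param weight_sdlog Log-scale SD of the weight distribution.
#' @param start_rate_per_kg Starting infusion rate (ug/kg/h).
#' @param start_policy `"per_kg"` for fixed weight-based starts, or
#'   `"model_typical"` for a model-based start targeting the window midpoint
#'   with the typical clearance for the subject's weight.
#' @param target_low,target_high Trough target window (ng/ml).
#' @param n_days Monitored days (one 24-h bag and one trough per day).
#' @param inhibitor_sample_fraction Expected fraction of observation rows
#'   with `INH = 1`.
#' @param inhibitor_block_days Length (days) of a subject's inhibitor course.
#' @param titrate Apply the daily titration rule (see Details).
#' @param dropout_rate Per-day probability of ending monitoring early, applied
#'   from day `dropout_from` on (0 disables censoring).
#' @param dropout_from First day eligible for dropout.
#' @param seed Optional RNG seed used by [simulate_cohort()].
#' @details The titration rule (a stand-in for the clinical protocol, whose
#'   adjustment formula is not published): if a trough falls outside the
#'   target window, the next bag's rate is `old_rate * midpoint / trough`,
#'   limited to a +/-50% change per day, with a floor of 0.1 ug/kg/h.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_subjects = 111, weight_median = 23.9,
                          weight_min = 5.5, weight_max = 155.5,
                          weight_sdlog = 0.64, start_rate_per_kg = 1.25,
                          start_policy = c("per_kg", "model_typical"),
                          target_low = 7, target_high = 10, n_days = 14,
                          inhibitor_sample_fraction = 0.117,
                          inhibitor_block_days = 7, titrate = TRUE,
                          dropout_rate = 0, dropout_from = 10, seed = NULL) {
  start_policy <- match.arg(start_policy)
  if (n_subjects < 1) stop("'n_subjects' must be >= 1", call. = FALSE)
  if (!(weight_min < weight_median && weight_median < weight_max))
    stop("need weight_min < weight_median < weight_max", call. = FALSE)
  if (!(target_low < target_high))
    stop("need target_low < target_high", call. = FALSE)
  if (n_days < 1) stop("'n_days' must be >= 1", call. = FALSE)
  if (inhibitor_sample_fraction < 0 || inhibitor_sample_fraction > 1)
    stop("'inhibitor_sample_fraction' must be in [0, 1]", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 weight_median = weight_median, weight_min = weight_min,
                 weight_max = weight_max, weight_sdlog = weight_sdlog,
                 start_rate_per_kg = start_rate_per_kg,
                 start_policy = start_policy,
                 target_low = target_low, target_high = target_high,
                 n_days = as.integer(n_days),
                 inhibitor_sample_fraction = inhibitor_sample_fraction,
                 inhibitor_block_days = as.integer(inhibitor_block_days),
                 titrate = titrate, dropout_rate = dropout_rate,
                 dropout_from = as.integer(dropout_from), seed = seed),
            class = "cohort_design")
}

#' Draw subject covariate profiles for a trial design
#'
#' Per subject, in a fixed draw order (weight; inhibitor indicator; block
#' start): the weight comes from the truncated log-normal of the design via
#' inverse-CDF sampling, and the inhibitor course is a contiguous block of
#' days assigned with probability
#' `inhibitor_sample_fraction * n_days / block_days`.
#'
#' @param design A [cohort_design()].
#' @param pop A [pop_parameters()] object; only used by the
#'   `"model_typical"` start policy (typical no-inhibitor clearance at the
#'   subject's weight).
#' @return List of [subject_profile()] objects; each carries the per-day
#'   starting regimen placeholder (day-1 bag at the design's starting rate;
#'   [simulate_trial()] rewrites the regimen as titration proceeds) and the
#'   inhibitor schedule.
#' @export
sample_subjects <- function(design, pop = pop_parameters()) {
  stopifnot(inherits(design, "cohort_design"))
  d <- design
  plo <- plnorm(d$weight_min, log(d$weight_median), d$weight_sdlog)
  phi <- plnorm(d$weight_max, log(d$weight_median), d$weight_sdlog)
  block <- min(d$inhibitor_block_days, d$n_days)
  p_sub <- min(1, d$inhibitor_sample_fraction * d$n_days / block)
  lapply(seq_len(d$n_subjects), function(i) {
    w <- qlnorm(plo + runif(1) * (phi - plo), log(d$weight_median),
                d$weight_sdlog)
    on_inh <- runif(1) < p_sub
    sched <- data.frame(time = 0, inh = 0)
    if (on_inh) {
      first <- 1L + as.integer(floor(runif(1) * (d$n_days - block + 1L)))
      sched <- data.frame(time = c(0, 24 * (first - 1L), 24 * (first - 1L + block)),
                          inh = c(0, 1, 0))
      if (first == 1L) sched <- sched[-1, ]
    } else {
      runif(1) # keep the draw count per subject fixed
    }
    rate0 <- switch(d$start_policy,
                    per_kg = d$start_rate_per_kg * w,
                    model_typical = (d$target_low + d$target_high) / 2 *
                      pop$theta_cl * (w / pop$ref_weight)^pop$exp_cl)
    subject_profile(id = sprintf("S%03d", i), weight = w,
                    regimen = data.frame(start = 0, duration = 24,
                                         rate = rate0),
                    inhibitor_schedule = sched,
                    occasion_breaks = seq(24, by = 24, length.out = d$n_days))
  })
}

#' Simulate a monitored trial into an event dataset
#'
#' For each subject draws `eta_cl`, `eta_v1` once and one `kappa` per 24-h
#' occasion, runs the daily bag/trough/titration cycle, and records dose
#' (`EVID = 1`) and observation (`EVID = 0`) rows in the NONMEM-like dialect
#' (see [read_pk_dataset()]). Troughs are drawn 15 min before the next bag
#' (`TIME = 24k - 0.25`), with proportional residual error on `DV`. The
#' per-subject random draw order is fixed (eta_cl, eta_v1, kappa_1..K,
#' eps_1..K, dropout u_1..K) so runs are reproducible under a fixed seed.
#'
#' @param subjects List of [subject_profile()]s from [sample_subjects()].
#' @param pop A [pop_parameters()] ground truth.
#' @param design The [cohort_design()].
#' @return A `pk_dataset` event table (`data.frame`). The generating
#'   (latent) random effects are attached as attribute `"latent"`: a list
#'   with `effects` (`data.frame` of `ID`, `weight`, `eta_cl`, `eta_v1`)
#'   and `kappa` (per-subject vectors of occasion effects) — useful for
#'   parameter-recovery studies.
#' @export
simulate_trial <- function(subjects, pop, design) {
  stopifnot(length(subjects) >= 1, inherits(pop, "pop_parameters"),
            inherits(design, "cohort_design"))
  d <- design
  mid <- (d$target_low + d$target_high) / 2
  out <- vector("list", length(subjects))
  lat_eta <- matrix(NA_real_, length(subjects), 2)
  lat_kap <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    w <- s$weight
    eta_cl <- rnorm(1, 0, pop$omega_cl)
    eta_v1 <- rnorm(1, 0, pop$omega_v1)
    kap <- rnorm(d$n_days, 0, pop$pi_cl)
    eps <- rnorm(d$n_days, 0, pop$sigma_prop)
    udrop <- runif(d$n_days)
    v1 <- pop$theta_v1 * (w / pop$ref_weight)^pop$exp_v * exp(eta_v1)
    v2 <- v1 * pop$fact
    wcl <- pop$theta_cl * (w / pop$ref_weight)^pop$exp_cl * exp(eta_cl)
    rate <- s$regimen$rate[1]
    a1 <- 0; a2 <- 0
    rows <- vector("list", 2L * d$n_days)
    for (k in seq_len(d$n_days)) {
      t0 <- 24 * (k - 1)
      inh <- inhibitor_at(t0 + 12, s$inhibitor_schedule)
      cl <- wcl * pop$theta_inh^inh * exp(kap[k])
      rows[[2L * k - 1L]] <- data.frame(
        ID = s$id, TIME = t0, EVID = 1L, AMT = rate * 24, RATE = rate,
        DV = NA_real_, MDV = 1L, WT = w, INH = inh, OCC = k)
      a <- cpp_propagate(a1, a2, cl, v1, cl * pop$fact, v2, rate, 23.75)
      a1 <- a[1]; a2 <- a[2]
      ipred <- a1 / v1
      dv <- max(0, ipred * (1 + eps[k]))
      rows[[2L * k]] <- data.frame(
        ID = s$id, TIME = t0 + 23.75, EVID = 0L, AMT = NA_real_,
        RATE = NA_real_, DV = dv, MDV = 0L, WT = w, INH = inh, OCC = k)
      a <- cpp_propagate(a1, a2, cl, v1, cl * pop$fact, v2, rate, 0.25)
      a1 <- a[1]; a2 <- a[2]
      if (d$titrate && (dv < d$target_low || dv > d$target_high) && dv > 0) {
        new_rate <- rate * mid / dv
        new_rate <- min(max(new_rate, 0.5 * rate), 1.5 * rate)
        rate <- max(new_rate, 0.1 * w)
      }
      if (d$dropout_rate > 0 && k >= d$dropout_from &&
          udrop[k] < d$dropout_rate) {
        rows <- rows[seq_len(2L * k)]
        break
      }
    }
    out[[i]] <- do.call(rbind, rows)
    lat_eta[i, ] <- c(eta_cl, eta_v1)
    lat_kap[[i]] <- kap
  }
  ds <- do.call(rbind, out)
  rownames(ds) <- NULL
  ids <- vapply(subjects, `[[`, "", "id")
  attr(ds, "latent") <- list(
    effects = data.frame(ID = ids,
                         weight = vapply(subjects, `[[`, 0, "weight"),
                         eta_cl = lat_eta[, 1], eta_v1 = lat_eta[, 2]),
    kappa = setNames(lat_kap, ids))
  class(ds) <- c("pk_dataset", "data.frame")
  ds
}

#' Generate a full synthetic cohort dataset
#'
#' Convenience wrapper: seeds the RNG (if the design carries a seed), draws
#' subjects and simulates the trial.
#'
#' @param design A [cohort_design()].
#' @param pop A [pop_parameters()] ground truth.
#' @return A `pk_dataset` event table.
#' @examples
#' ds <- simulate_cohort(cohort_design(n_subjects = 3, n_days = 2, seed = 1),
#'                       pop_parameters())
#' head(ds)
#' @export
simulate_cohort <- function(design, pop = pop_parameters()) {
  if (!is.null(design$seed)) set.seed(design$seed)
  simulate_trial(sample_subjects(design, pop), pop, design)
}
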