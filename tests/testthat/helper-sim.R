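# dataset-row builders used across tests

# one subject on daily 24-h bags with troughs 15 min before each next bag;
# dv defaults to the model's noise-free prediction at the given effects
mk_subject <- function(id = "S1", weight = 70, rates, pop = pop_parameters(),
                       inh = 0, eta_cl = 0, eta_v1 = 0, kappa = 0,
                       obs_times = NULL, dv = NULL) {
  n_days <- length(rates)
  inh <- rep(inh, length.out = n_days)
  dose <- data.frame(ID = id, TIME = 24 * (seq_len(n_days) - 1), EVID = 1L,
                     AMT = rates * 24, RATE = rates, DV = NA_real_, MDV = 1L,
                     WT = weight, INH = inh, OCC = seq_len(n_days))
  if (is.null(obs_times)) obs_times <- 24 * seq_len(n_days) - 0.25
  occ <- pmin(floor(obs_times / 24) + 1L, n_days)
  if (is.null(dv)) {
    sub <- subject_profile(id, weight,
                           data.frame(start = dose$TIME, duration = 24,
                                      rate = rates),
                           inhibitor_schedule = data.frame(
                             time = dose$TIME, inh = inh),
                           occasion_breaks = 24 * seq_len(n_days))
    dv <- simulate_profile(sub, pop, obs_times, eta_cl, eta_v1, kappa)
  }
  obs <- data.frame(ID = id, TIME = obs_times, EVID = 0L, AMT = NA_real_,
                    RATE = NA_real_, DV = dv, MDV = 0L, WT = weight,
                    INH = inh[occ], OCC = occ)
  ds <- rbind(dose, obs)
  ds <- ds[order(ds$TIME, -ds$EVID), ]
  rownames(ds) <- NULL
  validate_pk_dataset(ds)
}

# population with all variability switched off (deterministic model)
pop_novar <- function(..., sigma_prop = 0) {
  pop_parameters(omega_cl = 0, omega_v1 = 0, pi_cl = 0,
                 sigma_prop = sigma_prop, ...)
}
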