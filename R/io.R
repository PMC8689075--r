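#' Read / write / validate longitudinal PK event datasets
#'
#' The dataset dialect follows the NONMEM convention: one row per event,
#' with columns `ID` (subject), `TIME` (h from the subject's first dose),
#' `EVID` (0 = observation, 1 = infusion/dose record), `AMT` (ug; dose rows;
#' `AMT = RATE * duration`), `RATE` (ug/h; dose rows), `DV` (ng/ml;
#' observation rows), `MDV` (1 on dose rows), `WT` (kg), `INH` (0/1
#' CYP3A4/5-inhibitor status) and `OCC` (1-based occasion index). Extra
#' columns are preserved and ignored by the core (they can serve as
#' covariate candidates in [covariate_step()]).
#'
#' @param path File path of a CSV in the dialect above.
#' @return `read_pk_dataset()` returns a validated `pk_dataset`
#'   (`data.frame`); `write_pk_dataset()` writes CSV and returns the path
#'   invisibly; a write-then-read round trip is lossless.
#' @export
read_pk_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ds <- read.csv(path, stringsAsFactors = FALSE)
  validate_pk_dataset(ds)
}

#' @rdname read_pk_dataset
#' @param dataset A `pk_dataset` (or compatible `data.frame`).
#' @export
write_pk_dataset <- function(dataset, path) {
  validate_pk_dataset(dataset)
  write.csv(dataset, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname read_pk_dataset
#' @export
validate_pk_dataset <- function(dataset) {
  req <- c("ID", "TIME", "EVID", "AMT", "RATE", "DV", "MDV", "WT", "INH",
           "OCC")
  miss <- setdiff(req, names(dataset))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ds <- as.data.frame(dataset)
  if (any(ds$TIME < 0))
    stop("negative TIME at row ", which(ds$TIME < 0)[1], call. = FALSE)
  for (id in unique(ds$ID)) {
    sub <- ds[ds$ID == id, ]
    if (is.unsorted(sub$TIME))
      stop("TIME not non-decreasing within subject ", id, call. = FALSE)
    if (is.unsorted(sub$OCC))
      stop("OCC not non-decreasing within subject ", id, call. = FALSE)
  }
  dose <- ds$EVID == 1
  if (any(dose & !(is.na(ds$RATE) | ds$RATE > 0))) {
    bad <- which(dose & ds$RATE <= 0)[1]
    stop("dose row with RATE <= 0 at row ", bad, call. = FALSE)
  }
  if (any(dose & is.na(ds$RATE)))
    stop("dose row with missing RATE at row ",
         which(dose & is.na(ds$RATE))[1], call. = FALSE)
  if (any(dose & !is.na(ds$DV)))
    stop("DV present on dose row ", which(dose & !is.na(ds$DV))[1],
         call. = FALSE)
  obs <- ds$EVID == 0
  if (any(obs & (is.na(ds$DV) | ds$DV < 0)))
    stop("observation row with missing or negative DV at row ",
         which(obs & (is.na(ds$DV) | ds$DV < 0))[1], call. = FALSE)
  class(ds) <- c("pk_dataset", "data.frame")
  ds
}

#' @export
print.pk_dataset <- function(x, ...) {
  n_obs <- sum(x$EVID == 0)
  cat(sprintf("PK event dataset: %d subjects, %d rows (%d observations)\n",
              length(unique(x$ID)), nrow(x), n_obs))
  NextMethod()
}

# ---- internal: estimation grid -------------------------------------------
#
# Partition one subject's record into intervals of constant rate, occasion
# and covariate status; observations fall on interval ends. `covariates` is
# a named character vector column -> "binary"/"continuous" describing extra
# clearance covariates beyond INH (whose coefficient is log(theta_inh)).
# `effects` switches eta_cl / eta_v1 / kappa on or off; `kappa_all = TRUE`
# assigns a kappa to every occasion in the record (used for simulation),
# otherwise only occasions holding observations carry one (estimation).
build_subject_grid <- function(sub, covariates = character(),
                               effects = c(eta_cl = TRUE, eta_v1 = TRUE,
                                           kappa = TRUE),
                               kappa_all = FALSE, t_end = NULL,
                               cov_ref = NULL) {
  sub <- as.data.frame(sub)
  sub <- sub[order(sub$TIME, -sub$EVID), , drop = FALSE]
  doses <- sub[sub$EVID == 1, , drop = FALSE]
  obs <- sub[sub$EVID == 0, , drop = FALSE]
  if (is.null(t_end))
    t_end <- if (nrow(obs)) max(obs$TIME) else max(sub$TIME)
  dur <- if (nrow(doses)) doses$AMT / doses$RATE else numeric(0)
  step_cols <- c("OCC", "INH", names(covariates))
  knots <- sort(unique(c(0, doses$TIME, doses$TIME + dur, obs$TIME,
                         sub$TIME)))
  knots <- knots[knots <= t_end + 1e-9]
  if (max(knots) < t_end - 1e-9) knots <- c(knots, t_end)
  n_int <- length(knots) - 1L
  step_at <- function(col, t) {
    i <- findInterval(t, sub$TIME)
    v <- sub[[col]][pmax(i, 1L)]
    v[i == 0] <- sub[[col]][1L]
    v
  }
  tm <- (knots[-1] + knots[-length(knots)]) / 2
  occ <- step_at("OCC", tm)
  rate <- vapply(seq_len(n_int), function(k) {
    t0 <- knots[k]; t1 <- knots[k + 1L]
    act <- doses$TIME <= t0 + 1e-9 & doses$TIME + dur >= t1 - 1e-9
    sum(doses$RATE[act])
  }, numeric(1))
  # covariate matrix: INH first, then extras
  z <- matrix(0, n_int, 1L + length(covariates))
  z[, 1L] <- step_at("INH", tm)
  if (length(covariates)) {
    for (j in seq_along(covariates)) {
      col <- names(covariates)[j]
      v <- step_at(col, tm)
      if (covariates[[j]] == "continuous") {
        ref <- if (!is.null(cov_ref) && col %in% names(cov_ref))
          cov_ref[[col]] else stats::median(sub[[col]])
        v <- log(v / ref)
      }
      z[, j + 1L] <- v
    }
  }
  # kappa indices per interval (0-based into the kappa block of b)
  use_kappa <- isTRUE(effects[["kappa"]])
  occ_obs <- if (use_kappa) {
    if (kappa_all) unique(occ) else unique(step_at("OCC", obs$TIME))
  } else integer(0)
  kidx <- match(occ, occ_obs) - 1L
  kidx[is.na(kidx)] <- -1L
  # map observations to the interval ending at their time (-1: before start)
  obs_int <- match(obs$TIME, knots) - 2L
  obs_int[is.na(obs_int)] <- -1L
  ord <- order(obs_int)
  keep <- n_int > 0
  list(dt = if (keep) diff(knots) else numeric(0),
       rate = if (keep) rate else numeric(0),
       dv = obs$DV[ord],
       z = z, kidx = as.integer(kidx),
       obs_int = as.integer(obs_int[ord]),
       weight = sub$WT[1L],
       has_eta_cl = as.integer(isTRUE(effects[["eta_cl"]])),
       has_eta_v1 = as.integer(isTRUE(effects[["eta_v1"]])),
       n_kappa = length(occ_obs),
       id = sub$ID[1L], occ_labels = occ_obs, obs_time = obs$TIME[ord])
}
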