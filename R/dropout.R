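# Monotone MAR dropout: six propensity mechanisms, each calibrated by a
# scenario-level cutoff so the endpoint missingness hits a target rate.

#' Dropout mechanism specification
#'
#' Six missing-at-random mechanisms acting on the previous visit's outcome
#' (and, for model 6, the current visit's adverse-event status):
#' \describe{
#'   \item{1}{lack of efficacy: \eqn{P(Z_{ij}=0) \propto 1 - \Phi(Y_{j-1})}.}
#'   \item{2}{differing mechanism by arm: arm A drops when low
#'     (\eqn{1-\Phi}), arm B when high (\eqn{\Phi}).}
#'   \item{3}{model 2 with the arms reversed.}
#'   \item{4}{differential rates: model 1 weighted by `weight_A` (default
#'     0.3) in arm A and `weight_B` (default 1) in arm B.}
#'   \item{5}{logistic lack of efficacy:
#'     \eqn{1 / (1 + \exp(b_1 Y_{j-1}))}, `b1` = 0.01.}
#'   \item{6}{efficacy and tolerability:
#'     \eqn{1 / (1 + \exp(b_1 Y_{j-1} + b_2 AE_j))}, `b2` = -0.40.}
#' }
#' \eqn{\Phi} is the normal CDF with mean and SD estimated from the at-risk
#' subjects' \eqn{Y_{j-1}}, pooled over arms, per dataset.
#'
#' @param model_id integer 1..6.
#' @param target_rate desired proportion of subjects missing at the endpoint
#'   (visit 4), in (0, 1).
#' @param weight_A,weight_B arm multipliers for model 4.
#' @param b1,b2 logistic coefficients for models 5-6.
#' @param tolerance calibration tolerance on the achieved rate.
#' @param pilot_reps number of pilot datasets used to calibrate the cutoff.
#' @export
dropout_spec <- function(model_id, target_rate = 0.30,
                         weight_A = 0.3, weight_B = 1,
                         b1 = 0.01, b2 = -0.40,
                         tolerance = 0.005, pilot_reps = 200L) {
  model_id <- as.integer(model_id)
  if (!model_id %in% 1:6) stop("model_id must be 1..6", call. = FALSE)
  if (target_rate < 0 || target_rate >= 1) {
    stop("target_rate must lie in [0, 1)", call. = FALSE)
  }
  if (weight_A <= 0 || weight_B <= 0) {
    stop("arm weights must be positive", call. = FALSE)
  }
  structure(list(model_id = model_id, target_rate = target_rate,
                 weight_A = weight_A, weight_B = weight_B,
                 b1 = b1, b2 = b2, tolerance = tolerance,
                 pilot_reps = as.integer(pilot_reps)),
            class = "dropout_spec")
}

#' Per-subject dropout propensity at one visit
#'
#' Computes the (unnormalized) dropout propensity at visit `j` for the
#' subjects in `at_risk`, using only data observed before the visit (plus
#' the current AE status for model 6) -- the mechanism is MAR by
#' construction.
#'
#' @param data a `trial_data` (complete).
#' @param j visit, 2..4.
#' @param spec a [dropout_spec()].
#' @param at_risk logical vector: subjects still observed at `j - 1`.
#' @return numeric vector of propensities, one per at-risk subject, in
#'   `[0, 1]` up to the arm weight.
#' @export
propensity <- function(data, j, spec, at_risk = rep(TRUE, nrow(data))) {
  stopifnot(inherits(spec, "dropout_spec"))
  if (j < 2L || j > 4L) stop("propensities are defined for j in 2..4",
                             call. = FALSE)
  yprev <- data[[paste0("Y", j - 1L)]][at_risk]
  arm <- data$arm[at_risk]
  if (anyNA(yprev)) stop("Y at j-1 must be observed for at-risk subjects",
                         call. = FALSE)
  m <- spec$model_id
  if (m %in% 1:4) {
    phi <- stats::pnorm(yprev, mean(yprev), stats::sd(yprev))
    switch(m,
      `1` = 1 - phi,
      `2` = ifelse(arm == 1L, 1 - phi, phi),
      `3` = ifelse(arm == 1L, phi, 1 - phi),
      `4` = ifelse(arm == 1L, spec$weight_A, spec$weight_B) * (1 - phi))
  } else if (m == 5L) {
    stats::plogis(-spec$b1 * yprev)
  } else {
    aej <- data[[paste0("AE", j)]]
    if (is.null(aej)) {
      stop("dropout model 6 requires AE columns (run generate_ae first)",
           call. = FALSE)
    }
    stats::plogis(-(spec$b1 * yprev + spec$b2 * aej[at_risk]))
  }
}

# One sequential pass of the dropout process over visits 2..4 given a
# cutoff. U is an n x 3 matrix of uniforms. A subject at risk drops at
# visit j when propensity > cutoff * U, i.e. with realized probability
# min(1, propensity / cutoff) -- exactly proportional to the propensity,
# which is what the mechanism formulas state. Returns the integer first
# missing visit per subject (NA_integer_ = completer).
run_dropout_process <- function(data, spec, cutoff, U) {
  n <- nrow(data)
  dropout_time <- rep(NA_integer_, n)
  at_risk <- rep(TRUE, n)
  for (j in 2:4) {
    p <- propensity(data, j, spec, at_risk)
    newly <- which(at_risk)[p > cutoff * U[at_risk, j - 1L]]
    dropout_time[newly] <- j
    at_risk[newly] <- FALSE
  }
  dropout_time
}

#' Calibrate the scenario cutoff
#'
#' The mechanism compares each at-risk subject-visit's propensity against
#' `cutoff * Uniform(0,1)`: the subject drops at the first visit where the
#' propensity exceeds the scaled uniform, so the realized per-visit dropout
#' probability is `min(1, propensity / cutoff)` -- proportional to the
#' propensity, as the dropout-model formulas state. The cutoff is a
#' scenario-level constant found here by bisection so that the mean
#' endpoint missingness over pilot replicate datasets matches the target
#' rate. Pilot datasets and their uniforms are drawn once and reused across
#' bisection iterates (common random numbers), so the achieved rate is
#' monotone in the cutoff and the search is deterministic given the seed.
#'
#' @param make_data a function `(replicate_index) -> trial_data` producing
#'   pilot complete datasets.
#' @param spec a [dropout_spec()].
#' @param seed optional integer seed.
#' @return the calibrated cutoff (numeric scalar), with the achieved pilot
#'   rate attached as attribute `achieved`.
#' @export
calibrate_cutoff <- function(make_data, spec, seed = NULL) {
  stopifnot(inherits(spec, "dropout_spec"))
  if (spec$target_rate == 0) return(structure(1, achieved = 0))
  if (!is.null(seed)) set.seed(seed)
  reps <- spec$pilot_reps
  pilots <- vector("list", reps)
  for (r in seq_len(reps)) {
    d <- make_data(r)
    pilots[[r]] <- list(data = d,
                        U = matrix(stats::runif(3L * nrow(d)), ncol = 3L))
  }
  achieved <- function(cutoff) {
    miss <- vapply(pilots, function(p) {
      dt <- run_dropout_process(p$data, spec, cutoff, p$U)
      mean(!is.na(dt))
    }, numeric(1))
    mean(miss)
  }
  # achieved rate decreases in the cutoff: bracket from 0 (everyone drops)
  # upward, expanding the upper end until the target is straddled
  lo <- 0; hi <- 1
  a_lo <- achieved(lo)
  a_hi <- achieved(hi)
  while (a_hi > spec$target_rate && hi < 1e6) {
    hi <- hi * 2
    a_hi <- achieved(hi)
  }
  if (a_lo < spec$target_rate || a_hi > spec$target_rate) {
    stop(sprintf(
      "calibration failure: target %.3f outside achieved bracket [%.3f, %.3f]",
      spec$target_rate, a_hi, a_lo), call. = FALSE)
  }
  mid <- NA_real_; a_mid <- NA_real_
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    a_mid <- achieved(mid)
    if (abs(a_mid - spec$target_rate) <= spec$tolerance) break
    if (a_mid > spec$target_rate) lo <- mid else hi <- mid
  }
  if (abs(a_mid - spec$target_rate) > spec$tolerance) {
    stop(sprintf(
      "calibration failure: achieved %.4f vs target %.4f at tolerance %.4f",
      a_mid, spec$target_rate, spec$tolerance), call. = FALSE)
  }
  structure(mid, achieved = a_mid)
}

#' Impose monotone dropout on a complete dataset
#'
#' Runs the sequential dropout process (visits 2, 3, 4 in temporal order;
#' drop at the first visit where the propensity exceeds the cutoff times an
#' independent uniform, realizing a dropout probability proportional to the
#' propensity). Once a visit is missing all later visits are missing, and
#' the baseline is always observed.
#'
#' @param data a complete `trial_data`; for model 6 it must carry AE
#'   columns.
#' @param spec a [dropout_spec()].
#' @param cutoff the calibrated scenario cutoff from [calibrate_cutoff()].
#'   When `NULL`, a cutoff is calibrated on pilot replicates that resample
#'   rows of `data` (adequate for one-off use; scenario runners calibrate
#'   once and pass it in).
#' @param seed optional integer seed.
#' @return an object of class `dropout_mask`: list with `Z` (N x 4 0/1
#'   matrix, 0 = missing), `dropout_time` (first missing visit or `NA`),
#'   `achieved_rate` (fraction missing the endpoint), `cutoff`, `model_id`.
#' @export
apply_dropout <- function(data, spec, cutoff = NULL, seed = NULL) {
  stopifnot(inherits(spec, "dropout_spec"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cutoff)) {
    cutoff <- calibrate_cutoff(function(r) data, spec)
  }
  n <- nrow(data)
  if (spec$target_rate == 0) {
    dropout_time <- rep(NA_integer_, n)
  } else {
    U <- matrix(stats::runif(3L * n), ncol = 3L)
    dropout_time <- run_dropout_process(data, spec, cutoff, U)
  }
  Z <- matrix(1L, n, 4L)
  for (j in 2:4) Z[!is.na(dropout_time) & dropout_time <= j, j] <- 0L
  structure(list(Z = Z,
                 dropout_time = dropout_time,
                 achieved_rate = mean(Z[, 4L] == 0L),
                 cutoff = as.numeric(cutoff),
                 model_id = spec$model_id),
            class = "dropout_mask")
}

#' Apply a mask to a dataset
#'
#' Sets masked outcome cells to `NA`. For datasets carrying an AE series,
#' AE values after the dropout visit are masked as well (the subject has
#' left the study); the AE at the dropout visit itself remains observed, as
#' it informs the dropout decision under mechanism 6.
#'
#' @param data a `trial_data`.
#' @param mask a `dropout_mask` for the same dataset.
#' @return `data` with `NA` in masked cells.
#' @export
apply_mask <- function(data, mask) {
  stopifnot(inherits(mask, "dropout_mask"), nrow(data) == nrow(mask$Z))
  for (j in 2:4) {
    data[[paste0("Y", j)]][mask$Z[, j] == 0L] <- NA_real_
  }
  if (!is.null(data$AE2)) {
    dt <- mask$dropout_time
    for (j in 2:4) {
      gone <- !is.na(dt) & dt < j
      data[[paste0("AE", j)]][gone] <- NA_integer_
    }
  }
  data
}

#' Write a mask as 0/1 CSV
#'
#' One row per subject, columns `subject_id`, `Z1`..`Z4` (0 = missing).
#'
#' @param mask a `dropout_mask`.
#' @param path file path.
#' @export
write_mask_csv <- function(mask, path) {
  stopifnot(inherits(mask, "dropout_mask"))
  d <- data.frame(subject_id = seq_len(nrow(mask$Z)), mask$Z)
  names(d)[2:5] <- paste0("Z", 1:4)
  utils::write.csv(d, path, row.names = FALSE)
}

#' @export
print.dropout_mask <- function(x, ...) {
  cat(sprintf(
    "Monotone dropout mask: model %d, %d subjects, %.1f%% missing at visit 4 (cutoff %.4f)\n",
    x$model_id, nrow(x$Z), 100 * x$achieved_rate, x$cutoff))
  invisible(x)
}
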