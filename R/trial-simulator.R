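# Complete-data generation for a two-arm longitudinal trial with a
# dichotomized continuous endpoint.

#' Built-in response profiles
#'
#' Mean trajectories over four timepoints for treatment arm A and B. Four
#' profiles are available: `"linear"` (arm A improves linearly, B is flat),
#' `"nonlinear"` (trajectories cross but arms end 6 points apart), and two
#' null profiles with no arm difference at the final timepoint, used for
#' type I error assessment.
#'
#' @param name one of `"linear"`, `"nonlinear"`, `"null1"`, `"null2"`, or
#'   `"custom"` (requires `mu_A` and `mu_B`).
#' @param mu_A,mu_B length-4 mean vectors, only used with `name = "custom"`.
#' @return an object of class `response_profile` with fields `name`, `mu_A`,
#'   `mu_B`.
#' @examples
#' response_profile("linear")
#' @export
response_profile <- function(name = c("linear", "nonlinear", "null1", "null2",
                                      "custom"),
                             mu_A = NULL, mu_B = NULL) {
  name <- match.arg(name)
  means <- switch(name,
    linear    = list(mu_A = c(65, 67, 69, 71), mu_B = c(65, 65, 65, 65)),
    nonlinear = list(mu_A = c(65, 63, 68, 71), mu_B = c(65, 67, 66, 65)),
    null1     = list(mu_A = c(65, 65, 65, 65), mu_B = c(65, 65, 65, 65)),
    null2     = list(mu_A = c(65, 67, 69, 71), mu_B = c(65, 63, 68, 71)),
    custom    = list(mu_A = mu_A, mu_B = mu_B)
  )
  if (length(means$mu_A) != 4L || length(means$mu_B) != 4L) {
    stop("profile mean vectors must have length 4", call. = FALSE)
  }
  if (means$mu_A[1L] != means$mu_B[1L]) {
    stop("both arms must share the baseline mean (randomization)",
         call. = FALSE)
  }
  structure(list(name = name,
                 mu_A = as.numeric(means$mu_A),
                 mu_B = as.numeric(means$mu_B)),
            class = "response_profile")
}

#' Variance components of the random-intercept outcome model
#'
#' The outcome model is \eqn{Y_{ij} = \mu_{arm,j} + b_i + \epsilon_{ij}} with
#' \eqn{b_i \sim N(0, \sigma_b^2)} and \eqn{\epsilon_{ij} \sim N(0,
#' \sigma_\epsilon^2)}, i.e. a compound-symmetric covariance with
#' within-person correlation \eqn{\sigma_b^2 / (\sigma_b^2 +
#' \sigma_\epsilon^2)}. Defaults (\eqn{\sigma_b = 12}, \eqn{\sigma_\epsilon =
#' 7}) give correlation 0.75, typical of patient-reported outcome scales.
#'
#' @param sigma_b between-subject SD (outcome units), > 0.
#' @param sigma_eps within-subject SD (outcome units), > 0.
#' @return object of class `variance_components`.
#' @export
variance_components <- function(sigma_b = 12, sigma_eps = 7) {
  if (!is.numeric(sigma_b) || !is.numeric(sigma_eps) ||
      sigma_b < 0 || sigma_eps <= 0) {
    stop("variance components must be positive (sigma_b may be 0 only in ",
         "degenerate test settings)", call. = FALSE)
  }
  structure(list(sigma_b = sigma_b, sigma_eps = sigma_eps),
            class = "variance_components")
}

#' Responder rule: dichotomization of change from baseline
#'
#' A subject responds when the change from baseline to the endpoint visit
#' reaches the threshold: \eqn{R_i = I(Y_{i,end} - Y_{i,base} \ge \lambda)}.
#' The default threshold 12.4 gives approximately 80% power at N = 200 under
#' the linear profile.
#'
#' @param lambda change-from-baseline threshold (outcome units).
#' @param baseline_index,endpoint_index timepoints used for the change score.
#' @export
responder_rule <- function(lambda = 12.4, baseline_index = 1L,
                           endpoint_index = 4L) {
  baseline_index <- as.integer(baseline_index)
  endpoint_index <- as.integer(endpoint_index)
  if (endpoint_index <= baseline_index) {
    stop("endpoint_index must be after baseline_index", call. = FALSE)
  }
  structure(list(lambda = lambda, baseline_index = baseline_index,
                 endpoint_index = endpoint_index),
            class = "responder_rule")
}

#' Adverse-event process model
#'
#' Two-state first-order process: no AEs at baseline; initial AE probability
#' at visit 2 per arm; conditional probabilities
#' \eqn{P(AE_j = 1 \mid AE_{j-1} = \gamma, arm)} for visits 3 and 4. The
#' default table mirrors event rates observed in actual trial data.
#'
#' @param p_init_A,p_init_B probability of an AE at visit 2 in arm A / arm B.
#' @param conditional_table data.frame with columns `timepoint` (3 or 4),
#'   `arm` (1 = A, 0 = B), `gamma` (AE status at the previous visit) and
#'   `prob`; all 8 cells must be present.
#' @export
ae_model <- function(p_init_A = 0.3, p_init_B = 0.5,
                     conditional_table = default_ae_table()) {
  tab <- conditional_table
  need <- c("timepoint", "arm", "gamma", "prob")
  if (!is.data.frame(tab) || !all(need %in% names(tab))) {
    stop("conditional_table needs columns timepoint, arm, gamma, prob",
         call. = FALSE)
  }
  cells <- expand.grid(timepoint = c(3L, 4L), arm = c(0L, 1L),
                       gamma = c(0L, 1L))
  key <- function(d) paste(d$timepoint, d$arm, d$gamma)
  if (!all(key(cells) %in% key(tab))) {
    stop("conditional_table must cover all 8 (timepoint, arm, gamma) cells",
         call. = FALSE)
  }
  probs <- c(p_init_A, p_init_B, tab$prob)
  if (any(probs < 0 | probs > 1)) {
    stop("AE probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(p_init_A = p_init_A, p_init_B = p_init_B,
                 conditional_table = tab),
            class = "ae_model")
}

#' @rdname ae_model
#' @export
default_ae_table <- function() {
  data.frame(
    timepoint = rep(c(3L, 4L), each = 4L),
    arm       = rep(c(1L, 1L, 0L, 0L), 2L),
    gamma     = rep(c(0L, 1L), 4L),
    prob      = c(0.2, 0.8, 0.4, 0.8,   # visit 3
                  0.1, 0.8, 0.2, 0.8)   # visit 4
  )
}

#' Simulate a complete two-arm trial
#'
#' Draws `n` subjects (equal allocation, first half arm A) from the
#' random-intercept model: `Y[i, j] = mu[arm, j] + b_i + eps_ij`.
#'
#' @param profile a [response_profile()].
#' @param n total number of subjects, even, >= 4. Default 200.
#' @param var a [variance_components()].
#' @param seed optional integer seed; when supplied the simulation is
#'   bitwise reproducible.
#' @return a `data.frame` of class `trial_data` with columns `subject_id`,
#'   `arm` (1 = A, 0 = B), `Y1`..`Y4`.
#' @examples
#' d <- simulate_trial(response_profile("linear"), n = 200, seed = 1)
#' colMeans(d[d$arm == 1, c("Y1", "Y2", "Y3", "Y4")])
#' @export
simulate_trial <- function(profile, n = 200L, var = variance_components(),
                           seed = NULL) {
  stopifnot(inherits(profile, "response_profile"),
            inherits(var, "variance_components"))
  n <- as.integer(n)
  if (n < 4L || n %% 2L != 0L) {
    stop("n must be an even subject count >= 4 (equal allocation)",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  arm <- rep(c(1L, 0L), each = n %/% 2L)
  mu <- rbind(profile$mu_B, profile$mu_A)  # row 1: arm 0, row 2: arm 1
  b <- rnorm(n, 0, var$sigma_b)
  eps <- matrix(rnorm(n * 4L, 0, var$sigma_eps), n, 4L)
  Y <- mu[arm + 1L, , drop = FALSE] + b + eps
  out <- data.frame(subject_id = seq_len(n), arm = arm,
                    Y1 = Y[, 1L], Y2 = Y[, 2L], Y3 = Y[, 3L], Y4 = Y[, 4L])
  attr(out, "profile") <- profile$name
  attr(out, "var") <- var
  class(out) <- c("trial_data", "data.frame")
  out
}

#' Append a correlated auxiliary covariate
#'
#' Adds a normal covariate `CV` with population correlation `rho` with the
#' final outcome `Y4`, constructed conditionally:
#' `CV = mean + sd * (rho * z(Y4) + sqrt(1 - rho^2) * e)`, where `z(Y4)`
#' standardizes `Y4` by its population mean and SD for the subject's arm, so
#' the population correlation is exact by construction.
#'
#' @param data a `trial_data` from [simulate_trial()].
#' @param rho target correlation with `Y4`, in (-1, 1). Default 0.3.
#' @param mean,sd population mean and SD of `CV`. Defaults 38.0 and 62.7.
#' @param seed optional integer seed.
#' @return `data` with a `CV` column appended.
#' @export
generate_cv <- function(data, rho = 0.3, mean = 38.0, sd = 62.7,
                        seed = NULL) {
  stopifnot(inherits(data, "trial_data"))
  if (abs(rho) >= 1) stop("rho must lie strictly inside (-1, 1)",
                          call. = FALSE)
  if (sd <= 0) stop("sd must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  var <- attr(data, "var")
  prof <- response_profile(attr(data, "profile"))
  mu4 <- ifelse(data$arm == 1L, prof$mu_A[4L], prof$mu_B[4L])
  sd4 <- sqrt(var$sigma_b^2 + var$sigma_eps^2)
  z <- (data$Y4 - mu4) / sd4
  e <- rnorm(nrow(data))
  data$CV <- mean + sd * (rho * z + sqrt(1 - rho^2) * e)
  data
}

#' Generate the adverse-event series
#'
#' Appends binary columns `AE1`..`AE4`. No AEs occur at baseline; visit-2
#' status is Bernoulli with the per-arm initial probability; visits 3 and 4
#' are drawn from the conditional table given the subject's arm and previous
#' AE status.
#'
#' @param data a `trial_data`.
#' @param model an [ae_model()].
#' @param seed optional integer seed.
#' @export
generate_ae <- function(data, model = ae_model(), seed = NULL) {
  stopifnot(inherits(data, "trial_data"), inherits(model, "ae_model"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  tab <- model$conditional_table
  AE <- matrix(0L, n, 4L)
  p2 <- ifelse(data$arm == 1L, model$p_init_A, model$p_init_B)
  AE[, 2L] <- rbinom(n, 1L, p2)
  for (j in 3:4) {
    p <- numeric(n)
    for (a in c(0L, 1L)) for (g in c(0L, 1L)) {
      cell <- tab$prob[tab$timepoint == j & tab$arm == a & tab$gamma == g]
      sel <- data$arm == a & AE[, j - 1L] == g
      p[sel] <- cell
    }
    AE[, j] <- rbinom(n, 1L, p)
  }
  data$AE1 <- AE[, 1L]; data$AE2 <- AE[, 2L]
  data$AE3 <- AE[, 3L]; data$AE4 <- AE[, 4L]
  data
}

#' Classify responders
#'
#' `R_i = 1` when the change from baseline to endpoint reaches the
#' threshold (the boundary is inclusive). Subjects missing either the
#' baseline or the endpoint value get `NA`, the explicit "undetermined"
#' state -- they are never silently counted as non-responders.
#'
#' @param data a `trial_data`, possibly with missing values.
#' @param rule a [responder_rule()].
#' @return integer vector of 0/1/`NA` per subject.
#' @export
classify_responders <- function(data, rule = responder_rule()) {
  stopifnot(inherits(rule, "responder_rule"))
  y0 <- data[[paste0("Y", rule$baseline_index)]]
  y1 <- data[[paste0("Y", rule$endpoint_index)]]
  as.integer(y1 - y0 >= rule$lambda)
}

#' Analytic true responder rate
#'
#' Under the random-intercept normal model the change score
#' \eqn{C_i = Y_{i4} - Y_{i1}} has distribution \eqn{N(\Delta_{arm},
#' 2\sigma_\epsilon^2)} -- the random intercept cancels -- so the true
#' response rate is \eqn{1 - \Phi((\lambda - \Delta_{arm}) /
#' \sqrt{2\sigma_\epsilon^2})}.
#'
#' @param profile a [response_profile()].
#' @param rule a [responder_rule()].
#' @param var a [variance_components()].
#' @param arm 1 for arm A, 0 for arm B.
#' @return probability of response.
#' @examples
#' true_response_rate(response_profile("linear"), arm = 1)  # ~0.259
#' @export
true_response_rate <- function(profile, rule = responder_rule(),
                               var = variance_components(), arm = 1L) {
  stopifnot(arm %in% c(0L, 1L))
  mu <- if (arm == 1L) profile$mu_A else profile$mu_B
  delta <- mu[rule$endpoint_index] - mu[rule$baseline_index]
  1 - stats::pnorm((rule$lambda - delta) / sqrt(2 * var$sigma_eps^2))
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf("Two-arm trial data: %d subjects (%d per arm), profile '%s'\n",
              nrow(x), sum(x$arm == 1L), attr(x, "profile")))
  cat("Columns:", paste(names(x), collapse = ", "), "\n")
  NextMethod()
}
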