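# Difference in responder proportions and Rubin's rules pooling.

#' Difference in responder proportions with Wald SE
#'
#' Unpooled Wald form: \eqn{\hat p_A - \hat p_B} with
#' \eqn{SE = \sqrt{\hat p_A \hat q_A / n_A + \hat p_B \hat q_B / n_B}}.
#' When both arm proportions are degenerate (0 or 1) the SE is floored at
#' machine epsilon and flagged via attribute `degenerate` -- this arises in
#' tiny fixtures only.
#'
#' @param responders 0/1 vector with no `NA` (responder status must be
#'   determined for every subject before analysis).
#' @param arms 0/1 arm indicator (1 = A).
#' @return list with `p_A`, `p_B`, `diff`, `se`, `n_A`, `n_B`.
#' @examples
#' diff_proportions(c(rep(1, 26), rep(0, 74), rep(1, 11), rep(0, 89)),
#'                  rep(c(1, 0), each = 100))
#' @export
diff_proportions <- function(responders, arms) {
  if (anyNA(responders)) {
    stop("responder status contains undetermined values; impute first",
         call. = FALSE)
  }
  n_A <- sum(arms == 1L); n_B <- sum(arms == 0L)
  if (n_A == 0L || n_B == 0L) stop("both arms must be non-empty",
                                   call. = FALSE)
  p_A <- mean(responders[arms == 1L])
  p_B <- mean(responders[arms == 0L])
  se <- sqrt(p_A * (1 - p_A) / n_A + p_B * (1 - p_B) / n_B)
  degenerate <- se == 0
  if (degenerate) se <- .Machine$double.eps
  structure(list(p_A = p_A, p_B = p_B, diff = p_A - p_B, se = se,
                 n_A = n_A, n_B = n_B),
            degenerate = degenerate)
}

#' Pool multiple-imputation estimates by Rubin's rules
#'
#' Combines M per-imputation estimates \eqn{\hat\theta_m} with standard
#' errors \eqn{s_m}: pooled estimate = mean; within-variance
#' \eqn{W = \overline{s_m^2}}; between-variance \eqn{B} = sample variance
#' of the estimates; total \eqn{T = W + (1 + 1/M) B}; degrees of freedom
#' \eqn{(M-1)(1 + W / ((1+1/M)B))^2} (classic formula; with N = 200 per
#' dataset the small-sample correction is negligible). When \eqn{B = 0}
#' the reference distribution is normal (df infinite). The 95% CI uses the
#' t quantile on those df and the p-value tests a zero difference.
#'
#' @param estimates numeric vector of per-imputation estimates (M >= 2).
#' @param ses matching vector of per-imputation standard errors.
#' @param conf_level confidence level, default 0.95.
#' @return object of class `pooled_estimate`: `estimate`, `within_var`,
#'   `between_var`, `total_var`, `se`, `df`, `ci_low`, `ci_high`,
#'   `p_value`, `M`.
#' @examples
#' rubin_pool(c(0.10, 0.20), c(0.05, 0.05))
#' @export
rubin_pool <- function(estimates, ses, conf_level = 0.95) {
  M <- length(estimates)
  if (M < 2L) stop("Rubin's rules need at least M = 2 estimates",
                   call. = FALSE)
  if (length(ses) != M || !all(is.finite(estimates)) ||
      !all(is.finite(ses))) {
    stop("estimates and ses must be finite vectors of equal length",
         call. = FALSE)
  }
  qbar <- mean(estimates)
  W <- mean(ses^2)
  B <- stats::var(estimates)
  total <- W + (1 + 1 / M) * B
  if (B > 0) {
    df <- (M - 1) * (1 + W / ((1 + 1 / M) * B))^2
  } else {
    df <- Inf
  }
  se <- sqrt(total)
  alpha <- 1 - conf_level
  tq <- stats::qt(1 - alpha / 2, df)
  p <- 2 * stats::pt(-abs(qbar) / se, df)
  structure(list(estimate = qbar, within_var = W, between_var = B,
                 total_var = total, se = se, df = df,
                 ci_low = qbar - tq * se, ci_high = qbar + tq * se,
                 p_value = p, M = M),
            class = "pooled_estimate")
}

#' Pool an imputation result into a single inference
#'
#' MI strategies (M >= 2) are pooled by [rubin_pool()]. The single-dataset
#' NRI estimate gets the plain Wald z interval and test (its M = 1 result
#' has no between-imputation component).
#'
#' @param result an `imputation_result` from [run_strategy()].
#' @param conf_level confidence level, default 0.95.
#' @return a `pooled_estimate`.
#' @export
pool_result <- function(result, conf_level = 0.95) {
  stopifnot(inherits(result, "imputation_result"))
  est <- result$estimates
  if (result$M >= 2L) {
    return(rubin_pool(est$estimate, est$se, conf_level))
  }
  q <- est$estimate[1L]; se <- est$se[1L]
  alpha <- 1 - conf_level
  z <- stats::qnorm(1 - alpha / 2)
  structure(list(estimate = q, within_var = se^2, between_var = 0,
                 total_var = se^2, se = se, df = Inf,
                 ci_low = q - z * se, ci_high = q + z * se,
                 p_value = 2 * stats::pnorm(-abs(q) / se), M = 1L),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "Pooled difference in proportions: %.4f (95%% CI %.4f, %.4f), p = %.4g\n",
    x$estimate, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("  M = %d, within = %.3g, between = %.3g, df = %.1f\n",
              x$M, x$within_var, x$between_var, x$df))
  invisible(x)
}
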