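# Scenario orchestration: replicate loop, performance metrics, and the
# factorial study runner.

#' Percent bias of the difference in proportions
#'
#' \eqn{100 \times ((\bar p_A - \bar p_B) - (\pi_A - \pi_B)) /
#' (\pi_A - \pi_B)}; positive values are positive biases of the estimated
#' difference. Scale-invariant: proportions may be given as fractions or
#' percentages, consistently.
#'
#' @param mean_p_A,mean_p_B average estimated responder proportions.
#' @param pi_A,pi_B true responder proportions (must differ; null profiles
#'   are assessed through type I error instead).
#' @export
percent_bias <- function(mean_p_A, mean_p_B, pi_A, pi_B) {
  if (pi_A == pi_B) {
    stop("percent bias is undefined when the true difference is zero; ",
         "use the type I error rate for null profiles", call. = FALSE)
  }
  ((mean_p_A - mean_p_B) - (pi_A - pi_B)) / (pi_A - pi_B) * 100
}

#' Required number of simulated datasets
#'
#' Smallest `n_sim` with `MCSE(bias) = sd / sqrt(n_sim) <= max_mcse`, i.e.
#' `ceiling((sd / max_mcse)^2)`.
#'
#' @param sd_estimate anticipated SD of the replicate estimates.
#' @param max_mcse maximum tolerated Monte Carlo standard error.
#' @examples
#' simulation_size(6.0, 0.15)  # 1600
#' @export
simulation_size <- function(sd_estimate, max_mcse) {
  if (sd_estimate <= 0 || max_mcse <= 0) {
    stop("both arguments must be positive", call. = FALSE)
  }
  n <- (sd_estimate / max_mcse)^2
  # guard against floating-point overshoot of an exact integer ratio
  if (abs(n - round(n)) < 1e-8 * max(n, 1)) n <- round(n)
  as.integer(ceiling(n))
}

#' Scenario configuration
#'
#' Bundles everything one simulation cell needs: the response profile, the
#' dropout mechanism with its target rate, the strategies to compare, the
#' number of imputations (paper defaults: M = 30 at 30% missing, M = 50 at
#' 50%), the replicate count, and the true responder rates used as the
#' bias/coverage reference (analytic by default; override `pi_A`/`pi_B`,
#' e.g. with empirically derived printed values, to reproduce published
#' rows on their own scale).
#'
#' @param profile a [response_profile()] or its name.
#' @param dropout a [dropout_spec()].
#' @param strategies list of [imputation_spec()]s; `NULL` picks the default
#'   set (NRI, DTI, DTI+CV, IBD, IBD+CV, and the AE variants under dropout
#'   model 6).
#' @param n subjects per trial (default 200).
#' @param var a [variance_components()].
#' @param rule a [responder_rule()].
#' @param cv list with `rho`, `mean`, `sd` for the auxiliary covariate.
#' @param ae an [ae_model()].
#' @param M imputations; `NULL` picks 30 or 50 by the missing rate.
#' @param cycles FCS cycles per imputation.
#' @param n_sim replicate datasets (paper: 1600; scale down for desk runs).
#' @param pi_A,pi_B true responder rates; `NULL` = analytic oracle.
#' @export
scenario_config <- function(profile, dropout, strategies = NULL,
                            n = 200L, var = variance_components(),
                            rule = responder_rule(),
                            cv = list(rho = 0.3, mean = 38.0, sd = 62.7),
                            ae = ae_model(), M = NULL, cycles = 10L,
                            n_sim = 1600L, pi_A = NULL, pi_B = NULL) {
  if (is.character(profile)) profile <- response_profile(profile)
  stopifnot(inherits(profile, "response_profile"),
            inherits(dropout, "dropout_spec"))
  n_sim <- as.integer(n_sim)
  if (n_sim < 2L) stop("n_sim must be at least 2", call. = FALSE)
  if (is.null(M)) M <- if (dropout$target_rate >= 0.5) 50L else 30L
  if (is.null(strategies)) {
    strategies <- default_strategies(dropout$model_id, M, cycles)
  }
  if (is.null(pi_A)) pi_A <- true_response_rate(profile, rule, var, 1L)
  if (is.null(pi_B)) pi_B <- true_response_rate(profile, rule, var, 0L)
  structure(list(profile = profile, dropout = dropout,
                 strategies = strategies, n = as.integer(n), var = var,
                 rule = rule, cv = cv, ae = ae, M = as.integer(M),
                 cycles = as.integer(cycles), n_sim = n_sim,
                 pi_A = pi_A, pi_B = pi_B),
            class = "scenario_config")
}

#' @rdname scenario_config
#' @param model_id dropout mechanism (the AE variants are added under
#'   model 6).
#' @export
default_strategies <- function(model_id, M = 30L, cycles = 10L) {
  s <- list(
    imputation_spec("NRI"),
    imputation_spec("DTI", M = M, cycles = cycles),
    imputation_spec("DTI", include_cv = TRUE, M = M, cycles = cycles),
    imputation_spec("IBD", M = M, cycles = cycles),
    imputation_spec("IBD", include_cv = TRUE, M = M, cycles = cycles))
  if (model_id == 6L) {
    s <- c(s, list(
      imputation_spec("DTI", include_ae = TRUE, M = M, cycles = cycles),
      imputation_spec("IBD", include_ae = TRUE, M = M, cycles = cycles)))
  }
  s
}

#' Human-readable strategy label
#' @param spec an [imputation_spec()].
#' @export
strategy_label <- function(spec) {
  lab <- spec$strategy
  if (spec$include_cv) lab <- paste0(lab, "+CV")
  if (spec$include_ae) lab <- paste0(lab, "+AE")
  lab
}

#' Run one scenario: calibrate, replicate, analyze
#'
#' Calibrates the dropout cutoff once on pilot replicates, then for each of
#' `n_sim` replicates simulates a complete trial (with the auxiliary
#' covariate, and the AE series when needed), imposes dropout, runs every
#' strategy, and pools. RNG streams are hierarchical (scenario seed ->
#' replicate substream -> per-strategy imputation substream) so any single
#' replicate is reproducible in isolation. A complete-data `FULL` analysis
#' row is always included as reference. Individual replicate failures are
#' counted and the scenario aborts when more than 1% fail.
#'
#' @param config a [scenario_config()].
#' @param seed integer master seed for this scenario.
#' @return list with `replicates` (one row per replicate x strategy:
#'   `p_A`, `p_B`, `estimate`, `se`, `ci_low`, `ci_high`, `p_value` on the
#'   fraction scale), `metrics` (see [summarize_scenario()]), `cutoff`,
#'   `failures`.
#' @export
run_scenario <- function(config, seed = 1L) {
  stopifnot(inherits(config, "scenario_config"))
  need_ae <- config$dropout$model_id == 6L ||
    any(vapply(config$strategies, function(s) s$include_ae, logical(1)))
  need_cv <- any(vapply(config$strategies, function(s) s$include_cv,
                        logical(1)))
  make_complete <- function(s) {
    d <- simulate_trial(config$profile, config$n, config$var, seed = s)
    if (need_cv) d <- generate_cv(d, config$cv$rho, config$cv$mean,
                                  config$cv$sd)
    if (need_ae) d <- generate_ae(d, config$ae)
    d
  }
  cutoff <- if (config$dropout$target_rate > 0) {
    calibrate_cutoff(function(r) make_complete(derive_seed(seed, 0L, r)),
                     config$dropout, seed = derive_seed(seed, 0L))
  } else {
    1
  }
  labels <- vapply(config$strategies, strategy_label, character(1))
  rows <- vector("list", config$n_sim * (length(labels) + 1L))
  k <- 0L; failures <- 0L
  for (rep in seq_len(config$n_sim)) {
    rep_seed <- derive_seed(seed, rep)
    complete <- make_complete(rep_seed)
    full_r <- classify_responders(complete, config$rule)
    full <- diff_proportions(full_r, complete$arm)
    z <- stats::qnorm(0.975)
    k <- k + 1L
    rows[[k]] <- data.frame(
      replicate = rep, strategy = "FULL", p_A = full$p_A, p_B = full$p_B,
      estimate = full$diff, se = full$se,
      ci_low = full$diff - z * full$se, ci_high = full$diff + z * full$se,
      p_value = 2 * stats::pnorm(-abs(full$diff) / full$se))
    set.seed(derive_seed(rep_seed, 1L))
    mask <- apply_dropout(complete, config$dropout, cutoff)
    masked <- apply_mask(complete, mask)
    for (si in seq_along(config$strategies)) {
      spec <- config$strategies[[si]]
      row <- tryCatch({
        res <- run_strategy(masked, spec, config$rule,
                            seed = derive_seed(rep_seed, 2L, si))
        pooled <- pool_result(res)
        data.frame(replicate = rep, strategy = labels[si],
                   p_A = mean(res$estimates$p_A),
                   p_B = mean(res$estimates$p_B),
                   estimate = pooled$estimate, se = pooled$se,
                   ci_low = pooled$ci_low, ci_high = pooled$ci_high,
                   p_value = pooled$p_value)
      }, error = function(e) e)
      if (inherits(row, "error")) {
        failures <- failures + 1L
        warning(sprintf("replicate %d, strategy %s failed: %s", rep,
                        labels[si], conditionMessage(row)), call. = FALSE)
        if (failures > 0.01 * config$n_sim * length(labels)) {
          stop("more than 1% of replicates failed; aborting scenario",
               call. = FALSE)
        }
      } else {
        k <- k + 1L
        rows[[k]] <- row
      }
    }
  }
  replicates <- do.call(rbind, rows[seq_len(k)])
  list(replicates = replicates,
       metrics = summarize_scenario(replicates, config),
       cutoff = as.numeric(cutoff), failures = failures)
}

#' Summarize replicate results into scenario metrics
#'
#' Per strategy, on the percentage-point scale of the published tables:
#' mean arm proportions, mean difference with the average 95% CI, percent
#' bias (`NA` for null profiles), coverage of the true difference, the
#' fraction of replicates significant at 0.05 (power under alternatives,
#' type I error under nulls), `MCSE(bias) = SE_emp / sqrt(n_sim)`,
#' `MSE = mean((theta_hat - theta)^2)`, `SE_mod` (mean replicate SE) and
#' `SE_emp` (SD of replicate estimates).
#'
#' @param replicates replicate data.frame from [run_scenario()].
#' @param config the matching [scenario_config()].
#' @return data.frame of class `scenario_metrics`, one row per strategy.
#' @export
summarize_scenario <- function(replicates, config) {
  theta <- config$pi_A - config$pi_B
  null_profile <- config$pi_A == config$pi_B
  out <- lapply(split(replicates, replicates$strategy), function(d) {
    n_sim <- nrow(d)
    se_emp <- stats::sd(d$estimate) * 100
    data.frame(
      strategy = d$strategy[1L],
      n_sim = n_sim,
      mean_p_A = mean(d$p_A) * 100,
      mean_p_B = mean(d$p_B) * 100,
      mean_diff = mean(d$estimate) * 100,
      mean_ci_low = mean(d$ci_low) * 100,
      mean_ci_high = mean(d$ci_high) * 100,
      percent_bias = if (null_profile) NA_real_ else
        percent_bias(mean(d$p_A), mean(d$p_B), config$pi_A, config$pi_B),
      coverage = mean(d$ci_low <= theta & theta <= d$ci_high),
      power_or_type1 = mean(d$p_value < 0.05),
      mcse_bias = se_emp / sqrt(n_sim),
      mse = mean((d$estimate * 100 - theta * 100)^2),
      se_mod = mean(d$se) * 100,
      se_emp = se_emp)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  # stable ordering: FULL, then the configured strategy order
  labels <- c("FULL", vapply(config$strategies, strategy_label,
                             character(1)))
  out <- out[order(match(out$strategy, labels)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("scenario_metrics", "data.frame")
  out
}

#' Run a factorial study
#'
#' Executes every cell of `profiles x dropout models x missing rates` with
#' the default strategy set and writes table-shaped CSVs plus a
#' machine-readable JSON metrics file when `out_dir` is given. Each
#' scenario gets its own derived seed, so cells are reproducible in
#' isolation.
#'
#' @param profiles character vector of profile names.
#' @param model_ids dropout mechanisms to include (subset of 1..6).
#' @param rates endpoint missingness targets (subset of the paper's 0.30,
#'   0.50 -- any values in (0,1) are accepted).
#' @param n_sim replicates per scenario.
#' @param seed master seed.
#' @param out_dir optional output directory for CSV/JSON results.
#' @param ... further arguments passed to [scenario_config()] (e.g. `M`,
#'   `cycles`, `strategies`, `pi_A`, `pi_B`).
#' @return data.frame of metrics, one row per scenario x strategy, with
#'   identifying columns `profile`, `model_id`, `target_rate`.
#' @export
run_study <- function(profiles = c("linear", "nonlinear"),
                      model_ids = 1:6, rates = c(0.30, 0.50),
                      n_sim = 1600L, seed = 1L, out_dir = NULL, ...) {
  grid <- expand.grid(profile = profiles, model_id = model_ids,
                      rate = rates, stringsAsFactors = FALSE)
  all_metrics <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- scenario_config(
      profile = grid$profile[g],
      dropout = dropout_spec(grid$model_id[g],
                             target_rate = grid$rate[g]),
      n_sim = n_sim, ...)
    res <- run_scenario(cfg, seed = derive_seed(seed, g))
    m <- res$metrics
    m <- cbind(data.frame(profile = grid$profile[g],
                          model_id = grid$model_id[g],
                          target_rate = grid$rate[g]), m)
    all_metrics[[g]] <- m
  }
  metrics <- do.call(rbind, all_metrics)
  rownames(metrics) <- NULL
  if (!is.null(out_dir)) write_study_results(metrics, out_dir)
  metrics
}

#' Write study results in the published tables' shapes
#'
#' Emits `results_main.csv` (arm proportions, difference with CI, percent
#' bias, coverage, power -- the layout of the comparison tables),
#' `results_mc.csv` (MCSE, MSE, SE_mod, SE_emp), `results_type1.csv`
#' (significance rates for null profiles, when present), and
#' `metrics.json` with everything.
#'
#' @param metrics the data.frame returned by [run_study()].
#' @param out_dir output directory, created if absent.
#' @export
write_study_results <- function(metrics, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  keep <- metrics$strategy != "FULL"
  main <- metrics[keep, c("profile", "model_id", "target_rate", "strategy",
                          "mean_p_A", "mean_p_B", "mean_diff",
                          "mean_ci_low", "mean_ci_high", "percent_bias",
                          "coverage", "power_or_type1")]
  utils::write.csv(main, file.path(out_dir, "results_main.csv"),
                   row.names = FALSE)
  mc <- metrics[keep, c("profile", "model_id", "target_rate", "strategy",
                        "mcse_bias", "mse", "se_mod", "se_emp")]
  utils::write.csv(mc, file.path(out_dir, "results_mc.csv"),
                   row.names = FALSE)
  nulls <- metrics[keep & grepl("^null", metrics$profile),
                   c("profile", "model_id", "target_rate", "strategy",
                     "power_or_type1")]
  if (nrow(nulls) > 0) {
    names(nulls)[names(nulls) == "power_or_type1"] <- "type1_error"
    utils::write.csv(nulls, file.path(out_dir, "results_type1.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       dataframe = "rows", digits = NA, na = "null")
  invisible(metrics)
}
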