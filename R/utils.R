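# Internal helpers.

# Deterministic substream seed derivation (Lehmer-style mixing kept below
# 2^31 - 1 so results are valid R integer seeds on all platforms).
derive_seed <- function(seed, ...) {
  m <- 2147483647
  s <- as.numeric(seed) %% m
  for (k in c(...)) {
    s <- (s * 48271) %% m
    s <- (s + as.numeric(k)) %% m
    s <- (s * 48271) %% m
  }
  as.integer(s %% (m - 1)) + 1L
}

#' Write / read a trial dataset as wide CSV
#'
#' One row per subject; missing values are rendered as empty fields.
#' Columns: `subject_id`, `arm`, `Y1`..`Y4`, then any of `CV`,
#' `AE1`..`AE4` present.
#'
#' @param data a `trial_data`.
#' @param path file path.
#' @export
write_trial_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE,
                   na = "")
}

#' @rdname write_trial_csv
#' @param profile profile label to attach (metadata only; defaults to
#'   `"custom"` because a file does not carry its generating model).
#' @param var a [variance_components()] to attach as metadata.
#' @return `read_trial_csv` returns a `trial_data`.
#' @export
read_trial_csv <- function(path, profile = "custom",
                           var = variance_components()) {
  d <- utils::read.csv(path, na.strings = "")
  need <- c("subject_id", "arm", "Y1", "Y2", "Y3", "Y4")
  if (!all(need %in% names(d))) {
    stop("wide trial CSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  attr(d, "profile") <- profile
  attr(d, "var") <- var
  class(d) <- c("trial_data", "data.frame")
  d
}

#' Read a scenario configuration from JSON
#'
#' Keys (all optional, with package defaults): `profile`, `n`, `sigma_b`,
#' `sigma_eps`, `lambda`, `cv` (`rho`, `mean`, `sd`), `dropout`
#' (`model_id`, `target_rate`, `weight_A`, `weight_B`, `b1`, `b2`,
#' `tolerance`, `pilot_reps`), `ae_table` (rows `timepoint`, `arm`,
#' `gamma`, `prob`), `M`, `cycles`, `n_sim`, `seed`.
#'
#' @param path JSON file path.
#' @return a named list merged over the defaults, with constructor-backed
#'   components (`profile`, `var`, `rule`, `dropout`, `ae`).
#' @export
read_scenario_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  profile <- response_profile(cfg$profile %||% "linear")
  var <- variance_components(cfg$sigma_b %||% 12, cfg$sigma_eps %||% 7)
  rule <- responder_rule(cfg$lambda %||% 12.4)
  drop_cfg <- cfg$dropout %||% list()
  dropout <- dropout_spec(
    model_id = drop_cfg$model_id %||% 1L,
    target_rate = drop_cfg$target_rate %||% 0.30,
    weight_A = drop_cfg$weight_A %||% 0.3,
    weight_B = drop_cfg$weight_B %||% 1,
    b1 = drop_cfg$b1 %||% 0.01,
    b2 = drop_cfg$b2 %||% -0.40,
    tolerance = drop_cfg$tolerance %||% 0.005,
    pilot_reps = drop_cfg$pilot_reps %||% 200L)
  ae <- if (!is.null(cfg$ae_table)) {
    ae_model(cfg$p_init_A %||% 0.3, cfg$p_init_B %||% 0.5,
             as.data.frame(cfg$ae_table))
  } else {
    ae_model()
  }
  list(profile = profile, n = cfg$n %||% 200L, var = var, rule = rule,
       cv = list(rho = cfg$cv$rho %||% 0.3, mean = cfg$cv$mean %||% 38.0,
                 sd = cfg$cv$sd %||% 62.7),
       dropout = dropout, ae = ae,
       M = cfg$M %||% 30L, cycles = cfg$cycles %||% 10L,
       n_sim = cfg$n_sim %||% 1600L, seed = cfg$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
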