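#' Analysis configuration
#'
#' Collects the options shared by all fitting strategies: the epigenome-wide
#' significance threshold, the age at which the intercept is evaluated, the
#' covariates to adjust for, and the inference options of the cluster-robust
#' fit.
#'
#' @param significance_threshold p-value threshold declaring a CpG a hit.
#'   Default `1e-7`, the conventional epigenome-wide (Bonferroni-style)
#'   threshold.
#' @param age_origin age (years) at which the model intercept is evaluated;
#'   ages are centred at this value so that the exposure main effect is the
#'   group difference at baseline. `NULL` (default) means "minimum age
#'   present in the data".
#' @param covariates character vector of sample-sheet column names to adjust
#'   for as fixed effects.
#' @param strategy optional default hit-selection strategy, one of
#'   `"baseline"`, `"any_timepoint"`, `"all_timepoints"`, `"lmm_intercept"`,
#'   `"lmm_intercept_slope"`, `"robust_lm"`.
#' @param small_sample_correction logical; if `TRUE` the sandwich meat is
#'   multiplied by `m/(m-1)` (CR1). Default `FALSE`: the plain estimator.
#' @param df_method reference distribution for Wald p-values: `"normal"`
#'   (default) or `"t_clusters_minus_p"` (Student t with m - p df).
#' @param age_tolerance half-width (years) of the window used to match
#'   observations to a nominal time-point in cross-sectional EWAS. Exact ages
#'   (as produced by the simulator) always match.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(significance_threshold = 1e-7,
                            age_origin = NULL,
                            covariates = character(),
                            strategy = NULL,
                            small_sample_correction = FALSE,
                            df_method = c("normal", "t_clusters_minus_p"),
                            age_tolerance = 0.5) {
  if (!is.numeric(significance_threshold) || length(significance_threshold) != 1 ||
      !is.finite(significance_threshold) ||
      significance_threshold <= 0 || significance_threshold >= 1) {
    stop("`significance_threshold` must lie strictly between 0 and 1, got ",
         format(significance_threshold), call. = FALSE)
  }
  df_method <- match.arg(df_method)
  if (!is.null(strategy)) {
    strategy <- match.arg(strategy, strategy_names())
  }
  if (!is.null(age_origin)) {
    stopifnot(is.numeric(age_origin), length(age_origin) == 1, is.finite(age_origin))
  }
  stopifnot(is.character(covariates))
  structure(
    list(
      significance_threshold = significance_threshold,
      age_origin = age_origin,
      covariates = covariates,
      strategy = strategy,
      small_sample_correction = isTRUE(small_sample_correction),
      df_method = df_method,
      age_tolerance = age_tolerance
    ),
    class = "analysis_config"
  )
}

strategy_names <- function() {
  c("baseline", "any_timepoint", "all_timepoints",
    "lmm_intercept", "lmm_intercept_slope", "robust_lm")
}

#' Default per-scenario exposure effects
#'
#' The six causal-effect patterns used by the simulator, expressed through
#' the fixed effects of the trajectory model: `beta01` (group difference at
#' baseline), `beta10` (age slope of the unexposed) and `beta11` (difference
#' in age slope). All values are on the methylation beta-value scale
#' (fractions; slopes per year).
#'
#' * i — constant exposure effect, no age trend
#' * ii — diverging from a common baseline, no age trend in the unexposed
#' * iii — diverging from a common baseline with an age trend
#' * iv — constant exposure effect plus an age trend
#' * v — baseline effect and diverging over time
#' * vi — baseline effect converging over time (slope difference of opposite
#'   sign, small enough that the groups do not cross within the age span)
#'
#' @return a data frame with columns `scenario`, `beta01`, `beta10`, `beta11`.
#' @export
default_scenario_effects <- function() {
  data.frame(
    scenario = c("i", "ii", "iii", "iv", "v", "vi"),
    beta01 = c(0.02, 0, 0, 0.02, 0.02, 0.02),
    beta10 = c(0, 0, 0.002, 0.002, 0.002, 0),
    beta11 = c(0, 0.004, 0.004, 0, 0.004, -0.00125),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Parameters of the generative multilevel model used to simulate methylation
#' trajectories: a balanced panel of individuals measured at equally spaced
#' ages, a binary individual-level exposure, per-CpG fixed effects, a shared
#' 2x2 random intercept/slope covariance and residual noise.
#'
#' @param n_individuals number of individuals per replicate (default 464).
#' @param n_cpgs CpGs per replicate (default 100).
#' @param n_causal number of causal CpGs, one per scenario (default 6).
#' @param repeats number of equally spaced measurement occasions, one of
#'   3, 5 or 9 by convention (any integer >= 2 accepted).
#' @param age_min,age_max age span in years (default 10 to 18).
#' @param prevalence exposure prevalence, in (0, 1). Default 0.5.
#' @param scenario_effects data frame as [default_scenario_effects()].
#' @param sd_u0,sd_u1,cor_u random-intercept SD, random-slope SD (per year)
#'   and their correlation; together they define the unstructured 2x2
#'   random-effect covariance.
#' @param sigma_e residual SD.
#' @param beta00_range range of the per-CpG baseline methylation mean,
#'   drawn uniformly.
#' @param beta10_sd SD of the per-CpG age trend for null CpGs (age trends
#'   are ubiquitous in methylation; null means "no exposure effect", not
#'   "no change").
#' @param clip_beta logical; clip simulated values into \[0, 1\]. Off by
#'   default: the generative model is the linear mixed model itself and
#'   clipping would bias parameter-recovery checks.
#' @param n_replicates default replicate count for evaluation runs.
#' @param seed master seed; per-replicate seeds are derived with
#'   [derive_seed()].
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_individuals = 464,
                              n_cpgs = 100,
                              n_causal = 6,
                              repeats = 5,
                              age_min = 10,
                              age_max = 18,
                              prevalence = 0.5,
                              scenario_effects = default_scenario_effects(),
                              sd_u0 = 0.025,
                              sd_u1 = 0.007,
                              cor_u = -0.2,
                              sigma_e = 0.0325,
                              beta00_range = c(0.2, 0.8),
                              beta10_sd = 0.0015,
                              clip_beta = FALSE,
                              n_replicates = 100,
                              seed = 1L) {
  stopifnot(n_individuals >= 2, n_cpgs >= 1, repeats >= 2,
            age_max > age_min, sigma_e > 0, sd_u0 >= 0, sd_u1 >= 0,
            abs(cor_u) <= 1, n_causal <= n_cpgs, n_causal >= 0)
  if (prevalence <= 0 || prevalence >= 1) {
    stop("`prevalence` must lie strictly between 0 and 1", call. = FALSE)
  }
  required <- c("scenario", "beta01", "beta10", "beta11")
  if (!all(required %in% names(scenario_effects))) {
    stop("`scenario_effects` must have columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  if (n_causal > nrow(scenario_effects)) {
    stop("`n_causal` exceeds the number of scenarios provided", call. = FALSE)
  }
  # validate each scenario's zero/sign pattern
  for (k in seq_len(nrow(scenario_effects))) {
    with(scenario_effects[k, ], validate_scenario(scenario, beta01, beta10, beta11,
                                                  age_span = age_max - age_min))
  }
  Sigma_u <- matrix(c(sd_u0^2, cor_u * sd_u0 * sd_u1,
                      cor_u * sd_u0 * sd_u1, sd_u1^2), 2, 2)
  structure(
    list(
      n_individuals = n_individuals, n_cpgs = n_cpgs, n_causal = n_causal,
      repeats = repeats, age_min = age_min, age_max = age_max,
      prevalence = prevalence, scenario_effects = scenario_effects,
      Sigma_u = Sigma_u, sigma_e = sigma_e,
      beta00_range = beta00_range, beta10_sd = beta10_sd,
      clip_beta = isTRUE(clip_beta),
      n_replicates = n_replicates, seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

validate_scenario <- function(label, beta01, beta10, beta11, age_span = 8) {
  bad <- function(msg) stop("scenario (", label, "): ", msg, call. = FALSE)
  switch(as.character(label),
    "i"  = { if (beta01 == 0) bad("beta01 must be nonzero")
             if (beta10 != 0 || beta11 != 0) bad("beta10 and beta11 must be 0") },
    "ii" = { if (beta01 != 0 || beta10 != 0) bad("beta01 and beta10 must be 0")
             if (beta11 == 0) bad("beta11 must be nonzero") },
    "iii" = { if (beta01 != 0) bad("beta01 must be 0")
              if (beta10 == 0 || beta11 == 0) bad("beta10 and beta11 must be nonzero") },
    "iv" = { if (beta01 == 0 || beta10 == 0) bad("beta01 and beta10 must be nonzero")
             if (beta11 != 0) bad("beta11 must be 0") },
    "v"  = { if (beta01 == 0 || beta11 == 0) bad("beta01 and beta11 must be nonzero") },
    "vi" = { if (beta01 == 0 || beta11 == 0) bad("beta01 and beta11 must be nonzero")
             if (sign(beta11) != -sign(beta01)) bad("beta11 must oppose beta01 in sign")
             if (abs(beta11) * age_span > abs(beta01))
               bad("|beta11| * age span must not exceed |beta01| (groups would cross)") },
    bad("unknown scenario label")
  )
  invisible(TRUE)
}

#' Load analysis and simulation configuration from a YAML file
#'
#' The document may contain an `analysis:` section and a `simulation:`
#' section; either may be absent (defaults apply) and unknown keys are
#' rejected. An empty document yields all defaults, in particular the
#' epigenome-wide threshold of 1e-7.
#'
#' @param path path to a YAML (or JSON, a YAML subset) file.
#' @return list with elements `analysis` ([analysis_config]) and
#'   `simulation` ([simulation_config]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  unknown <- setdiff(names(doc), c("analysis", "simulation"))
  if (length(unknown)) {
    stop("unknown top-level config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ana <- doc$analysis %||% list()
  sim <- doc$simulation %||% list()
  check_keys <- function(given, fn, what) {
    allowed <- setdiff(names(formals(fn)), "...")
    unknown <- setdiff(names(given), allowed)
    if (length(unknown)) {
      stop("unknown ", what, " config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  check_keys(ana, analysis_config, "analysis")
  check_keys(sim, simulation_config, "simulation")
  if (!is.null(ana$covariates)) ana$covariates <- as.character(unlist(ana$covariates))
  if (!is.null(sim$scenario_effects)) {
    sim$scenario_effects <- as.data.frame(
      do.call(rbind.data.frame, sim$scenario_effects))
  }
  list(
    analysis = do.call(analysis_config, ana),
    simulation = do.call(simulation_config, sim)
  )
}
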