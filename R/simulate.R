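#' Simulate the individual table for one replicate
#'
#' A balanced panel: every individual is observed at every configured age
#' (equally spaced between `age_min` and `age_max`), with an individual-level
#' binary exposure drawn with the configured prevalence. If a draw leaves
#' one exposure group empty (possible at small n) it is redrawn, up to 100
#' attempts.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed for this table (defaults to the config master
#'   seed).
#' @return data frame with one row per individual: `individual_id`,
#'   `exposure`; the common age grid is attached as attribute `ages`.
#' @export
simulate_individuals <- function(config, seed = config$seed) {
  set.seed(seed)
  n <- config$n_individuals
  z <- stats::rbinom(n, 1, config$prevalence)
  tries <- 0
  while (length(unique(z)) < 2 && tries < 100) {
    z <- stats::rbinom(n, 1, config$prevalence)
    tries <- tries + 1
  }
  if (length(unique(z)) < 2) {
    stop("could not draw both exposure groups at prevalence ",
         config$prevalence, " with n = ", n, call. = FALSE)
  }
  ind <- data.frame(
    individual_id = sprintf("id%05d", seq_len(n)),
    exposure = z,
    stringsAsFactors = FALSE
  )
  attr(ind, "ages") <- seq(config$age_min, config$age_max,
                           length.out = config$repeats)
  ind
}

expand_observations <- function(individuals) {
  ages <- attr(individuals, "ages")
  n <- nrow(individuals)
  data.frame(
    observation_id = sprintf("%s_t%02d", rep(individuals$individual_id,
                                             each = length(ages)),
                             rep(seq_along(ages), times = n)),
    individual_id = rep(individuals$individual_id, each = length(ages)),
    age = rep(ages, times = n),
    exposure = rep(individuals$exposure, each = length(ages)),
    stringsAsFactors = FALSE
  )
}

#' Simulate one CpG's methylation values
#'
#' Draws from the generative trajectory model
#' `y_ij = (b00 + b01 z_j + u0j) + (b10 + b11 z_j + u1j) x_ij + e_ij`
#' with `(u0j, u1j) ~ N(0, Sigma_u)` and `e_ij ~ N(0, sigma_e^2)`, where
#' `x_ij` is age centred at `age_origin`. A null CpG is one with
#' `b01 = b11 = 0`.
#'
#' @param observations long-format observation table (`individual_id`,
#'   `age`, `exposure`), e.g. from [simulate_individuals()] expanded to the
#'   age grid.
#' @param effects list or one-row data frame with `beta00`, `beta01`,
#'   `beta10`, `beta11`.
#' @param Sigma_u 2x2 positive-semidefinite random-effect covariance.
#' @param sigma_e residual SD (> 0 unless exactly noise-free simulation is
#'   wanted, which is allowed).
#' @param age_origin age at which trajectories start (default: minimum age).
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return numeric vector of methylation values, one per observation row.
#' @export
simulate_cpg <- function(observations, effects, Sigma_u, sigma_e,
                         age_origin = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(c("individual_id", "age", "exposure") %in% names(observations)))
  Sigma_u <- as.matrix(Sigma_u)
  ev <- eigen(Sigma_u, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-12)) stop("Sigma_u must be positive semidefinite", call. = FALSE)
  origin <- age_origin %||% min(observations$age)
  x <- observations$age - origin
  z <- observations$exposure
  ids <- factor(observations$individual_id,
                levels = unique(observations$individual_id))
  m <- nlevels(ids)
  # u via eigen square root (tolerates singular Sigma_u)
  es <- eigen(Sigma_u, symmetric = TRUE)
  rt <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), 2) %*% t(es$vectors)
  u <- matrix(stats::rnorm(2 * m), m, 2) %*% rt
  idx <- as.integer(ids)
  eps <- if (sigma_e > 0) stats::rnorm(length(x), 0, sigma_e) else 0
  (effects$beta00 + effects$beta01 * z + u[idx, 1]) +
    (effects$beta10 + effects$beta11 * z + u[idx, 2]) * x + eps
}

#' Simulate a full replicate dataset with its truth table
#'
#' Generates `n_cpgs` CpGs for one replicate: `n_causal` causal CpGs (one
#' per scenario, placed at random positions) and the rest null
#' (`beta01 = beta11 = 0`, but with their own baseline level and age trend).
#' The replicate seed is derived from the master seed and the replicate
#' index with [derive_seed()], so replicates are deterministic and
#' non-overlapping.
#'
#' @param config a [simulation_config()].
#' @param replicate_index 1-based replicate counter.
#' @return list with `dataset` (a [longitudinal_dataset()]) and `truth`
#'   (data frame: `cpg_id`, `scenario` — `"null"` for non-causal CpGs —
#'   and the true `beta00`, `beta01`, `beta10`, `beta11`).
#' @export
simulate_dataset <- function(config, replicate_index = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  rep_seed <- derive_seed(config$seed, replicate_index, salt = 0L)
  set.seed(rep_seed)
  individuals <- simulate_individuals(config, seed = derive_seed(config$seed,
                                                                 replicate_index,
                                                                 salt = 1L))
  set.seed(rep_seed) # CpG stream independent of the individual draw above
  obs <- expand_observations(individuals)
  C <- config$n_cpgs
  cpg_ids <- sprintf("cpg%03d", seq_len(C))
  scen <- config$scenario_effects
  causal_pos <- if (config$n_causal > 0) {
    sort(sample.int(C, config$n_causal))
  } else integer()

  truth <- data.frame(
    cpg_id = cpg_ids,
    scenario = "null",
    beta00 = stats::runif(C, config$beta00_range[1], config$beta00_range[2]),
    beta01 = 0,
    beta10 = stats::rnorm(C, 0, config$beta10_sd),
    beta11 = 0,
    stringsAsFactors = FALSE
  )
  if (length(causal_pos)) {
    truth$scenario[causal_pos] <- scen$scenario[seq_along(causal_pos)]
    truth$beta01[causal_pos] <- scen$beta01[seq_along(causal_pos)]
    truth$beta10[causal_pos] <- scen$beta10[seq_along(causal_pos)]
    truth$beta11[causal_pos] <- scen$beta11[seq_along(causal_pos)]
  }

  beta <- matrix(NA_real_, C, nrow(obs),
                 dimnames = list(cpg_ids, obs$observation_id))
  for (k in seq_len(C)) {
    beta[k, ] <- simulate_cpg(obs, truth[k, ], config$Sigma_u, config$sigma_e,
                              age_origin = config$age_min)
  }
  if (config$clip_beta) beta <- pmin(pmax(beta, 0), 1)
  list(
    dataset = longitudinal_dataset(beta, obs),
    truth = truth,
    replicate_index = replicate_index,
    seed = rep_seed
  )
}
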