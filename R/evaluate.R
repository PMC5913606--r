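#' Power and Type I error across replicates
#'
#' Power for a (strategy, scenario) cell is the fraction of replicates in
#' which that scenario's causal CpG was flagged; Type I error for a strategy
#' is the fraction of all (replicate x null CpG) tests flagged. Monte-Carlo
#' standard errors are `sqrt(p(1-p)/n)`.
#'
#' @param hits_list list over replicates; each element a named list of
#'   [select_hits()] results (one per strategy).
#' @param truth_list list over replicates of truth tables from
#'   [simulate_dataset()].
#' @return object of class `power_table`: `power` (data frame strategy x
#'   scenario with `power`, `mc_se`, `n_replicates`) and `type1` (per
#'   strategy with `type1`, `mc_se`, `n_tests`).
#' @export
compute_power <- function(hits_list, truth_list) {
  stopifnot(length(hits_list) == length(truth_list), length(hits_list) >= 1)
  R <- length(hits_list)
  strategies <- names(hits_list[[1]])
  scenarios <- unique(unlist(lapply(truth_list, function(tt)
    setdiff(tt$scenario, "null"))))

  power <- do.call(rbind, lapply(strategies, function(st) {
    do.call(rbind, lapply(scenarios, function(sc) {
      flags <- vapply(seq_len(R), function(r) {
        causal <- truth_list[[r]]$cpg_id[truth_list[[r]]$scenario == sc]
        length(causal) > 0 && causal %in% hits_list[[r]][[st]]$hits
      }, logical(1))
      p <- mean(flags)
      data.frame(strategy = st, scenario = sc, power = p,
                 mc_se = sqrt(p * (1 - p) / R), n_replicates = R,
                 stringsAsFactors = FALSE)
    }))
  }))

  type1 <- do.call(rbind, lapply(strategies, function(st) {
    flagged <- 0L; total <- 0L
    for (r in seq_len(R)) {
      nulls <- truth_list[[r]]$cpg_id[truth_list[[r]]$scenario == "null"]
      total <- total + length(nulls)
      flagged <- flagged + sum(nulls %in% hits_list[[r]][[st]]$hits)
    }
    p <- if (total > 0) flagged / total else NA_real_
    data.frame(strategy = st, type1 = p,
               mc_se = if (total > 0) sqrt(p * (1 - p) / total) else NA_real_,
               n_tests = total, stringsAsFactors = FALSE)
  }))

  structure(list(power = power, type1 = type1, n_replicates = R),
            class = "power_table")
}

#' @exportS3Method base::print
print.power_table <- function(x, ...) {
  cat("power_table over", x$n_replicates, "replicate(s)\n")
  pw <- stats::reshape(x$power[, c("strategy", "scenario", "power")],
                       idvar = "strategy", timevar = "scenario",
                       direction = "wide")
  names(pw) <- sub("^power\\.", "", names(pw))
  print(pw, row.names = FALSE, digits = 3)
  cat("\nType I error (per null-CpG test):\n")
  print(x$type1, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Relative bias of the exposure parameters
#'
#' Summarises `(estimate - truth) / truth` for the exposure baseline effect
#' and the exposure x age interaction, per model and scenario; cells whose
#' true parameter is zero are `NA` (relative bias is undefined there). The
#' reported quantiles are the 2.5% and 97.5% points; SE summaries are the
#' mean and SD of the per-fit reported standard errors.
#'
#' @param estimates data frame with columns `replicate`, `cpg_id`, `model`,
#'   `parameter` (`"exposure"` or `"exposure:age"`), `estimate`, `se`.
#' @param truth data frame with columns `replicate`, `cpg_id`, `scenario`,
#'   `beta01`, `beta11`.
#' @return object of class `bias_table`: a data frame with per
#'   (model, scenario, parameter) cell the mean, SD and quantiles of the
#'   relative bias and the mean (SD) of the SEs.
#' @export
relative_bias <- function(estimates, truth) {
  need <- c("replicate", "cpg_id", "model", "parameter", "estimate", "se")
  stopifnot(all(need %in% names(estimates)),
            all(c("replicate", "cpg_id", "scenario", "beta01", "beta11") %in%
                  names(truth)))
  d <- merge(estimates, truth, by = c("replicate", "cpg_id"))
  d$true <- ifelse(d$parameter == "exposure", d$beta01, d$beta11)
  d$rel_bias <- ifelse(d$true != 0, (d$estimate - d$true) / d$true, NA_real_)

  cells <- unique(d[, c("model", "scenario", "parameter")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- d$model == cells$model[i] & d$scenario == cells$scenario[i] &
      d$parameter == cells$parameter[i]
    dd <- d[sel, ]
    rb <- dd$rel_bias
    all_na <- all(is.na(rb))
    data.frame(
      model = cells$model[i], scenario = cells$scenario[i],
      parameter = cells$parameter[i],
      mean_rel_bias = if (all_na) NA_real_ else mean(rb, na.rm = TRUE),
      sd_rel_bias = if (all_na) NA_real_ else stats::sd(rb, na.rm = TRUE),
      q_lower = if (all_na) NA_real_ else
        stats::quantile(rb, 0.025, na.rm = TRUE, names = FALSE),
      q_upper = if (all_na) NA_real_ else
        stats::quantile(rb, 0.975, na.rm = TRUE, names = FALSE),
      mean_se = mean(dd$se, na.rm = TRUE),
      sd_se = stats::sd(dd$se, na.rm = TRUE),
      n = nrow(dd),
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(out$model, out$scenario, out$parameter), ]
  rownames(out) <- NULL
  class(out) <- c("bias_table", "data.frame")
  out
}

#' Run the full strategy-comparison loop
#'
#' For each replicate: simulate a dataset, fit the requested strategies,
#' classify hits at the configured threshold, and collect the causal-CpG
#' exposure-parameter estimates. Aggregates power, Type I error, relative
#' bias and a methods-equivalence report (per-CpG estimate and SE deltas
#' between the cluster-robust regression and the random intercept + slope
#' mixed model). Per-replicate failures are isolated; the run aborts only
#' if more than 10% of replicates fail.
#'
#' @param sim_config a [simulation_config()].
#' @param config an [analysis_config()].
#' @param n_replicates number of replicates (default from `sim_config`).
#' @param strategies subset of the six strategy names to evaluate.
#' @param verbose print a progress line every 10 replicates.
#' @return list with `power` ([compute_power()] result), `bias`
#'   ([relative_bias()] result), `equivalence` (data frame of per-parameter
#'   correlations and deltas, when both longitudinal methods ran),
#'   `failed_replicates`.
#' @export
compare_strategies <- function(sim_config, config = analysis_config(),
                               n_replicates = sim_config$n_replicates,
                               strategies = strategy_names(),
                               verbose = FALSE) {
  strategies <- match.arg(strategies, strategy_names(), several.ok = TRUE)
  cross <- intersect(strategies, c("baseline", "any_timepoint", "all_timepoints"))
  cfg <- config
  cfg$age_origin <- cfg$age_origin %||% sim_config$age_min

  hits_list <- list()
  truth_list <- list()
  est_rows <- list()
  failed <- integer()

  for (r in seq_len(n_replicates)) {
    res <- tryCatch({
      sim <- simulate_dataset(sim_config, r)
      causal <- sim$truth$cpg_id[sim$truth$scenario != "null"]
      hits <- list()
      ests <- list()
      if (length(cross)) {
        ew <- ewas_all_timepoints(sim$dataset, cfg)
        for (st in cross) hits[[st]] <- select_hits(ew, st, cfg)
      }
      if (any(c("robust_lm") %in% strategies)) {
        rt <- as_result_table(fit_robust(sim$dataset, cfg))
        hits[["robust_lm"]] <- select_hits(rt, "robust_lm", cfg)
        sel <- rt$cpg_id %in% causal & rt$parameter %in% c("exposure", "exposure:age")
        if (any(sel)) {
          ests[["robust_lm"]] <- data.frame(
            replicate = r, rt[sel, c("cpg_id", "parameter", "estimate", "se")],
            model = "robust_lm", stringsAsFactors = FALSE)
        }
      }
      for (mode in c("intercept", "intercept_slope")) {
        st <- paste0("lmm_", mode)
        if (!st %in% strategies) next
        lt <- as_result_table(fit_lmm_batch(sim$dataset, cfg, random = mode))
        hits[[st]] <- select_hits(lt, st, cfg)
        sel <- lt$cpg_id %in% causal & !is.na(lt$parameter) &
          lt$parameter %in% c("exposure", "exposure:age")
        if (any(sel)) {
          ests[[st]] <- data.frame(
            replicate = r, lt[sel, c("cpg_id", "parameter", "estimate", "se")],
            model = st, stringsAsFactors = FALSE)
        }
      }
      list(hits = hits, truth = sim$truth, ests = ests)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, r)
      if (length(failed) > 0.1 * n_replicates) {
        stop("more than 10% of replicates failed; last error: ",
             conditionMessage(res), call. = FALSE)
      }
      next
    }
    hits_list[[length(hits_list) + 1L]] <- res$hits
    truth_list[[length(truth_list) + 1L]] <- res$truth
    res$truth$replicate <- r
    est_rows[[length(est_rows) + 1L]] <-
      list(truth = res$truth, ests = do.call(rbind, res$ests))
    if (verbose && r %% 10 == 0) message("replicate ", r, "/", n_replicates)
  }

  power <- compute_power(hits_list, truth_list)
  truth_all <- do.call(rbind, lapply(est_rows, `[[`, "truth"))
  est_all <- do.call(rbind, lapply(est_rows, `[[`, "ests"))
  bias <- if (!is.null(est_all) && nrow(est_all))
    relative_bias(est_all, truth_all) else NULL

  equivalence <- NULL
  if (!is.null(est_all) &&
      all(c("robust_lm", "lmm_intercept_slope") %in% est_all$model)) {
    a <- est_all[est_all$model == "robust_lm", ]
    b <- est_all[est_all$model == "lmm_intercept_slope", ]
    mm <- merge(a, b, by = c("replicate", "cpg_id", "parameter"),
                suffixes = c("_robust", "_lmm"))
    equivalence <- do.call(rbind, lapply(split(mm, mm$parameter), function(d) {
      data.frame(
        parameter = d$parameter[1],
        cor_estimates = stats::cor(d$estimate_robust, d$estimate_lmm),
        mean_abs_delta = mean(abs(d$estimate_robust - d$estimate_lmm)),
        mean_delta_over_se = mean(abs(d$estimate_robust - d$estimate_lmm) /
                                    pmin(d$se_robust, d$se_lmm)),
        n = nrow(d), stringsAsFactors = FALSE
      )
    }))
    rownames(equivalence) <- NULL
  }

  list(power = power, bias = bias, equivalence = equivalence,
       failed_replicates = failed)
}
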