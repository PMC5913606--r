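#' Cross-sectional EWAS at a single time-point
#'
#' Ordinary least squares of methylation on exposure (plus covariates)
#' restricted to the observations at one age, with classical (model-based)
#' standard errors — observations at one time-point are independent across
#' individuals. Ages are matched within `config$age_tolerance` of the
#' requested time-point; exact simulated ages always match.
#'
#' @param dataset a [longitudinal_dataset()].
#' @param timepoint age (years) of the wave to analyse.
#' @param config an [analysis_config()].
#' @return data frame, one row per CpG: `cpg_id`, `timepoint`, `estimate`
#'   (exposure coefficient), `se`, `statistic`, `p_value`, `n_used`,
#'   `status`.
#' @export
ewas_at_timepoint <- function(dataset, timepoint, config = analysis_config()) {
  stopifnot(inherits(dataset, "longitudinal_dataset"))
  s <- dataset$samples
  rows <- which(abs(s$age - timepoint) <= config$age_tolerance + 1e-9)
  if (!length(rows)) {
    stop("no observations at age ", timepoint, "; available ages: ",
         paste(sort(unique(round(s$age, 2))), collapse = ", "), call. = FALSE)
  }
  z <- s$exposure[rows]
  if (sum(z == 0) < 2 || sum(z == 1) < 2) {
    stop("need at least 2 observations per exposure group at age ",
         timepoint, call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, exposure = z)
  for (cv in config$covariates) {
    if (!cv %in% names(s)) {
      stop("covariate `", cv, "` named in the config is absent from the ",
           "sample sheet", call. = FALSE)
    }
    X <- cbind(X, s[[cv]][rows])
    colnames(X)[ncol(X)] <- cv
  }
  check_full_rank(X)
  Y <- t(dataset$beta[, rows, drop = FALSE])
  fit <- fit_ols_batch(Y, X)
  p <- ncol(X)
  XtXinv_diag <- stats::setNames(diag(chol2inv(chol(crossprod(X)))),
                                 colnames(X))
  est <- fit$coefficients["exposure", ]
  rss <- colSums(fit$residuals^2, na.rm = TRUE)
  dfree <- fit$n_used - p
  s2 <- ifelse(dfree > 0, rss / dfree, NA_real_)
  # classical SE for complete CpGs; refit diag for incomplete ones
  se <- sqrt(s2 * XtXinv_diag["exposure"])
  incomplete <- fit$n_used < length(rows) & fit$ok
  for (c_idx in which(incomplete)) {
    used <- which(!is.na(fit$residuals[, c_idx]))
    di <- diag(chol2inv(chol(crossprod(X[used, , drop = FALSE]))))
    se[c_idx] <- sqrt(s2[c_idx] * di[which(colnames(X) == "exposure")])
  }
  stat <- est / se
  pval <- 2 * stats::pt(-abs(stat), df = pmax(dfree, 1))
  data.frame(
    cpg_id = dataset$cpg_ids, timepoint = timepoint,
    estimate = est, se = se, statistic = stat, p_value = pval,
    n_used = fit$n_used,
    status = ifelse(fit$ok & dfree > 0, "converged", "unfit"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Cross-sectional EWAS at every time-point
#'
#' @param dataset a [longitudinal_dataset()].
#' @param config an [analysis_config()].
#' @param timepoints ages to analyse; default all distinct ages present.
#' @return data frame stacking [ewas_at_timepoint()] results, ordered by
#'   time-point.
#' @export
ewas_all_timepoints <- function(dataset, config = analysis_config(),
                                timepoints = NULL) {
  if (is.null(timepoints)) {
    timepoints <- sort(unique(dataset$samples$age))
  }
  do.call(rbind, lapply(timepoints, function(tp) {
    ewas_at_timepoint(dataset, tp, config)
  }))
}

#' Select hit CpGs under a strategy
#'
#' Applies one of the hit-selection rules at the configured significance
#' threshold:
#' * `baseline` — p-value at the earliest time-point below the threshold;
#' * `any_timepoint` — minimum over time-points below the threshold;
#' * `all_timepoints` — maximum over time-points below the threshold;
#' * `robust_lm`, `lmm_intercept`, `lmm_intercept_slope` — minimum over the
#'   exposure-related parameters (baseline effect `exposure` and interaction
#'   `exposure:age`) below the threshold.
#'
#' CpGs with missing p-values are excluded and counted.
#'
#' @param results for the cross-sectional strategies, the data frame from
#'   [ewas_all_timepoints()]; for the longitudinal strategies, a result
#'   table from [as_result_table()].
#' @param strategy one of the names above.
#' @param config an [analysis_config()] supplying the threshold.
#' @return object of class `strategy_hits`: `strategy`, `hits` (character
#'   vector of CpG ids), `trigger` (data frame naming, per hit, the
#'   time-point or parameter that crossed the threshold), `n_excluded`.
#' @export
select_hits <- function(results, strategy, config = analysis_config()) {
  strategy <- match.arg(strategy, strategy_names())
  tau <- config$significance_threshold
  if (strategy %in% c("baseline", "any_timepoint", "all_timepoints")) {
    stopifnot(all(c("cpg_id", "timepoint", "p_value") %in% names(results)))
    sp <- split(results, results$cpg_id)
    keep <- vapply(sp, function(d) !anyNA(d$p_value), logical(1))
    n_excluded <- sum(!keep)
    sp <- sp[keep]
    is_hit <- vapply(sp, function(d) {
      switch(strategy,
        baseline = d$p_value[which.min(d$timepoint)] < tau,
        any_timepoint = min(d$p_value) < tau,
        all_timepoints = max(d$p_value) < tau)
    }, logical(1))
    hits <- names(sp)[is_hit]
    trigger <- do.call(rbind, lapply(hits, function(cpg) {
      d <- sp[[cpg]]
      tp <- switch(strategy,
        baseline = min(d$timepoint),
        any_timepoint = d$timepoint[which.min(d$p_value)],
        all_timepoints = d$timepoint[which.max(d$p_value)])
      data.frame(cpg_id = cpg, trigger = paste0("age_", tp),
                 stringsAsFactors = FALSE)
    }))
  } else {
    stopifnot(all(c("cpg_id", "parameter", "p_value") %in% names(results)))
    expo <- results[!is.na(results$parameter) &
                      results$parameter %in% c("exposure", "exposure:age"), ,
                    drop = FALSE]
    sp <- split(expo, expo$cpg_id)
    failed_ids <- setdiff(unique(results$cpg_id), names(sp))
    keep <- vapply(sp, function(d) nrow(d) >= 2 && !anyNA(d$p_value), logical(1))
    n_excluded <- sum(!keep) + length(failed_ids)
    sp <- sp[keep]
    is_hit <- vapply(sp, function(d) min(d$p_value) < tau, logical(1))
    hits <- names(sp)[is_hit]
    trigger <- do.call(rbind, lapply(hits, function(cpg) {
      d <- sp[[cpg]]
      data.frame(cpg_id = cpg,
                 trigger = d$parameter[which.min(d$p_value)],
                 stringsAsFactors = FALSE)
    }))
  }
  structure(
    list(strategy = strategy, hits = hits,
         trigger = trigger %||% data.frame(cpg_id = character(),
                                           trigger = character()),
         n_excluded = n_excluded),
    class = "strategy_hits"
  )
}

#' @exportS3Method base::print
print.strategy_hits <- function(x, ...) {
  cat("strategy_hits [", x$strategy, "]: ", length(x$hits), " hit(s)",
      if (x$n_excluded) paste0(", ", x$n_excluded, " CpG(s) excluded"),
      "\n", sep = "")
  invisible(x)
}
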