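#' Fit a per-CpG linear mixed model
#'
#' The comparator longitudinal method: a multilevel model of the methylation
#' trajectory with either a random intercept only, or a random intercept and
#' random age slope with unstructured 2x2 covariance, estimated by REML.
#' Fixed effects are intercept, exposure, centred age, exposure x age and
#' any covariates — the same mean structure as [fit_robust()].
#'
#' Estimation is delegated to [lme4::lmer()] (REML criterion; the
#' random-effect covariance is kept positive semidefinite by lme4's
#' Cholesky-factor parameterisation). A singular fit — a variance component
#' on the zero boundary — is reported with status `"boundary"`, never
#' silently replaced by the simpler model. Wald p-values use the standard
#' normal reference, matching the robust fit's default.
#'
#' @param y numeric vector of methylation values, one per observation
#'   (`NA` rows are dropped).
#' @param samples long-format sample sheet (`individual_id`, `age`,
#'   `exposure`, covariates) aligned to `y`.
#' @param random `"intercept"` or `"intercept_slope"`.
#' @param config an [analysis_config()].
#' @return object of class `lmm_fit`: coefficients, SEs, p-values, `Sigma_u`
#'   (random-effect covariance), `sigma2_e`, REML log-likelihood, `status`
#'   in `{"converged","boundary","max_iter","failed"}`, `n_used`, `m`.
#' @export
fit_lmm <- function(y, samples, random = c("intercept_slope", "intercept"),
                    config = analysis_config()) {
  random <- match.arg(random)
  stopifnot(length(y) == nrow(samples))
  origin <- config$age_origin %||% min(samples$age)
  dat <- data.frame(
    y = y,
    exposure = samples$exposure,
    age = samples$age - origin,
    individual_id = samples$individual_id,
    stringsAsFactors = FALSE
  )
  for (cv in config$covariates) {
    if (!cv %in% names(samples)) {
      stop("covariate `", cv, "` named in the config is absent from the ",
           "sample sheet", call. = FALSE)
    }
    dat[[cv]] <- samples[[cv]]
  }
  dat <- dat[!is.na(dat$y), , drop = FALSE]
  failed <- function(msg) {
    structure(list(coefficients = NULL, se = NULL, p_value = NULL,
                   Sigma_u = NULL, sigma2_e = NA_real_, logLik = NA_real_,
                   status = "failed", message = msg,
                   n_used = nrow(dat), m = length(unique(dat$individual_id))),
              class = "lmm_fit")
  }
  if (length(unique(dat$individual_id)) < 2) {
    return(failed("fewer than 2 clusters"))
  }
  re_term <- if (random == "intercept") "(1 | individual_id)" else
    "(1 + age | individual_id)"
  fixed <- paste(c("exposure * age", config$covariates), collapse = " + ")
  fml <- stats::as.formula(paste("y ~", fixed, "+", re_term))

  status <- "converged"
  fit <- withCallingHandlers(
    tryCatch(
      lme4::lmer(fml, data = dat, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore")),
      error = function(e) e
    ),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
        status <<- "max_iter"
      }
      invokeRestart("muffleWarning")
    }
  )
  if (inherits(fit, "error")) return(failed(conditionMessage(fit)))
  if (lme4::isSingular(fit, tol = 1e-4) && status == "converged") {
    status <- "boundary"
  }

  b <- lme4::fixef(fit)
  vc <- suppressWarnings(as.matrix(stats::vcov(fit)))
  if (anyNA(vc) || anyNA(b)) {
    return(failed("degenerate fit: fixed-effect covariance unavailable"))
  }
  se <- sqrt(pmax(diag(vc), 0))
  names(se) <- names(b)
  vcs <- lme4::VarCorr(fit)
  Sigma_u <- as.matrix(vcs$individual_id)
  attr(Sigma_u, "stddev") <- NULL
  attr(Sigma_u, "correlation") <- NULL
  nm <- names(b)
  nm[nm == "exposure:age"] <- "exposure:age" # interaction keeps shared naming
  structure(
    list(
      coefficients = stats::setNames(as.numeric(b), nm),
      se = stats::setNames(as.numeric(se), nm),
      p_value = NULL, # filled by lmm_wald
      Sigma_u = Sigma_u,
      sigma2_e = stats::sigma(fit)^2,
      logLik = as.numeric(stats::logLik(fit)),
      status = status,
      boundary = status == "boundary",
      n_used = nrow(dat),
      m = length(unique(dat$individual_id))
    ),
    class = "lmm_fit"
  )
}

#' Wald p-values for a mixed-model fit
#'
#' Two-sided p-values from the standard normal reference for every fixed
#' effect (the exposure baseline effect and the exposure x age interaction
#' being the parameters of scientific interest). A failed fit yields no
#' p-values.
#'
#' @param fit an `lmm_fit`.
#' @param config an [analysis_config()] (reserved for future df options).
#' @return the fit with its `p_value` element populated, or unchanged if the
#'   fit failed.
#' @export
lmm_wald <- function(fit, config = analysis_config()) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (fit$status == "failed") return(fit)
  w <- wald_test(fit$coefficients, fit$se, df_method = "normal")
  fit$statistic <- w$statistic
  fit$p_value <- w$p_value
  fit
}

#' @exportS3Method base::print
print.lmm_fit <- function(x, ...) {
  cat("lmm_fit (status:", x$status, ")\n")
  if (!is.null(x$coefficients)) {
    print(cbind(estimate = x$coefficients, se = x$se,
                p = x$p_value %||% rep(NA_real_, length(x$coefficients))))
    cat("sigma_e^2:", format(x$sigma2_e, digits = 4), "\n")
  }
  invisible(x)
}

#' Fit mixed models to every CpG of a dataset
#'
#' One REML fit per CpG; failures (e.g. constant methylation) are isolated
#' and flagged, never fatal. Each CpG's rows with missing methylation are
#' dropped for that CpG only.
#'
#' @param dataset a [longitudinal_dataset()].
#' @param config an [analysis_config()].
#' @param random `"intercept_slope"` (default) or `"intercept"`.
#' @return object of class `lmm_batch`: list of `lmm_fit`s (named by CpG)
#'   plus the strategy label. [as_result_table()] gives the long table.
#' @export
fit_lmm_batch <- function(dataset, config = analysis_config(),
                          random = c("intercept_slope", "intercept")) {
  random <- match.arg(random)
  stopifnot(inherits(dataset, "longitudinal_dataset"))
  origin <- config$age_origin %||% min(dataset$samples$age)
  cfg <- config
  cfg$age_origin <- origin
  fits <- lapply(seq_along(dataset$cpg_ids), function(i) {
    f <- tryCatch(
      fit_lmm(dataset$beta[i, ], dataset$samples, random = random, config = cfg),
      error = function(e) {
        structure(list(coefficients = NULL, se = NULL, p_value = NULL,
                       Sigma_u = NULL, sigma2_e = NA_real_, logLik = NA_real_,
                       status = "failed", message = conditionMessage(e),
                       n_used = NA_integer_, m = NA_integer_),
                  class = "lmm_fit")
      }
    )
    lmm_wald(f, cfg)
  })
  names(fits) <- dataset$cpg_ids
  structure(list(fits = fits,
                 strategy = paste0("lmm_", random),
                 n_failed = sum(vapply(fits, function(f) f$status == "failed",
                                       logical(1)))),
            class = "lmm_batch")
}

#' @export
as_result_table.lmm_batch <- function(x, ...) {
  rows <- lapply(names(x$fits), function(cpg) {
    f <- x$fits[[cpg]]
    if (f$status == "failed") {
      return(data.frame(cpg_id = cpg, strategy = x$strategy,
                        parameter = NA_character_, estimate = NA_real_,
                        se = NA_real_, statistic = NA_real_,
                        p_value = NA_real_, n_used = f$n_used,
                        m_used = f$m, status = "failed",
                        stringsAsFactors = FALSE))
    }
    data.frame(
      cpg_id = cpg, strategy = x$strategy,
      parameter = names(f$coefficients),
      estimate = as.numeric(f$coefficients),
      se = as.numeric(f$se),
      statistic = as.numeric(f$statistic),
      p_value = as.numeric(f$p_value),
      n_used = f$n_used, m_used = f$m, status = f$status,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
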