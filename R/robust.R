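#' Batch ordinary least squares across many CpGs
#'
#' Fits the same design to every CpG (outcome column) in one shared QR
#' factorisation; CpGs with missing values are refitted on their complete
#' rows only. QR solving is used throughout for numerical robustness; an
#' ill-conditioned design (condition number > 1e8) additionally triggers a
#' warning.
#'
#' @param y numeric vector (one outcome) or n x C matrix, one column per
#'   CpG, rows aligned to the design.
#' @param X design matrix as built by [build_design()].
#' @return list with `coefficients` (p x C), `residuals` (n x C, `NA` where
#'   the outcome was missing or the CpG unfit), `n_used` (rows per CpG) and
#'   `ok` (logical per CpG; `FALSE` when fewer usable rows than parameters).
#' @export
fit_ols_batch <- function(y, X) {
  y <- as.matrix(y)
  stopifnot(nrow(y) == nrow(X))
  p <- ncol(X)
  C <- ncol(y)
  kap <- kappa(X, exact = FALSE)
  if (is.finite(kap) && kap > 1e8) {
    warning("design matrix is ill-conditioned (condition number ",
            format(kap, digits = 3), "); estimates may be unstable")
  }
  coefs <- matrix(NA_real_, p, C, dimnames = list(colnames(X), colnames(y)))
  resid <- matrix(NA_real_, nrow(y), C, dimnames = dimnames(y))
  n_used <- integer(C)
  ok <- rep(TRUE, C)

  complete <- !apply(y, 2L, anyNA)
  if (any(complete)) {
    qx <- qr(X)
    yc <- y[, complete, drop = FALSE]
    b <- qr.coef(qx, yc)
    coefs[, complete] <- b
    resid[, complete] <- yc - X %*% b
    n_used[complete] <- nrow(X)
  }
  for (c_idx in which(!complete)) {
    rows <- which(!is.na(y[, c_idx]))
    n_used[c_idx] <- length(rows)
    if (length(rows) < p || qr(X[rows, , drop = FALSE])$rank < p) {
      ok[c_idx] <- FALSE
      next
    }
    b <- qr.coef(qr(X[rows, , drop = FALSE]), y[rows, c_idx])
    coefs[, c_idx] <- b
    resid[rows, c_idx] <- y[rows, c_idx] - X[rows, , drop = FALSE] %*% b
  }
  list(coefficients = coefs, residuals = resid, n_used = n_used, ok = ok)
}

# plain-R meat accumulation, used for CpGs with missing rows
meat_loop <- function(X, e, rows_list) {
  p <- ncol(X)
  meat <- matrix(0, p, p)
  for (rows in rows_list) {
    w <- crossprod(X[rows, , drop = FALSE], e[rows])
    meat <- meat + tcrossprod(w)
  }
  meat
}

#' Cluster-robust (sandwich) covariance of batch OLS fits
#'
#' Computes, per CpG, `V = (X'X)^-1 [ sum_j w_j' w_j ] (X'X)^-1` with
#' `w_j = sum_{k in cluster j} e_k x_k`, the cluster-robust variance of the
#' OLS coefficients under arbitrary within-individual correlation of the
#' residuals. With every cluster of size one this reduces to the HC0
#' heteroskedasticity-robust estimator. CpGs with complete data share one
#' bread matrix and a vectorised meat accumulation (compiled); CpGs with
#' missing rows are handled individually with their cluster count `m`
#' recomputed.
#'
#' @param X design matrix.
#' @param residuals n x C residual matrix from [fit_ols_batch()] (`NA` rows
#'   are treated as missing for that CpG).
#' @param clusters a [cluster_index()] on the same rows.
#' @param correction logical; multiply the meat by `m/(m-1)` (CR1). Default
#'   `FALSE`, the plain estimator.
#' @return list with `V` (p x p x C array), `m_used` (clusters contributing
#'   per CpG) and `reliable` (logical; `FALSE` when `m_used <= p`, where
#'   cluster-robust inference is not trustworthy).
#' @export
cluster_robust_variance <- function(X, residuals, clusters, correction = FALSE) {
  stopifnot(inherits(clusters, "cluster_index"), nrow(X) == nrow(residuals))
  residuals <- as.matrix(residuals)
  p <- ncol(X)
  C <- ncol(residuals)
  V <- array(NA_real_, c(p, p, C),
             dimnames = list(colnames(X), colnames(X), colnames(residuals)))
  m_used <- integer(C)
  reliable <- rep(TRUE, C)

  complete <- !apply(residuals, 2L, anyNA)
  if (any(complete)) {
    ord <- order(clusters$id)
    starts <- cumsum(c(0L, as.integer(table(clusters$id))))
    meat <- cpp_cluster_meat(X[ord, , drop = FALSE],
                             residuals[ord, complete, drop = FALSE],
                             as.integer(starts))
    m <- clusters$m
    if (correction) meat <- meat * m / (m - 1)
    bread <- chol2inv(chol(crossprod(X)))
    for (c_idx in seq_along(which(complete))) {
      col <- which(complete)[c_idx]
      Vc <- bread %*% matrix(meat[, c_idx], p, p) %*% bread
      V[, , col] <- (Vc + t(Vc)) / 2
      m_used[col] <- m
    }
  }
  for (col in which(!complete)) {
    rows <- which(!is.na(residuals[, col]))
    if (length(rows) < p) { reliable[col] <- FALSE; next }
    keep <- lapply(clusters$rows, intersect, rows)
    keep <- keep[lengths(keep) > 0]
    m <- length(keep)
    m_used[col] <- m
    Xs <- X[rows, , drop = FALSE]
    if (qr(Xs)$rank < p) { reliable[col] <- FALSE; next }
    meat <- meat_loop(X, residuals[, col], keep)
    if (correction) meat <- meat * m / (m - 1)
    bread <- chol2inv(chol(crossprod(Xs)))
    Vc <- bread %*% meat %*% bread
    V[, , col] <- (Vc + t(Vc)) / 2
  }
  reliable <- reliable & (m_used > p)
  list(V = V, m_used = m_used, reliable = reliable)
}

#' Wald statistics and two-sided p-values
#'
#' @param estimate,se numeric vectors (or matrices) of estimates and
#'   standard errors.
#' @param df_method `"normal"` (default) or `"t_clusters_minus_p"`.
#' @param df degrees of freedom (m - p) when the t reference is used.
#' @return list with `statistic` and `p_value` shaped like `estimate`.
#' @export
wald_test <- function(estimate, se, df_method = c("normal", "t_clusters_minus_p"),
                      df = NULL) {
  df_method <- match.arg(df_method)
  z <- estimate / se
  degen <- !is.na(se) & se == 0
  if (any(degen & !is.na(estimate) & estimate != 0)) {
    warning("zero standard error with nonzero estimate; p-value set to 0")
  }
  z[which(degen & !is.na(estimate) & estimate == 0)] <- 0
  p <- if (df_method == "normal") {
    2 * stats::pnorm(-abs(z))
  } else {
    if (is.null(df)) stop("`df` required for the t reference", call. = FALSE)
    2 * stats::pt(-abs(z), df = pmax(df, 1))
  }
  p[degen & !is.na(estimate) & estimate != 0] <- 0
  p[degen & !is.na(estimate) & estimate == 0] <- 1
  list(statistic = z, p_value = p)
}

#' Linear regression with cluster-robust standard errors across all CpGs
#'
#' The package's fast longitudinal method: one OLS fit per CpG of
#' methylation on exposure, centred age, their interaction and covariates,
#' with the within-individual correlation of repeated measures absorbed by
#' the cluster-robust sandwich variance rather than random effects.
#'
#' @param dataset a [longitudinal_dataset()].
#' @param config an [analysis_config()].
#' @return an object of class `robust_fit` with per-CpG coefficient
#'   estimates, sandwich covariances, standard errors, Wald statistics and
#'   p-values. Use [as_result_table()] for a long-format table.
#' @export
fit_robust <- function(dataset, config = analysis_config()) {
  d <- build_design(dataset, config)
  Y <- t(dataset$beta)
  fit <- fit_ols_batch(Y, d$X)
  vr <- cluster_robust_variance(d$X, fit$residuals, d$clusters,
                                correction = config$small_sample_correction)
  p <- ncol(d$X)
  C <- ncol(Y)
  se <- t(apply(vr$V, 3L, function(v) sqrt(pmax(diag(v), 0))))
  if (C == 1L) se <- matrix(se, nrow = 1L)
  dimnames(se) <- list(colnames(Y), colnames(d$X))
  est <- t(fit$coefficients)
  df <- if (config$df_method == "t_clusters_minus_p") vr$m_used - p else NULL
  w <- wald_test(est, se, df_method = config$df_method,
                 df = if (is.null(df)) NULL else matrix(df, C, p))
  structure(
    list(
      coefficients = est, se = se,
      statistic = w$statistic, p_value = w$p_value,
      V = vr$V, n_used = fit$n_used, m_used = vr$m_used,
      ok = fit$ok & vr$reliable,
      parameters = colnames(d$X),
      age_origin = d$age_origin,
      config = config
    ),
    class = "robust_fit"
  )
}

#' @exportS3Method base::print
print.robust_fit <- function(x, ...) {
  cat("robust_fit:", nrow(x$coefficients), "CpGs,",
      length(x$parameters), "parameters (",
      paste(x$parameters, collapse = ", "), ")\n")
  cat("  clusters:", max(x$m_used), " unfit CpGs:", sum(!x$ok), "\n")
  invisible(x)
}

#' Convert a fit object to a long result table
#'
#' One row per CpG x parameter with estimate, SE, Wald statistic, p-value,
#' rows and clusters used, and a status flag.
#'
#' @param x a `robust_fit` or `lmm_batch` object.
#' @param ... unused.
#' @return a data frame.
#' @export
as_result_table <- function(x, ...) UseMethod("as_result_table")

#' @export
as_result_table.robust_fit <- function(x, ...) {
  C <- nrow(x$coefficients)
  p <- length(x$parameters)
  data.frame(
    cpg_id = rep(rownames(x$coefficients), each = p),
    strategy = "robust_lm",
    parameter = rep(x$parameters, times = C),
    estimate = as.vector(t(x$coefficients)),
    se = as.vector(t(x$se)),
    statistic = as.vector(t(x$statistic)),
    p_value = as.vector(t(x$p_value)),
    n_used = rep(x$n_used, each = p),
    m_used = rep(x$m_used, each = p),
    status = rep(ifelse(x$ok, "converged", "unfit"), each = p),
    stringsAsFactors = FALSE
  )
}
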