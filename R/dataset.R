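#' Construct a longitudinal methylation dataset
#'
#' Pairs a CpG-by-observation methylation matrix with a long-format sample
#' sheet (one row per observation) and validates their consistency. Each
#' observation belongs to an individual (the clustering unit); the exposure
#' is an individual-level binary variable.
#'
#' @param beta numeric matrix, CpGs in rows (rownames = CpG ids),
#'   observations in columns (colnames = observation ids). Values are
#'   methylation beta values; `NA` marks missing cells.
#' @param samples data frame with columns `observation_id`, `individual_id`,
#'   `age`, `exposure` and optionally further covariate columns. Row order
#'   defines the canonical observation order; `beta` columns are aligned to
#'   it.
#' @param validate run consistency checks (default `TRUE`).
#' @return an object of class `longitudinal_dataset`: a list with elements
#'   `beta`, `samples`, `cpg_ids`, `n_individuals`, `n_obs` and
#'   `obs_per_individual`.
#' @export
longitudinal_dataset <- function(beta, samples, validate = TRUE) {
  beta <- as.matrix(beta)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  required <- c("observation_id", "individual_id", "age", "exposure")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    stop("sample sheet lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  samples$observation_id <- as.character(samples$observation_id)
  samples$individual_id <- as.character(samples$individual_id)

  if (is.null(colnames(beta))) {
    stop("beta matrix must carry observation ids as column names", call. = FALSE)
  }
  not_in_beta <- setdiff(samples$observation_id, colnames(beta))
  not_in_sheet <- setdiff(colnames(beta), samples$observation_id)
  if (length(not_in_beta) || length(not_in_sheet)) {
    stop("observation ids do not align between beta matrix and sample sheet; ",
         if (length(not_in_beta))
           paste0("missing from beta: ",
                  paste(utils::head(not_in_beta, 5), collapse = ", "), ". "),
         if (length(not_in_sheet))
           paste0("missing from sample sheet: ",
                  paste(utils::head(not_in_sheet, 5), collapse = ", ")),
         call. = FALSE)
  }
  beta <- beta[, samples$observation_id, drop = FALSE]

  obj <- structure(
    list(
      beta = beta,
      samples = samples,
      cpg_ids = rownames(beta),
      n_individuals = length(unique(samples$individual_id)),
      n_obs = nrow(samples),
      obs_per_individual = table(samples$individual_id)
    ),
    class = "longitudinal_dataset"
  )
  if (validate) validate_dataset(obj)
  obj
}

#' Validate a longitudinal dataset
#'
#' Checks the structural invariants: aligned observation ids, numeric and
#' finite (or `NA`) methylation values, finite ages, binary exposure constant
#' within each individual. Errors name the offending column or individual.
#'
#' @param x a `longitudinal_dataset`.
#' @return `x`, invisibly, on success.
#' @export
validate_dataset <- function(x) {
  stopifnot(inherits(x, "longitudinal_dataset"))
  s <- x$samples
  if (!identical(colnames(x$beta), s$observation_id)) {
    stop("beta columns are not aligned to the sample sheet order", call. = FALSE)
  }
  if (anyDuplicated(s$observation_id)) {
    stop("duplicated observation_id: ",
         s$observation_id[duplicated(s$observation_id)][1], call. = FALSE)
  }
  if (!is.numeric(x$beta)) {
    stop("beta matrix must be numeric", call. = FALSE)
  }
  bad <- which(!is.na(x$beta) & !is.finite(x$beta), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-finite methylation value at CpG ", rownames(x$beta)[bad[1, 1]],
         ", observation ", colnames(x$beta)[bad[1, 2]], call. = FALSE)
  }
  if (!is.numeric(s$age) || any(!is.finite(s$age))) {
    stop("`age` must be numeric and finite for every observation", call. = FALSE)
  }
  if (!all(s$exposure %in% c(0, 1))) {
    stop("`exposure` must be binary 0/1", call. = FALSE)
  }
  per_ind <- tapply(s$exposure, s$individual_id, function(z) length(unique(z)))
  if (any(per_ind > 1)) {
    stop("exposure varies within individual ",
         names(per_ind)[which(per_ind > 1)[1]],
         "; the exposure is individual-level", call. = FALSE)
  }
  invisible(x)
}

#' @exportS3Method base::print
print.longitudinal_dataset <- function(x, ...) {
  cat("longitudinal_dataset:", length(x$cpg_ids), "CpGs x", x$n_obs,
      "observations,", x$n_individuals, "individuals\n")
  cat("  ages:", paste(sort(unique(round(x$samples$age, 3))), collapse = ", "), "\n")
  cat("  exposed individuals:",
      sum(tapply(x$samples$exposure, x$samples$individual_id, max)), "\n")
  n_miss <- sum(is.na(x$beta))
  if (n_miss) cat("  missing beta cells:", n_miss, "\n")
  invisible(x)
}
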