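#' Build the longitudinal design matrix and cluster index
#'
#' The design has exactly the columns intercept, exposure, centred age,
#' exposure x centred age, then any covariates named in the configuration.
#' Age is centred at `age_origin` (default: minimum age present), so the
#' exposure main effect is the group difference at baseline and the
#' interaction is the difference in yearly slope.
#'
#' @param dataset a [longitudinal_dataset()].
#' @param config an [analysis_config()].
#' @return a list with elements `X` (numeric matrix with column names),
#'   `clusters` (a `cluster_index`: factor of individual ids plus row
#'   indices per cluster) and `age_origin`.
#' @export
build_design <- function(dataset, config = analysis_config()) {
  stopifnot(inherits(dataset, "longitudinal_dataset"))
  s <- dataset$samples
  origin <- config$age_origin %||% min(s$age)
  age_c <- s$age - origin
  X <- cbind(`(Intercept)` = 1, exposure = s$exposure,
             age = age_c, `exposure:age` = s$exposure * age_c)
  for (cv in config$covariates) {
    if (!cv %in% names(s)) {
      stop("covariate `", cv, "` named in the config is absent from the ",
           "sample sheet", call. = FALSE)
    }
    v <- s[[cv]]
    if (!is.numeric(v)) {
      stop("covariate `", cv, "` must be numeric", call. = FALSE)
    }
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  check_full_rank(X)
  list(X = X, clusters = cluster_index(s$individual_id), age_origin = origin)
}

check_full_rank <- function(X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "),
         " (e.g. a constant exposure or duplicated covariate)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Cluster index mapping individuals to observation rows
#'
#' @param individual_id character/factor vector, one entry per observation.
#' @return object of class `cluster_index`: list with `id` (factor),
#'   `rows` (list of row indices per cluster), `m`, `sizes`.
#' @export
cluster_index <- function(individual_id) {
  f <- factor(individual_id, levels = unique(individual_id))
  rows <- split(seq_along(f), f)
  structure(list(id = f, rows = rows, m = nlevels(f),
                 sizes = lengths(rows)),
            class = "cluster_index")
}
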