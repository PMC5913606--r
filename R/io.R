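detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (!grepl("\t", header) && grepl(",", header)) "," else "\t"
}

read_table_auto <- function(path) {
  sep <- detect_sep(path)
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = "NA",
                    comment.char = "", quote = "\"")
}

#' Read a methylation matrix and sample sheet from delimited text
#'
#' The beta matrix is TSV (comma autodetected) with first column `cpg_id`
#' and one column per observation; the sample sheet is long format with one
#' row per observation and columns `observation_id`, `individual_id`, `age`,
#' `exposure` plus optional covariates.
#'
#' @param beta_path path to the methylation matrix file.
#' @param samples_path path to the sample sheet file.
#' @return a validated [longitudinal_dataset()].
#' @export
read_dataset <- function(beta_path, samples_path) {
  for (p in c(beta_path, samples_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  braw <- read_table_auto(beta_path)
  if (!ncol(braw) >= 2 || names(braw)[1] != "cpg_id") {
    stop("beta matrix must have a leading `cpg_id` column", call. = FALSE)
  }
  cpg_ids <- as.character(braw[[1]])
  vals <- braw[, -1, drop = FALSE]
  non_num <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(non_num)) {
    stop("non-numeric methylation values in column(s): ",
         paste(utils::head(non_num, 5), collapse = ", "), call. = FALSE)
  }
  beta <- as.matrix(vals)
  rownames(beta) <- cpg_ids
  samples <- read_table_auto(samples_path)
  longitudinal_dataset(beta, samples)
}

#' Write a longitudinal dataset to delimited text
#'
#' Writes the beta matrix and sample sheet as TSV with full floating-point
#' precision so that [read_dataset()] round-trips to an identical dataset.
#'
#' @param dataset a `longitudinal_dataset`.
#' @param beta_path,samples_path output paths.
#' @return the two paths, invisibly.
#' @export
write_dataset <- function(dataset, beta_path, samples_path) {
  stopifnot(inherits(dataset, "longitudinal_dataset"))
  bdf <- data.frame(cpg_id = dataset$cpg_ids, stringsAsFactors = FALSE)
  mat <- dataset$beta
  for (j in seq_len(ncol(mat))) bdf[[colnames(mat)[j]]] <- mat[, j]
  write_delim_full(bdf, beta_path)
  write_delim_full(dataset$samples, samples_path)
  invisible(c(beta_path, samples_path))
}

#' Write a result table to delimited text
#'
#' One row per CpG x strategy x parameter, deterministic column order, full
#' floating-point precision (re-reading reproduces every value exactly).
#'
#' @param results a non-empty result data frame as returned by
#'   [as_result_table()] and the batch fitters.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) == 0) {
    stop("refusing to write an empty result table", call. = FALSE)
  }
  lead <- intersect(
    c("cpg_id", "strategy", "parameter", "timepoint", "estimate", "se",
      "statistic", "p_value", "n_used", "m_used", "status", "hit"),
    names(results))
  results <- results[, c(lead, setdiff(names(results), lead)), drop = FALSE]
  write_delim_full(results, path)
  invisible(path)
}

#' Read a result table written by [write_results()]
#' @param path path to the file.
#' @return a data frame.
#' @export
read_results <- function(path) {
  read_table_auto(path)
}
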