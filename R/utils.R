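`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a child seed from a master seed and counters
#'
#' Deterministic counter-based seed derivation so that replicate streams are
#' reproducible and non-overlapping regardless of execution order. The result
#' is always a positive integer below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param counter integer counter (e.g. replicate index).
#' @param salt integer stream discriminator.
#' @return a single integer usable with [set.seed()].
#' @export
derive_seed <- function(master, counter = 0L, salt = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483629 # largest prime < 2^31
  s <- (abs(master) %% m)
  s <- (s * 48271 + counter * 1299721 + salt * 7919 + 1) %% m
  as.integer(s %% 2147483646 + 1)
}

fmt_num <- function(x) {
  # full-precision, locale-independent formatting for round-trippable output
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

write_delim_full <- function(df, path, sep = "\t") {
  cols <- lapply(df, function(col) {
    if (is.double(col)) fmt_num(col) else as.character(col)
  })
  lines <- do.call(paste, c(cols, sep = sep))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(names(df), collapse = sep), lines), con)
  invisible(path)
}
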