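#' Round half up
#'
#' Rounds to the given number of digits with ties going away from zero for
#' positive input (128/377 * 100 reports as 34), unlike base R's
#' round-half-even. Used for all reported integer percentages.
#'
#' @param x non-negative numeric vector.
#' @param digits decimal digits to keep.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Stable JSON writer: unboxed scalars, full precision, sorted-by-insertion
# keys so re-runs are byte-identical.
.writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

.stop <- function(class, fmt, ...) {
  stop(structure(class = c(class, "mcwoundError", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}
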