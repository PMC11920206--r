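#' Round half away from zero
#'
#' Rounding as used for printed genomic interval sizes (kb values): exact
#' halves round up, unlike [base::round()]'s round-half-even. Only relevant at
#' the last printed digit.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(structure(class = c("fmscan_invalid_parameter", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_invalid(name, " must be a single probability in [0, 1]")
  invisible(x)
}

assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x))
    stop_invalid(name, " must be a single nonnegative integer")
  invisible(x)
}
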