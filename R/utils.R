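#' Round half away from zero
#'
#' Reporting-layer rounding used for logBB and other printed quantities.
#' Unlike [base::round()] (banker's rounding), exact halves move away from
#' zero, matching how the source tables were produced.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @examples
#' round_half_away(c(0.705, -0.705), 2)
#' @export
round_half_away <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Stop with a consistent error class so callers can test on it.
#' @keywords internal
abort <- function(msg, class = "cnstriage_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' @keywords internal
assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    abort(sprintf("`%s` must be a single integer >= %d", name, min),
          "cnstriage_invalid_spec")
  as.integer(x)
}

#' @keywords internal
assert_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max)
    abort(sprintf("`%s` must be a single finite number in [%g, %g]",
                  name, min, max), "cnstriage_invalid_spec")
  as.numeric(x)
}

# Population standard deviation (divisor n, not n - 1).
#' @keywords internal
sd_pop <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}
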