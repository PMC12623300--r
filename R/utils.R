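#' Round half away from zero
#'
#' Percentages in concordance reports are rounded half away from zero
#' (92.7 -> 93, 98.5 -> 99), matching the usual clinical-report convention
#' rather than [base::round()]'s banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep (default 0).
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' round_half_away(c(92.7, 98.5, 90.8))
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# internal: stop with a classed condition so callers/tests can target errors
abort_panometry <- function(msg, class) {
  rlang::abort(msg, class = c(class, "panometry_error"))
}

# internal: check a scalar against a predicate, with a readable message
check_scalar <- function(x, name, ok, what) {
  if (length(x) != 1 || is.na(x) || !ok(x)) {
    abort_panometry(
      sprintf("`%s` must be %s (got %s).", name, what, paste(format(x), collapse = ", ")),
      "panometry_invalid_argument"
    )
  }
  invisible(x)
}

# internal: run code under a local RNG stream seeded by `seed`; the caller's
# RNG state is untouched (no hidden global state leaks between studies)
with_local_seed <- function(seed, code) {
  check_scalar(seed, "seed", function(s) s == trunc(s), "a single integer")
  withr::with_seed(as.integer(seed), code)
}

# internal: does `x` name columns present in `data`?
check_columns <- function(data, cols, fn) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort_panometry(
      sprintf("`%s()` requires column(s) %s.", fn, paste0("`", missing, "`", collapse = ", ")),
      "panometry_missing_column"
    )
  }
  invisible(data)
}
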