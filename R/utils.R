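`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(..., call. = FALSE)

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_config(sprintf("'%s' must be a probability in [0, 1]", name))
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop_config(sprintf("'%s' must be an integer >= %d", name, min))
  invisible(as.integer(x))
}

#' Round half away from zero
#'
#' Deterministic half-up rounding used wherever an index formula calls for
#' rounding; avoids the round-half-to-even behaviour of [base::round()].
#' @param x numeric vector.
#' @return rounded integer vector.
#' @keywords internal
round_half_up <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# logistic cdf shorthand used across the package
sigmoid <- function(x) 1 / (1 + exp(-x))

# matrix -> EBImage convention is identical for square ops; resize/affine take
# the first dim as 'w'. Helper kept so the convention lives in one place.
as_ebimage <- function(m) m
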