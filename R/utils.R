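# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

clamp01 <- function(x) pmin(1, pmax(0, x))

is_fraction <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)

check_fraction <- function(x, name) {
  if (!is_fraction(x)) stopf("`%s` must be numeric in [0, 1]", name)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
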