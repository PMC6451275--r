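# Internal helpers shared across modules.

# Round half away from zero (a.k.a. commercial rounding). Base R's round()
# rounds half to even, which would turn 194.775 * deaths into the wrong
# whole-death count for some published cells.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
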