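# Internal helpers shared across modules.

# Deterministic substream seed derived from a master seed and a text label.
# Keeps all derived seeds inside the 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 2654435761) %% 2147483563) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= min && x == as.integer(x)
}

is_fraction <- function(x) {
  is.numeric(x) && !anyNA(x) && all(x >= 0) && all(x <= 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Render an exact rational as fixed-precision decimal (rates are kept as
# integer numerator/denominator internally and only rendered for output).
render_rate <- function(num, den, digits = 3) {
  ifelse(den == 0, NA_real_, round(num / den, digits))
}
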