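# internal helpers

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state;
# seed = NULL means "use the current RNG stream".
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

stopifnot_scalar_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (strict && x <= min) abort(sprintf("`%s` must be > %g.", name, min))
  if (!strict && x < min) abort(sprintf("`%s` must be >= %g.", name, min))
  invisible(x)
}
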