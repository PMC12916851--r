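# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# user's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stage seed from a master seed by a fixed offset, kept within the
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% 2147483647L)
}

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integerish = FALSE, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x)
  if (ok && integerish) ok <- abs(x - round(x)) < 1e-8
  if (ok) {
    ok <- if (strict) x > lower && x < upper else x >= lower && x <= upper
  }
  if (!ok) {
    stopf("`%s` must be a %s in %s%s, %s%s; got %s", name,
          if (integerish) "single integer" else "single number",
          if (strict) "(" else "[", format(lower),
          format(upper), if (strict) ")" else "]",
          paste(format(x), collapse = ", "))
  }
  invisible(x)
}

round1 <- function(x) round(x, 1)
round3 <- function(x) round(x, 3)
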