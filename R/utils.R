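## Internal helpers shared across modules.

#' Derive a per-animal (or per-stage) RNG seed from a master seed
#'
#' A counter-based derivation scheme: the seed for animal `index` of stream
#' `stream` (a group or pipeline-stage name) depends only on
#' `(master, stream, index)`, so cohorts are bit-reproducible and an animal's
#' seed never changes when other animals or groups are added. All arithmetic
#' stays below 2^53 (exact in doubles, platform independent) and the result is
#' a valid positive 32-bit seed.
#'
#' @param master Master seed (integer).
#' @param stream Character stream label.
#' @param index Counter within the stream.
#' @return A positive integer seed below 2^31.
#' @export
derive_animal_seed <- function(master, stream, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  ch <- utf8ToInt(as.character(stream))
  h <- sum(ch * seq_along(ch)) %% 65011
  s <- ((as.numeric(master) %% 65011) * 33013 + h * 4099 + as.numeric(index) * 7919)
  as.integer(s %% 2147483629) + 1L
}

## internal alias
derive_seed <- derive_animal_seed

## Evaluate expr with a locally seeded RNG; the caller's RNG state is untouched.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf("`%s` = %s is outside its allowed range", name, format(x)))
  }
  invisible(x)
}

is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
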