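#' @keywords internal
"_PACKAGE"

# Run `code` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored on exit so simulation helpers never leak global
# RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
    set.seed(seed)
  }
  force(code)
}

# Derive a reproducible child seed for stage `offset` from one master seed,
# kept inside the 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647L)
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == floor(x) && x >= 0
}

is_prob <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x <= 1
}
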