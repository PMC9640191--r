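# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. All stochastic operations in the package route through this,
# which is what makes generators pure functions of (parameters, seed).
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
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a stream-specific child seed from a global seed. Keeps every derived
# seed a valid 32-bit integer.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + sum(utf8ToInt(as.character(stream)))) %% 2147483647)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0", name))
  invisible(x)
}
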