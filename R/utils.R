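# internal helpers shared across modules

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All user-facing determinism contracts go
# through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% 2147483647L))
  }
  force(expr)
}

stop_f <- function(...) stop(sprintf(...), call. = FALSE)

warn_f <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
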