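# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. Every generator and every seeded
# procedure in the package goes through this, so no call mutates global
# RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic sub-seed from a base seed plus string/integer context
# (e.g. sample and gene ids), kept below 2^31 - 1. Used so partial reruns
# of grouped computations reproduce the same draws.
derive_seed <- function(seed, ...) {
  parts <- unlist(lapply(list(...), as.character))
  h <- as.double(seed %% 2147483647L)
  for (p in parts) {
    for (v in utf8ToInt(p)) h <- (h * 31 + v) %% 2147483647
  }
  as.integer(h)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

check_prob <- function(x, name, allow_one = TRUE) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) ||
      any(if (allow_one) x > 1 else x >= 1)) {
    stop(sprintf("`%s` must be in [0, %s]", name, if (allow_one) "1" else "1)"),
         call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
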