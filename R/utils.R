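# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
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
  force(expr)
}

# Derive a child seed < 2^31 from a parent seed and an index, deterministically.
derive_seed <- function(seed, index) {
  (as.numeric(seed) * 1000003 + as.numeric(index) * 7919) %% 2147483629 + 1
}

# Canonical key for an unordered electrode pair, e.g. "0-1".
pair_key <- function(a, b) {
  stopifnot(a != b)
  paste(min(a, b), max(a, b), sep = "-")
}

# The C(5,2) = 10 electrode pairs in canonical order.
all_pairs <- function() {
  out <- list()
  for (a in 0:3) for (b in (a + 1):4) out[[length(out) + 1]] <- c(a, b)
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_positive_spectrum <- function(x, what = "impedance") {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("%s must be positive and finite", what), call. = FALSE)
  }
  invisible(x)
}
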