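# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG seeded with `seed`, restoring any
# pre-existing global .Random.seed afterwards. All stochastic operations in
# the package flow through this so no function touches global random state.
with_local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  expr
}

abort_invalid <- function(msg, class = "ecgtriage_invalid_argument") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_invalid(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || x > upper) {
    abort_invalid(sprintf("`%s` = %g is outside [%g, %g]", name, x, lower, upper))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  check_scalar_number(x, name, lower = lower)
  if (x != as.integer(x)) {
    abort_invalid(sprintf("`%s` must be an integer, got %g", name, x))
  }
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
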