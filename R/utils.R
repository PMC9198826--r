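# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG state
#'
#' Runs `code` with the global RNG seeded at `seed`, restoring the caller's
#' RNG state afterwards so library code never clobbers a user's stream.
#' @noRd
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("`%s` must be a single probability in [0, 1]", name)
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stopf("`%s` must be a single integer >= %d", name, min)
  invisible(as.integer(x))
}

# Numerically safe sigmoid / binary cross-entropy.
sigmoid <- function(x) 1 / (1 + exp(-pmin(pmax(x, -30), 30)))

bce <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}
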