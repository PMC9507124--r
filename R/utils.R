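# Internal helpers: seeded sub-streams and argument checks.

#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from one user-visible seed. Stages and
#' per-embryo draws use named sub-streams derived deterministically from
#' `(seed, key...)` so that, e.g., adding embryos to a cohort never shifts the
#' draws of existing embryos, and changing one pipeline stage's consumption of
#' random numbers cannot silently alter another stage.
#'
#' @param seed Integer master seed.
#' @param ... Keys (characters or integers) naming the sub-stream.
#' @return An integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @keywords internal
substream_seed <- function(seed, ...) {
  keys <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  m <- 2147483647  # 2^31 - 1, prime
  h <- (as.numeric(seed) %% m + m) %% m
  for (code in utf8ToInt(keys)) {
    h <- (h * 131 + code) %% m
  }
  # avoid 0; keep strictly below 2^31
  as.integer(h %% (m - 1L) + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_substream <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_bad <- function(...) stop(..., call. = FALSE)

check_scalar_number <- function(x, name, positive = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_bad(sprintf("'%s' must be a single finite number", name))
  }
  if (positive && x <= 0) stop_bad(sprintf("'%s' must be > 0", name))
  if (integer && x != round(x)) stop_bad(sprintf("'%s' must be an integer", name))
  invisible(x)
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_bad(sprintf("'%s' must be a probability in [0, 1]", name))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
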