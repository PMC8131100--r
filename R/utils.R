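# Internal helpers: argument checks and deterministic seed fan-out.

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("gemcm_invalid_argument", "error")))
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop_invalid(name, " must be a single integer >= ", min, " (got ", deparse(x), ")")
  as.integer(x)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         lower_open = FALSE, upper_open = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop_invalid(name, " must be a single finite number")
  lo_ok <- if (lower_open) x > lower else x >= lower
  hi_ok <- if (upper_open) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_invalid(name, " = ", x, " is outside the allowed range ",
                 if (lower_open) "(" else "[", lower, ", ", upper,
                 if (upper_open) ")" else "]")
  as.numeric(x)
}

# Deterministic seed splitting: one user-facing seed fans out to per-stage,
# per-unit sub-seeds so that subject-level work can be reordered or
# parallelised without changing results.  Linear-congruential style mixing,
# kept strictly inside the 32-bit signed-integer range R requires.
split_seed <- function(seed, stage, index = 0L) {
  seed <- check_count(seed, "seed", min = 0L)
  stage_code <- sum(utf8ToInt(as.character(stage))) %% 99991L
  v <- (as.double(seed) * 48271 + stage_code * 7919 + as.double(index) * 104729)
  as.integer(v %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
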