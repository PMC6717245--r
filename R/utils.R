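# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cfg <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_cfg("'%s' must be a single finite number", name)
  if (strict_lower && x <= lower)
    stop_cfg("'%s' must be > %g", name, lower)
  if (!strict_lower && x < lower)
    stop_cfg("'%s' must be >= %g", name, lower)
  if (strict_upper && x >= upper)
    stop_cfg("'%s' must be < %g", name, upper)
  if (!strict_upper && x > upper)
    stop_cfg("'%s' must be <= %g", name, upper)
  invisible(x)
}

# Deterministic per-stage substream: a single global seed drives every stage,
# each stage hashing its label into an offset so streams are independent yet
# reproducible. Offsets stay below 2^31 - 1.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# population variance (divide by n, not n-1)
pop_var <- function(x) mean((x - mean(x))^2)
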