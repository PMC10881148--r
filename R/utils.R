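# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

check_scalar <- function(x, name, lo = -Inf, hi = Inf,
                         lo_open = FALSE, hi_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  ok_lo <- if (lo_open) x > lo else x >= lo
  ok_hi <- if (hi_open) x < hi else x <= hi
  if (!ok_lo || !ok_hi) {
    stop(sprintf(
      "`%s` = %g is outside %s%g, %g%s", name, x,
      if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]"
    ), call. = FALSE)
  }
  x
}

check_count <- function(x, name, min = 0L) {
  check_scalar(x, name, lo = min)
  if (x != round(x)) stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  as.integer(x)
}

# Fold a coordinate back into [lo, hi] by reflection.
reflect_into <- function(p, lo, hi) {
  width <- hi - lo
  if (width <= 0) stop("degenerate reflection interval")
  q <- (p - lo) %% (2 * width)
  ifelse(q > width, 2 * width - q, q) + lo
}
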