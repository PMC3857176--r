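#' @keywords internal
"_PACKAGE"

# Round half away from zero at a given number of decimals. Base round() uses
# round-half-even, which would send an index of 0.25 to 0.2; network exports
# and histogram binning need the conventional half-up rule.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. A NULL seed leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ws <- function(...) stop(..., call. = FALSE)
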