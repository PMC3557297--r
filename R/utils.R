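# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Deterministic child-seed derivation: fold integer labels into the top-level
# seed with a Lehmer-style multiplier, modulo the Mersenne prime 2^31 - 1.
# All intermediates stay below 2^53, so the arithmetic is exact in doubles.
# Keyed only on the labels, never on iteration order.
derive_seed <- function(seed, ...) {
  labels <- c(...)
  s <- (abs(as.numeric(seed)) + 1) %% 2147483647
  for (x in labels) {
    s <- (s * 48271 + (abs(as.numeric(x)) %% 2147483647)) %% 2147483647
  }
  as.integer(s)
}

# Classed conditions so the CLI can map error families to exit codes.
resa_error <- function(message, class) {
  stop(structure(
    class = c(class, "resa_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

config_error <- function(message) resa_error(message, "resa_config_error")
parse_error <- function(message) resa_error(message, "resa_parse_error")

# Single centralized percentile convention: linear interpolation between order
# statistics with plotting position (k-1)/(m-1) (quantile type 7).
pctl <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
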