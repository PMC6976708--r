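# Internal helpers shared across the package.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. seed = NULL means "use the current stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    sg_stop("`seed` must be a single finite number or NULL", "sgmatch_bad_seed")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible sub-seed from a base seed and a counter
#'
#' Counter-based scheme (a fixed affine map modulo a Mersenne prime) so that
#' independent parts of a simulation each get their own stream: adding new
#' scenarios or iterations never perturbs seeds already assigned. The result
#' is always a positive integer below 2^31.
#'
#' @param base_seed single integer-valued number.
#' @param index nonnegative integer counter (which sub-stream).
#' @return a single integer usable with [set.seed()].
#' @examples
#' derive_seed(1, 1)
#' derive_seed(1, 2)
#' @export
derive_seed <- function(base_seed, index) {
  stopifnot(is.numeric(base_seed), length(base_seed) == 1L, is.finite(base_seed),
            is.numeric(index), length(index) == 1L, index >= 0)
  s <- as.double(base_seed) %% 2147483647
  as.integer(((s * 48271 + as.double(index) * 16807) %% 2147483629) + 1)
}

# Classed error so callers can distinguish package failures programmatically.
sg_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "sgmatch_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
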