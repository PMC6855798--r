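# Shared internal helpers.

# Clamp correlations away from +/-1 so that atanh stays finite.  The limit
# only bites for |r| >= 1 - 1e-7, i.e. numerically identical series.
r_clamp_limit <- 1 - 1e-7

clamp_r <- function(r, limit = r_clamp_limit) {
  pmin(pmax(r, -limit), limit)
}

#' Fisher z-transform of a correlation
#'
#' `fisher_z()` computes `atanh(r)` after clamping `|r|` to `1 - 1e-7` so
#' that perfectly correlated series map to a large finite value rather than
#' infinity.  `inv_fisher_z()` is `tanh()`.
#'
#' @param r Correlation value(s) in `[-1, 1]`.
#' @param z Fisher-z value(s).
#' @return Numeric vector of the same length.
#' @examples
#' fisher_z(0.5)
#' inv_fisher_z(fisher_z(0.5))
#' @export
fisher_z <- function(r) atanh(clamp_r(r))

#' @rdname fisher_z
#' @export
inv_fisher_z <- function(z) tanh(z)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so generators do not perturb the global stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
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

# Deterministic sub-stream seeds derived from a global seed, kept within
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% .Machine$integer.max)
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}
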