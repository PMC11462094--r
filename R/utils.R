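# Internal helpers shared across modules.

#' Percentage of a count over a denominator
#'
#' Convenience used throughout reporting: `100 * n / d`, optionally rounded.
#' Printed study-style proportions use one decimal place.
#'
#' @param n Numerator (count).
#' @param d Denominator.
#' @param digits Decimal places to round to, or `NULL` for full precision.
#' @return Numeric percentage.
#' @export
#' @examples
#' pct(423, 1255)      # 33.7
#' pct(26.9, 30)       # 89.7
pct <- function(n, d, digits = 1) {
  stopifnot(is.numeric(n), is.numeric(d))
  out <- 100 * n / d
  if (!is.null(digits)) out <- round(out, digits)
  out
}

# Location parameter m such that E[max(0, N(m, sd))] equals `target` (> 0).
# E[max(0, X)] = m * pnorm(m/sd) + sd * dnorm(m/sd) is strictly increasing in m
# and spans (0, Inf), so the root is unique.
censored_normal_location <- function(target, sd) {
  stopifnot(target > 0, sd > 0)
  f <- function(m) m * stats::pnorm(m / sd) + sd * stats::dnorm(m / sd) - target
  stats::uniroot(f, lower = target - 10 * sd, upper = target + sd,
                 extendInt = "upX", tol = 1e-10)$root
}

# Run `expr` with the global RNG seeded at `seed` (when non-NULL), restoring
# the caller's RNG state afterwards so fits do not perturb user simulations.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
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

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a consistent prefix naming the offending row of an input file
row_error <- function(row, ...) {
  stop("row ", row, ": ", ..., call. = FALSE)
}
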