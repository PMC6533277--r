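# Shared internal helpers.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so library functions that need reproducible draws do not
#' disturb the session stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Derive a bounded sub-seed for a named generation stage from a master seed.
# Keeps independent stages on independent streams so e.g. covariate draws do
# not move when the gene count changes.
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(stage) * 7919L
}

#' Two-tailed p-value for a Pearson correlation via the Fisher z transform
#'
#' `p = 2 * pnorm(-|atanh(r)| * sqrt(n - 3))`, the asymptotic normal test on
#' the z-transformed correlation.
#'
#' @param r Correlation(s) in `[-1, 1]`.
#' @param n Number of paired observations (must be at least 4).
#' @return Two-tailed p-value(s).
#' @export
#' @examples
#' fisher_z_p(0.5, 28)
fisher_z_p <- function(r, n) {
  if (any(n < 4)) stop("Fisher z p-value requires n >= 4")
  r <- pmin(pmax(r, -1), 1)
  p <- 2 * pnorm(-abs(atanh(r)) * sqrt(n - 3))
  p[abs(r) >= 1] <- 0
  p
}

geometric_mean <- function(x) exp(mean(log(x)))

# Stop with a compact message listing offending items.
stop_listing <- function(msg, items, max_show = 8) {
  items <- unique(as.character(items))
  shown <- paste(head(items, max_show), collapse = ", ")
  if (length(items) > max_show) shown <- paste0(shown, ", ...")
  stop(msg, ": ", shown, call. = FALSE)
}
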