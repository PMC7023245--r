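# Step empirical CDFs over ddG samples: construction, evaluation, type-1
# quantiles, inverse-transform sampling and fixed-length quantile grids.
#
# Every amino-acid substitution is assumed to carry its own cumulative
# distribution of energy changes; these objects hold such distributions both
# when learned from observations and when produced by Monte-Carlo prediction.

#' Build an empirical CDF from ddG samples
#'
#' @param xs non-empty numeric vector (kcal/mol), all finite; order irrelevant.
#' @return a `ddg_ecdf`: list with sorted `values` and sample count `n`.
#' @examples
#' build_ecdf(c(2, -1, 0))
#' @export
build_ecdf <- function(xs) {
  xs <- as.numeric(xs)
  if (length(xs) == 0L) stop("cannot build an ECDF from no samples",
                             call. = FALSE)
  if (any(!is.finite(xs))) stop("non-finite sample(s)", call. = FALSE)
  structure(list(values = sort(xs), n = length(xs)), class = "ddg_ecdf")
}

#' @export
print.ddg_ecdf <- function(x, ...) {
  cat(sprintf("<ddg_ecdf> n = %d, range [%g, %g], median %g\n",
              x$n, x$values[1], x$values[x$n], ecdf_median(x)))
  invisible(x)
}

#' Evaluate the step CDF
#'
#' Right-continuous: returns the fraction of stored samples `<= x`.
#'
#' @param c a `ddg_ecdf`.
#' @param x numeric vector of evaluation points.
#' @return probabilities in `[0, 1]`.
#' @export
ecdf_eval <- function(c, x) {
  stopifnot(inherits(c, "ddg_ecdf"))
  findInterval(x, c$values) / c$n
}

#' Type-1 empirical quantile (left-continuous inverse CDF)
#'
#' Smallest stored value `v` with `ecdf_eval(c, v) >= p`; `p = 0` returns the
#' minimum.
#'
#' @param c a `ddg_ecdf`.
#' @param p probabilities in `[0, 1]` (vectorized).
#' @return ddG values (kcal/mol).
#' @export
ecdf_quantile <- function(c, p) {
  stopifnot(inherits(c, "ddg_ecdf"))
  if (any(p < 0 | p > 1 | is.na(p))) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  idx <- pmax(1L, ceiling(p * c$n))
  c$values[idx]
}

#' Inverse-transform sampling from an empirical CDF
#'
#' Draws are i.i.d. `ecdf_quantile(c, U)` with `U ~ Uniform(0, 1)`, which for
#' a step ECDF is distribution-identical to acceptance/rejection sampling
#' against the same CDF (each order statistic has mass `1/n`). Uses the
#' current R RNG stream; seed at the call site for reproducibility.
#'
#' @param c a `ddg_ecdf`.
#' @param n_draws number of draws (>= 1).
#' @return numeric vector of length `n_draws`.
#' @export
ecdf_sample <- function(c, n_draws) {
  stopifnot(inherits(c, "ddg_ecdf"), n_draws >= 1)
  ecdf_quantile(c, stats::runif(n_draws))
}

#' Fixed-length quantile grid
#'
#' Quantiles at the mid-point probabilities `p_j = (j - 0.5)/m`, `j = 1..m`;
#' the convention avoids the degenerate endpoints p = 0 and p = 1. The
#' default `m = 100` is the CDF discretization fed to the neural network.
#'
#' @param c a `ddg_ecdf`.
#' @param m grid length (>= 1).
#' @return non-decreasing numeric vector of length `m`.
#' @export
quantile_grid <- function(c, m = 100L) {
  stopifnot(m >= 1)
  ecdf_quantile(c, (seq_len(m) - 0.5) / m)
}

#' Median of an empirical CDF
#'
#' Conventional sample median: the mid value, or for even `n` the average of
#' the two central order statistics. Its sign classifies a predicted mutation
#' as stabilizing (positive) or destabilizing (negative).
#'
#' @param c a `ddg_ecdf`.
#' @return ddG in kcal/mol.
#' @export
ecdf_median <- function(c) {
  stopifnot(inherits(c, "ddg_ecdf"))
  v <- c$values; n <- c$n
  if (n %% 2L == 1L) v[(n + 1L) %/% 2L] else (v[n %/% 2L] + v[n %/% 2L + 1L]) / 2
}

#' Serialize an empirical CDF to a JSON string
#' @param c a `ddg_ecdf`.
#' @return JSON text with fields `values` and `n`.
#' @export
ecdf_to_json <- function(c) {
  jsonlite::toJSON(list(values = c$values, n = c$n),
                   auto_unbox = TRUE, digits = NA)
}

#' Rebuild an empirical CDF from its JSON form
#' @param txt JSON produced by [ecdf_to_json()].
#' @export
ecdf_from_json <- function(txt) {
  obj <- jsonlite::fromJSON(txt)
  build_ecdf(obj$values)
}
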