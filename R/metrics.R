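# Evaluation metrics and aggregation across repeated experiments.

#' Pearson product-moment correlation
#'
#' Implemented from the definition; returns `NA` (undefined) when either
#' vector has zero variance.
#'
#' @param x,y equal-length numeric vectors, `n >= 2`.
#' @return coefficient in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  n <- length(x)
  if (n < 2L) stop("need at least two pairs", call. = FALSE)
  dx <- x - mean(x); dy <- y - mean(y)
  sx <- sqrt(sum(dx * dx)); sy <- sqrt(sum(dy * dy))
  if (sx == 0 || sy == 0) return(NA_real_)
  sum(dx * dy) / (sx * sy)
}

#' Root mean square error
#'
#' @param x,y equal-length numeric vectors (kcal/mol).
#' @return RMSE in kcal/mol.
#' @export
rmse <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) == 0L) stop("need at least one pair", call. = FALSE)
  sqrt(mean((x - y)^2))
}

# Closed-form simple OLS of y on x; NA slope when x is constant.
ols_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L || stats::sd(x) == 0) {
    return(list(slope = NA_real_, intercept = NA_real_))
  }
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  list(slope = sl, intercept = mean(y) - sl * mean(x))
}

#' Aggregate evaluation reports from repeated splits
#'
#' Means and standard deviations of each metric over repeats (undefined
#' Pearson values are dropped from its mean/sd with a count), a sign
#' accuracy histogram on `[0, 1]`, and the ordinary-least-squares line of
#' Pearson against RMSE across repeats (the Pearson coefficient increases
#' linearly as the RMSE decreases, so the slope is typically negative).
#'
#' @param reports data frame from [repeated_split_experiment()] (columns
#'   `pearson`, `rmse`, `sign_accuracy`).
#' @param n_bins histogram bins on `[0, 1]` (default 20).
#' @return an `aggregate_summary` list: `n_repeats`, `mean`/`sd` lists,
#'   `n_pearson_defined`, `histogram` (`breaks`, `counts`), `pearson_vs_rmse`
#'   (`slope`, `intercept`).
#' @export
aggregate_reports <- function(reports, n_bins = 20L) {
  stopifnot(nrow(reports) >= 1L)
  pe <- reports$pearson[is.finite(reports$pearson)]
  sd0 <- function(v) if (length(v) < 2L) 0 else stats::sd(v)
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  acc <- pmin(pmax(reports$sign_accuracy, 0), 1)
  bin <- findInterval(acc, breaks, rightmost.closed = TRUE, left.open = TRUE)
  bin[bin == 0L] <- 1L  # accuracy exactly 0 falls in the first bin
  h <- list(breaks = breaks, counts = tabulate(bin, nbins = n_bins))
  structure(list(
    n_repeats = nrow(reports),
    mean = list(pearson = if (length(pe)) mean(pe) else NA_real_,
                rmse = mean(reports$rmse),
                sign_accuracy = mean(reports$sign_accuracy)),
    sd = list(pearson = if (length(pe)) sd0(pe) else NA_real_,
              rmse = sd0(reports$rmse),
              sign_accuracy = sd0(reports$sign_accuracy)),
    n_pearson_defined = length(pe),
    histogram = list(breaks = h$breaks, counts = h$counts),
    pearson_vs_rmse = ols_fit(reports$rmse, reports$pearson)),
    class = "aggregate_summary")
}

#' @export
print.aggregate_summary <- function(x, ...) {
  cat(sprintf(paste0("<aggregate_summary> %d repeats | Pearson %.4f (sd ",
                     "%.4f) | RMSE %.4f | sign accuracy %.4f\n"),
              x$n_repeats, x$mean$pearson, x$sd$pearson, x$mean$rmse,
              x$mean$sign_accuracy))
  invisible(x)
}

#' False-stable and false-unstable rates of a sign predictor
#'
#' A false-stable call predicts a stabilizing (positive) change for a
#' mutation observed to destabilize, and vice versa. Rates are fractions of
#' all scored records.
#'
#' @param predicted,observed paired ddG vectors.
#' @return list `false_stable`, `false_unstable`, `n`.
#' @export
sign_error_rates <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("length mismatch", call. = FALSE)
  }
  sp <- ddg_sign(predicted); so <- ddg_sign(observed)
  n <- length(sp)
  list(false_stable = sum(sp > 0 & so < 0) / n,
       false_unstable = sum(sp < 0 & so > 0) / n,
       n = n)
}
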