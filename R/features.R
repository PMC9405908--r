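#' Names of the nine per-node statistical time-series features
#' @export
stat_feature_names <- function() {
  c("absolute_sum_of_changes", "benford_correlation", "c3", "cid_ce",
    "longest_strike_above_mean", "variance", "standard_deviation",
    "skewness", "quantile_25")
}

benford_probs <- log10(1 + 1 / (1:9))

leading_digit <- function(x) {
  x <- abs(x)
  x <- x[x > 0]
  if (length(x) == 0) return(integer(0))
  as.integer(floor(x / 10^floor(log10(x))))
}

#' Statistical features of one node's time series
#'
#' Computes the nine named scalar features used as per-node attributes:
#' \describe{
#'   \item{absolute_sum_of_changes}{`sum |x_{i+1} - x_i|`.}
#'   \item{benford_correlation}{Pearson correlation between the empirical
#'     leading-digit frequencies of `|x|` (exact zeros dropped) and the
#'     Benford probabilities `log10(1 + 1/d)`, `d = 1..9`; defined as 0 when
#'     the series has no nonzero values or the frequencies are constant.}
#'   \item{c3}{`(1/(T - 2 lag)) * sum x_{i+2lag} x_{i+lag} x_i`, a
#'     non-linearity measure.}
#'   \item{cid_ce}{`sqrt(sum (x_{i+1} - x_i)^2)` on the z-normalized series
#'     (complexity estimate); 0 for a constant series when normalizing.}
#'   \item{longest_strike_above_mean}{longest run of consecutive values
#'     strictly above the series mean.}
#'   \item{variance, standard_deviation}{population (1/T) moments.}
#'   \item{skewness}{population standardized third moment; 0 when the
#'     variance is 0.}
#'   \item{quantile_25}{0.25 quantile with linear interpolation (type 7).}
#' }
#'
#' @param x numeric series of length T >= 3.
#' @param c3_lag lag for the `c3` statistic (default 1).
#' @param cid_normalize z-normalize before computing `cid_ce` (default TRUE).
#' @return named numeric vector of length 9, in [stat_feature_names()] order.
#' @export
statistical_features <- function(x, c3_lag = 1L, cid_normalize = TRUE) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3) stop("need a series of length >= 3")
  if (anyNA(x)) stop("series contains missing values")
  mu <- mean(x)
  v <- mean((x - mu)^2)
  s <- sqrt(v)

  asc <- sum(abs(diff(x)))

  dg <- leading_digit(x)
  benford <- if (length(dg) == 0) {
    0
  } else {
    freq <- tabulate(dg, nbins = 9) / length(dg)
    if (stats::sd(freq) == 0) 0 else stats::cor(freq, benford_probs)
  }

  c3 <- if (n <= 2 * c3_lag) {
    0
  } else {
    idx <- seq_len(n - 2L * c3_lag)
    mean(x[idx + 2L * c3_lag] * x[idx + c3_lag] * x[idx])
  }

  cid <- if (cid_normalize) {
    if (s == 0) 0 else sqrt(sum(diff((x - mu) / s)^2))
  } else {
    sqrt(sum(diff(x)^2))
  }

  above <- x > mu
  strikes <- rle(above)
  strike <- if (any(strikes$values)) max(strikes$lengths[strikes$values]) else 0L

  skw <- if (v == 0) 0 else mean((x - mu)^3) / s^3

  q25 <- unname(stats::quantile(x, 0.25, type = 7))

  out <- c(asc, benford, c3, cid, strike, v, s, skw, q25)
  names(out) <- stat_feature_names()
  if (!all(is.finite(out))) {
    stop(sprintf("non-finite feature(s): %s",
                 paste(names(out)[!is.finite(out)], collapse = ", ")))
  }
  out
}

#' Per-node statistical feature matrix of a run
#'
#' @param series T x N parcel time-series matrix.
#' @inheritParams statistical_features
#' @return N x 9 matrix; row i holds [statistical_features()] of column i.
#' @export
node_stat_features <- function(series, c3_lag = 1L, cid_normalize = TRUE) {
  series <- as.matrix(series)
  out <- t(apply(series, 2, statistical_features,
                 c3_lag = c3_lag, cid_normalize = cid_normalize))
  rownames(out) <- colnames(series)
  out
}

#' Assemble the node feature matrix
#'
#' Column-wise concatenation of the statistical feature block and (optionally)
#' a topology embedding block, yielding the `N x d` node feature matrix fed to
#' the first convolutional layer.
#'
#' @param stat_features N x p matrix of per-node statistical features.
#' @param embedding optional N x q embedding matrix (same node order).
#' @param scaler optional scaler from [fit_feature_scaler()]; when supplied,
#'   columns are standardized with these (training-split) statistics.
#' @return N x d numeric matrix, d = p + q.
#' @export
assemble_feature_matrix <- function(stat_features, embedding = NULL,
                                    scaler = NULL) {
  stat_features <- as.matrix(stat_features)
  x <- if (is.null(embedding)) {
    stat_features
  } else {
    embedding <- as.matrix(embedding)
    if (nrow(embedding) != nrow(stat_features)) {
      stop(sprintf("node count mismatch: %d statistical rows vs %d embedding rows",
                   nrow(stat_features), nrow(embedding)))
    }
    cbind(stat_features, embedding)
  }
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-finite feature at node %d, column %s",
                 bad[1, 1], colnames(x)[bad[1, 2]] %||% bad[1, 2]))
  }
  if (!is.null(scaler)) x <- scale_features(x, scaler)
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a column standardizer on training-split node features
#'
#' Computes per-column mean and standard deviation over the node rows of all
#' training graphs, so held-out graphs are standardized with training
#' statistics only.
#'
#' @param feature_list list of N x d node feature matrices (training split).
#' @return an object of class `feature_scaler` with `center` and `scale`.
#' @export
fit_feature_scaler <- function(feature_list) {
  stacked <- do.call(rbind, lapply(feature_list, as.matrix))
  center <- colMeans(stacked)
  scale <- apply(stacked, 2, stats::sd)
  scale[scale == 0] <- 1 # constant column: center only
  structure(list(center = center, scale = scale), class = "feature_scaler")
}

#' Apply a fitted feature scaler
#'
#' @param x N x d node feature matrix.
#' @param scaler a [fit_feature_scaler()] result.
#' @return standardized matrix.
#' @export
scale_features <- function(x, scaler) {
  sweep(sweep(as.matrix(x), 2, scaler$center, "-"), 2, scaler$scale, "/")
}
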