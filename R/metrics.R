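#' Model-performance statistics
#'
#' Root mean squared error, mean absolute relative error, mean bias error
#' (observed minus predicted, so over-prediction gives a negative bias) and
#' Pearson correlation, computed over paired observations and predictions.
#'
#' @param observations,predictions Equal-length numeric vectors (length >= 2).
#' @return A `metric_report`: list with `rmse`, `mare`, `mbe`, `r`, `r2`, `n`.
#' @examples
#' evaluate_metrics(c(2, 4), c(1, 5))  # RMSE 1, MBE 0, MARE 0.375
#' @export
evaluate_metrics <- function(observations, predictions) {
  if (length(observations) != length(predictions))
    stop("observations and predictions must have equal length")
  n <- length(observations)
  if (n < 2) stop("need at least two paired values")
  if (any(observations == 0))
    stop("MARE undefined: zero observation present")
  d <- observations - predictions
  rmse <- sqrt(mean(d^2))
  mare <- mean(abs(d / observations))
  mbe  <- mean(d)
  if (stats::sd(observations) == 0 || stats::sd(predictions) == 0)
    stop("correlation undefined for a constant series")
  r <- stats::cor(observations, predictions)
  structure(list(rmse = rmse, mare = mare, mbe = mbe, r = r, r2 = r^2, n = n),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> n=%d RMSE=%.4g MARE=%.4g MBE=%.4g R2=%.4g\n",
              x$n, x$rmse, x$mare, x$mbe, x$r2))
  invisible(x)
}
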