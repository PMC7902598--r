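#' Impute missing values per feature
#'
#' Replaces missing entries of each feature (column) by the mean or the
#' median of its non-missing values. Non-missing entries are untouched.
#'
#' @param x numeric matrix, samples in rows.
#' @param strategy "mean" or "median".
#' @return The matrix with no missing entries.
#' @examples
#' m <- cbind(a = c(1, NA, 3), b = c(2, 2, NA))
#' imputeMissing(m, "mean")
#' @export
imputeMissing <- function(x, strategy = c("mean", "median")) {
  strategy <- match.arg(strategy)
  x <- asFeatureMatrix(x)
  allMissing <- colSums(!is.na(x)) == 0L
  if (any(allMissing))
    stop("feature(s) entirely missing: ",
         paste(colnames(x)[allMissing], collapse = ", "))
  if (!anyNA(x)) return(x)
  fun <- if (strategy == "mean") function(v) mean(v, na.rm = TRUE)
         else function(v) median(v, na.rm = TRUE)
  for (j in which(colSums(is.na(x)) > 0L)) {
    v <- x[, j]
    v[is.na(v)] <- fun(v)
    x[, j] <- v
  }
  x
}

# IQR / (1.349 * |median|); infinite when the median is 0 so genuinely
# variable features are never dropped by a zero denominator.
robustCV <- function(v) {
  m <- median(v)
  iqr <- stats::IQR(v, type = 7)
  if (m == 0) return(if (iqr > 0) Inf else 0)
  iqr / (1.349 * abs(m))
}

#' Intensity and variation prefilter for molecular tables
#'
#' Drops low-signal features before feature selection. The intensity
#' threshold `T` is the `intensityQuantile` quantile (linear interpolation)
#' of the per-feature maxima; a feature is kept iff at least
#' `minFractionAbove` of its samples exceed `T` *and* its robust coefficient
#' of variation, IQR / (1.349 |median|), exceeds `robustCVMin`. The order of
#' surviving features is preserved and values are never rescaled.
#'
#' @param x numeric matrix with no missing values (impute first).
#' @param intensityQuantile quantile of per-feature maxima defining `T`.
#' @param minFractionAbove minimal fraction of samples that must exceed `T`.
#' @param robustCVMin minimal robust coefficient of variation.
#' @param log2 apply a log2 transform before filtering; values <= 0 are an
#'   error in that case.
#' @param intensityThreshold optional explicit threshold overriding the
#'   quantile computation (re-applying the filter at the recorded threshold
#'   is idempotent).
#' @return A list with `table` (surviving features), `dropped` (data.frame
#'   feature/reason) and `threshold` (the `T` used).
#' @export
intensityVariationFilter <- function(x, intensityQuantile = 0.25,
                                     minFractionAbove = 0.10,
                                     robustCVMin = 0.05, log2 = FALSE,
                                     intensityThreshold = NULL) {
  x <- asFeatureMatrix(x)
  if (ncol(x) == 0L || nrow(x) == 0L) stop("empty table")
  if (anyNA(x)) stop("table contains missing values; impute first")
  if (intensityQuantile < 0 || intensityQuantile > 1 ||
      minFractionAbove < 0 || minFractionAbove > 1)
    stop("quantile and fraction parameters must lie in [0,1]")
  if (robustCVMin < 0) stop("robustCVMin must be >= 0")
  if (log2) {
    if (any(x <= 0)) stop("log2 transform requires strictly positive values")
    x <- base::log2(x)
  }
  maxima <- apply(x, 2, max)
  thr <- intensityThreshold %||%
    quantile(maxima, probs = intensityQuantile, names = FALSE, type = 7)
  fracAbove <- colMeans(x > thr)
  rcv <- apply(x, 2, robustCV)
  keepInt <- fracAbove >= minFractionAbove
  keepVar <- rcv > robustCVMin
  keep <- keepInt & keepVar
  if (!any(keep))
    stop(sprintf(
      "all %d features dropped (intensity criterion failed for %d, variation for %d)",
      ncol(x), sum(!keepInt), sum(!keepVar)))
  reason <- ifelse(!keepInt & !keepVar, "intensity+variation",
                   ifelse(!keepInt, "intensity", "variation"))
  list(table = x[, keep, drop = FALSE],
       dropped = data.frame(feature = colnames(x)[!keep],
                            reason = reason[!keep],
                            stringsAsFactors = FALSE),
       threshold = thr)
}
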