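#' Train a random forest base classifier with OOB vote fractions
#'
#' Fits a classification forest (bootstrap bagging, random feature subset
#' per split) and records for every training sample the out-of-bag fraction
#' of trees voting for the positive class, the OOB tree count, and the vote
#' cutoff maximising MCC on the OOB votes ([tuneVoteCutoff()]). Each sample
#' is in the bag for about `1 - exp(-1)` of the trees and OOB for about
#' `exp(-1)`. Samples never OOB (possible at very small `nTrees`) get vote
#' 0.5 with a warning. Training is reproducible given `seed`.
#'
#' @param X numeric feature matrix, samples in rows, no missing values.
#' @param y binary 0/1 decision vector; both classes required.
#' @param nTrees number of trees (default 500).
#' @param mtry features tried per split; default `floor(sqrt(ncol(X)))`.
#' @param seed integer seed.
#' @return A [ForestModel-class].
#' @export
trainForest <- function(X, y, nTrees = 500L, mtry = NULL, seed = 1L) {
  X <- asFeatureMatrix(X)
  y <- stopIfNot01(as.integer(y))
  checkBothClasses(y, "forest training")
  if (min(table(y)) < 2L) stop("at least 2 samples per class required")
  if (anyNA(X)) stop("missing values in features; impute first")
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(X))))
  fit <- withSeed(seed, randomForest::randomForest(
    x = X, y = factor(y, levels = c(0, 1)), ntree = as.integer(nTrees),
    mtry = mtry))
  votes <- fit$votes[, "1"]
  coverage <- as.integer(fit$oob.times)
  if (any(coverage == 0L)) {
    warning(sum(coverage == 0L),
            " sample(s) never out-of-bag; their OOB vote set to 0.5")
    votes[coverage == 0L] <- 0.5
  }
  names(votes) <- rownames(X)
  tune <- tuneVoteCutoff(votes, y)
  new("ForestModel", fit = fit, nTrees = as.integer(nTrees),
      features = colnames(X), oobVotes = as.numeric(votes),
      oobCoverage = coverage, cutoff = tune$cutoff, cutoffMCC = tune$mcc,
      seed = as.integer(seed))
}

#' Predict positive-class vote fractions for new samples
#'
#' @param object a [ForestModel-class].
#' @param newdata numeric matrix containing at least the training features.
#' @param type "fraction" for the per-sample fraction of trees voting
#'   positive, "class" for 0/1 labels obtained by applying the tuned cutoff.
#' @param ... ignored.
#' @return Numeric vector in \[0,1\] (or integer 0/1 labels).
#' @export
setMethod("predict", "ForestModel", function(object, newdata,
                                             type = c("fraction", "class"),
                                             ...) {
  type <- match.arg(type)
  newdata <- asFeatureMatrix(newdata)
  missing <- setdiff(object@features, colnames(newdata))
  if (length(missing))
    stop("missing features in newdata: ", paste(missing, collapse = ", "))
  votes <- predict(object@fit,
                   newdata[, object@features, drop = FALSE],
                   type = "vote")[, "1"]
  if (type == "fraction") as.numeric(votes)
  else as.integer(votes > object@cutoff)
})
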