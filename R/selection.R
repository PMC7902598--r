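#' Sequential goodness-of-fit (SGoF) multiple-testing correction
#'
#' Iterative binomial SGoF: let F be the number of p-values at or below
#' `gamma`. While a one-sided binomial test of F successes in n trials at
#' rate `gamma` is significant at level `alpha`, the smallest undeclared
#' p-value is declared significant and F is decremented. The procedure is
#' optimised for power rather than strict false-discovery control (it
#' tolerates on the order of ten percent false positives among the
#' declarations under dense signal).
#'
#' @param pvalues numeric vector of p-values in \[0,1\].
#' @param gamma per-test significance threshold (default 0.05).
#' @param alpha level of the binomial metatest (default 0.05).
#' @return Integer count R of p-values declared significant
#'   (the R smallest ones); 0 <= R <= #\{p <= gamma\}.
#' @examples
#' sgofSelect(c(rep(0.001, 20), runif(80)))
#' @export
sgofSelect <- function(pvalues, gamma = 0.05, alpha = 0.05) {
  if (!length(pvalues)) stop("empty p-value vector")
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0,1]")
  n <- length(pvalues)
  f <- sum(pvalues <= gamma)
  r <- 0L
  while (f > 0L && pbinom(f - 1L, n, gamma, lower.tail = FALSE) <= alpha) {
    r <- r + 1L
    f <- f - 1L
  }
  r
}

#' Greedy redundancy removal along a feature ranking
#'
#' Walks the ranking from the most to the least significant feature and
#' keeps a feature iff its absolute Spearman correlation (average ranks for
#' ties) with every already-kept feature is below `rhoMax`. Stops once
#' `nKeepMax` features are kept. Kept order equals ranking order, so the
#' result is invariant to shuffles among features ranked below the last one
#' kept.
#'
#' @param ranking a `FeatureRanking` data.frame (or any data.frame with a
#'   `feature` column ordered by decreasing relevance).
#' @param X numeric matrix holding at least the ranked features.
#' @param rhoMax Spearman threshold in (0,1\] (default 0.7).
#' @param nKeepMax stop after this many kept features.
#' @return Character vector of kept feature names, in ranking order.
#' @export
greedyRedundancyFilter <- function(ranking, X, rhoMax = 0.7, nKeepMax = Inf) {
  if (rhoMax <= 0) stop("rhoMax must be positive")
  X <- asFeatureMatrix(X)
  feats <- if (is.data.frame(ranking)) ranking$feature else as.character(ranking)
  if (!all(feats %in% colnames(X)))
    stop("ranking contains features absent from the table")
  kept <- character(0)
  keptRanks <- NULL
  for (f in feats) {
    if (length(kept) >= nKeepMax) break
    rf <- rank(X[, f])
    if (length(kept)) {
      rho <- suppressWarnings(as.vector(cor(rf, keptRanks)))
      rho[is.na(rho)] <- 0  # constant feature: no usable correlation
      if (any(abs(rho) >= rhoMax)) next
    }
    kept <- c(kept, f)
    keptRanks <- cbind(keptRanks, rf)
  }
  kept
}

#' Configuration for the molecular feature-selection cascade
#'
#' @param method "utest", "mdfs1d" or "mdfs2d".
#' @param sgofGamma per-test level of the SGoF correction.
#' @param sgofAlpha metatest level of the SGoF correction.
#' @param rhoMax Spearman redundancy threshold (default 0.7).
#' @param mCap maximal number of features used for model building
#'   (default 100).
#' @param nBins,nDiscretizations,rangeParam discretization settings for the
#'   entropy filter (see [mdfsRank()]).
#' @return A list of class `selectionConfig`.
#' @export
selectionConfig <- function(method = c("utest", "mdfs1d", "mdfs2d"),
                            sgofGamma = 0.05, sgofAlpha = 0.05,
                            rhoMax = 0.7, mCap = 100L, nBins = 2L,
                            nDiscretizations = 30L, rangeParam = 1) {
  method <- match.arg(method)
  if (rhoMax <= 0 || rhoMax > 1) stop("rhoMax must lie in (0,1]")
  if (mCap < 1L) stop("mCap must be >= 1")
  cfg <- list(method = method, sgofGamma = sgofGamma, sgofAlpha = sgofAlpha,
              rhoMax = rhoMax, mCap = as.integer(mCap), nBins = as.integer(nBins),
              nDiscretizations = as.integer(nDiscretizations),
              rangeParam = rangeParam)
  class(cfg) <- "selectionConfig"
  cfg
}

#' Molecular feature selection: rank, correct, deduplicate, cap
#'
#' Composition of the full cascade applied to one molecular table: rank all
#' features ([uTestRank()] or [mdfsRank()]), keep the R most significant
#' ones according to [sgofSelect()] on the raw p-values, remove redundant
#' features with [greedyRedundancyFilter()], and cap the result at `mCap`.
#' An empty significant set yields an empty selection with a warning, not an
#' error.
#'
#' @param X numeric matrix, samples in rows (preprocessed, no missing values).
#' @param y binary 0/1 decision vector.
#' @param config a [selectionConfig()].
#' @param seed seed for the random discretizations of the entropy filter.
#' @return A [SelectedFeatureSet-class].
#' @export
selectFeatures <- function(X, y, config = selectionConfig(), seed = 1L) {
  X <- asFeatureMatrix(X)
  ranking <- switch(config$method,
    utest = uTestRank(X, y),
    mdfs1d = mdfsRank(X, y, 1L, config$nBins, config$nDiscretizations,
                      config$rangeParam, seed),
    mdfs2d = mdfsRank(X, y, 2L, config$nBins, config$nDiscretizations,
                      config$rangeParam, seed))
  nSig <- sgofSelect(ranking$p.value, config$sgofGamma, config$sgofAlpha)
  if (nSig == 0L) {
    warning("no features significant after SGoF correction; empty selection")
    return(new("SelectedFeatureSet", features = character(0),
               table = ranking[0, ], nSignificant = 0L,
               nAfterRedundancy = 0L, nFinal = 0L,
               method = config$method, config = unclass(config),
               empty = TRUE))
  }
  sig <- ranking[seq_len(nSig), , drop = FALSE]
  kept <- greedyRedundancyFilter(sig, X, config$rhoMax, config$mCap)
  final <- utils::head(kept, config$mCap)
  new("SelectedFeatureSet", features = final,
      table = sig[match(final, sig$feature), , drop = FALSE],
      nSignificant = as.integer(nSig),
      nAfterRedundancy = length(kept), nFinal = length(final),
      method = config$method, config = unclass(config), empty = FALSE)
}

#' All-relevant clinical feature selection with shadow features
#'
#' Boruta-style procedure for the heterogeneous clinical table: at each
#' iteration every still-undecided feature is paired with a shuffled shadow
#' copy, a random forest with permutation importance is trained on real +
#' shadow columns, and a feature scores a hit when its importance exceeds
#' the maximum shadow importance. From iteration 5 onwards, features are
#' confirmed (or rejected) by a two-sided binomial test on their hit counts
#' at level `alpha` with Bonferroni correction across the original features;
#' rejected features are dropped from subsequent forests.
#'
#' @param X numeric clinical matrix, samples in rows.
#' @param y binary 0/1 decision vector.
#' @param nIterations number of shadow iterations (>= 5).
#' @param alpha level of the binomial confirmation tests.
#' @param nTrees trees per iteration forest.
#' @param seed integer seed.
#' @return A list with `confirmed` (feature names ordered by decreasing mean
#'   importance), `rejected`, `tentative`, and `importance` (data.frame of
#'   mean importances and hit counts).
#' @export
shadowSelectClinical <- function(X, y, nIterations = 50L, alpha = 0.01,
                                 nTrees = 300L, seed = 1L) {
  if (nIterations < 5L) stop("nIterations must be >= 5")
  X <- asFeatureMatrix(X)
  if (ncol(X) < 2L) stop("at least 2 features required")
  y <- stopIfNot01(as.integer(y))
  checkBothClasses(y)
  feats <- colnames(X)
  nFeat <- length(feats)
  withSeed(seed, {
    hits <- stats::setNames(integer(nFeat), feats)
    tested <- stats::setNames(integer(nFeat), feats)
    activeIter <- stats::setNames(integer(nFeat), feats)
    impSum <- stats::setNames(numeric(nFeat), feats)
    status <- stats::setNames(rep("tentative", nFeat), feats)
    for (it in seq_len(nIterations)) {
      active <- feats[status != "rejected"]
      undecided <- feats[status == "tentative"]
      if (!length(undecided)) break
      shadows <- apply(X[, active, drop = FALSE], 2, sample)
      colnames(shadows) <- paste0(".shadow.", active)
      xs <- cbind(X[, active, drop = FALSE], shadows)
      fit <- randomForest::randomForest(
        x = xs, y = factor(y, levels = c(0, 1)), ntree = nTrees,
        importance = TRUE)
      imp <- randomForest::importance(fit, type = 1, scale = TRUE)[, 1]
      shadowMax <- max(imp[colnames(shadows)])
      realImp <- imp[active]
      impSum[active] <- impSum[active] + realImp
      activeIter[active] <- activeIter[active] + 1L
      hits[undecided] <- hits[undecided] +
        as.integer(realImp[undecided] > shadowMax)
      tested[undecided] <- tested[undecided] + 1L
      if (it >= 5L) {
        for (f in undecided) {
          pUp <- pbinom(hits[f] - 1L, tested[f], 0.5, lower.tail = FALSE)
          pDown <- pbinom(hits[f], tested[f], 0.5)
          if (pUp < alpha / nFeat) status[f] <- "confirmed"
          else if (pDown < alpha / nFeat) status[f] <- "rejected"
        }
      }
    }
    meanImp <- impSum / pmax(activeIter, 1)
    conf <- feats[status == "confirmed"]
    conf <- conf[order(-meanImp[conf], conf)]
    list(confirmed = conf,
         rejected = feats[status == "rejected"],
         tentative = feats[status == "tentative"],
         importance = data.frame(feature = feats, meanImportance = meanImp,
                                 hits = hits, tested = tested,
                                 status = status, row.names = NULL,
                                 stringsAsFactors = FALSE))
  })
}
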