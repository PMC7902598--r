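# Hybrid strategy over an explicit combined feature set (clinical columns +
# synthetic layer variables), minus an exclusion list. Removing a synthetic
# name drops the whole layer; synthetic variables are recomputed per fold as
# usual.
combinedStrategy <- function(clinFeats, layers, exclude = character(0),
                             selection = selectionConfig(), nTrees = 100L,
                             name = "full") {
  keepClin <- setdiff(clinFeats, exclude)
  keepLayers <- layers[!syntheticName(layers) %in% exclude]
  hybridStrategy(layers = keepLayers, selection = selection,
                 clinicalFeatures = keepClin, nTrees = nTrees, name = name)
}

repMeans <- function(records, label, metric = "auc") {
  rs <- records[records$strategy == label, ]
  as.numeric(tapply(rs[[metric]], rs$rep, mean))
}

looCore <- function(bundle, clinFeats, layers, selection, r, k, nTrees, seed,
                    estimator = "cv") {
  feats <- c(clinFeats, syntheticName(layers))
  strategies <- c(list(full = combinedStrategy(clinFeats, layers,
                                               selection = selection,
                                               nTrees = nTrees)),
                  stats::setNames(lapply(feats, function(f)
                    combinedStrategy(clinFeats, layers, exclude = f,
                                     selection = selection, nTrees = nTrees,
                                     name = paste0("minus_", f))),
                    paste0("minus_", feats)))
  if (estimator == "oob") {
    # one forest per candidate model on the whole data set, quality taken
    # from the final model's out-of-bag votes (the protocol's own device
    # for internally cross-validated estimates); r plays the role of
    # forest-seed replicates
    y <- decision(bundle)
    aucs <- vapply(seq_len(r), function(rep_) {
      vapply(strategies, function(st) {
        m <- st$fit(bundle, deriveSeed(seed, rep_))
        aucScore(oobVotes(m@finalModel), y)
      }, numeric(1))
    }, numeric(length(strategies)))
    aucs <- matrix(aucs, nrow = length(strategies),
                   dimnames = list(names(strategies), NULL))
    mFull <- aucs["full", ]
    tab <- do.call(rbind, lapply(feats, function(f) {
      d <- mFull - aucs[paste0("minus_", f), ]
      data.frame(feature = f, deltaAUC = mean(d), sd = sd(d),
                 aucWithout = mean(mFull) - mean(d), stringsAsFactors = FALSE)
    }))
  } else {
    records <- suppressWarnings(
      repeatedCV(bundle, strategies, r = r, k = k, seed = seed))
    mFull <- repMeans(records, "full")
    tab <- do.call(rbind, lapply(feats, function(f) {
      d <- mFull - repMeans(records, paste0("minus_", f))
      data.frame(feature = f, deltaAUC = mean(d), sd = sd(d),
                 aucWithout = mean(mFull) - mean(d), stringsAsFactors = FALSE)
    }))
  }
  tab <- tab[order(-tab$deltaAUC, tab$feature), ]
  rownames(tab) <- NULL
  list(fullMean = mean(mFull), fullSd = sd(mFull), table = tab)
}

#' Single-feature-removal sensitivity analysis
#'
#' For every feature of the combined hybrid model (clinical columns and
#' per-layer synthetic variables), refits and cross-validates the model with
#' that single feature removed and reports the AUC drop
#' `deltaAUC = AUC(full) - AUC(without feature)`, with the standard
#' deviation of the per-repeat paired differences. All models share the same
#' CV partitions. Note that perfectly redundant features mask each other:
#' each member of a duplicated pair gets deltaAUC near 0 despite their joint
#' importance.
#'
#' @param bundle an [OmicsBundle-class].
#' @param clinicalFeatures clinical columns of the combined model
#'   (NULL = all).
#' @param layers molecular layers contributing synthetic variables
#'   (NULL = all).
#' @param selection a [selectionConfig()] for the layer models.
#' @param r,k repeats and folds of the evaluation CV. With the "oob"
#'   estimator, `r` counts forest-seed replicates and `k` is unused.
#' @param nTrees trees per forest.
#' @param seed master seed.
#' @param estimator "cv" scores every candidate model by repeated
#'   cross-validation; "oob" scores it by the out-of-bag AUC of one forest
#'   fitted on all samples - the protocol's internal estimate, much cheaper
#'   and with no fold-sampling noise (every sample serves as internal
#'   test).
#' @return A list of class `sensitivityReport`: `fullMean`, `fullSd` (AUC of
#'   the full model over repeats) and `table` (feature, deltaAUC, sd,
#'   aucWithout) ordered by decreasing deltaAUC.
#' @export
looSensitivity <- function(bundle, clinicalFeatures = NULL, layers = NULL,
                           selection = selectionConfig(), r = 5L, k = 5L,
                           nTrees = 100L, seed = 1L,
                           estimator = c("cv", "oob")) {
  estimator <- match.arg(estimator)
  clinFeats <- clinicalFeatures %||% colnames(clinical(bundle))
  layers <- layers %||% omicsNames(bundle)
  if (length(clinFeats) + length(layers) < 2L)
    stop("the combined model needs at least 2 features")
  res <- looCore(bundle, clinFeats, layers, selection, r, k, nTrees, seed,
                 estimator)
  structure(res, class = "sensitivityReport")
}

#' @export
print.sensitivityReport <- function(x, ...) {
  cat(sprintf("Full-model AUC %.3f (sd %.3f) over CV repeats\n",
              x$fullMean, x$fullSd))
  print(x$table, digits = 3)
  invisible(x)
}

#' Recursive feature elimination over the combined hybrid model
#'
#' Starting from the full combined feature set, repeatedly removes the
#' feature with the smallest single-removal AUC drop (ties broken
#' lexicographically) and records mean and SD of the model AUC at every
#' size, down to a single feature. By default the removal importances are
#' recomputed at every step (a model is refitted for each candidate
#' removal); `recompute = FALSE` reuses the initial ranking and only
#' re-evaluates the shrinking models - much cheaper, at the cost of ignoring
#' masking changes along the path. The recommended compact model is the
#' smallest size whose mean AUC is at least the full-model mean minus one
#' full-model SD.
#'
#' @inheritParams looSensitivity
#' @param recompute recompute removal importances at every step.
#' @return A list of class `rfeTrace`: `trace` (data.frame size, removed,
#'   aucMean, aucSd; one row per model size, `removed` being the feature
#'   eliminated after evaluating that size), `recommendedSize`,
#'   `recommendedFeatures`, `fullMean`, `fullSd`.
#' @export
rfe <- function(bundle, clinicalFeatures = NULL, layers = NULL,
                selection = selectionConfig(), r = 5L, k = 5L,
                nTrees = 100L, seed = 1L, recompute = TRUE,
                estimator = c("cv", "oob")) {
  estimator <- match.arg(estimator)
  clinFeats <- clinicalFeatures %||% colnames(clinical(bundle))
  layers <- layers %||% omicsNames(bundle)
  allFeats <- c(clinFeats, syntheticName(layers))
  if (length(allFeats) < 2L) stop("at least 2 features required")
  curClin <- clinFeats; curLayers <- layers
  rows <- list(); step <- 0L
  fullMean <- NA_real_; fullSd <- NA_real_
  fixedOrder <- NULL
  evalModel <- function(cl, ly, s) {
    st <- combinedStrategy(cl, ly, selection = selection, nTrees = nTrees)
    if (estimator == "oob") {
      y <- decision(bundle)
      m <- vapply(seq_len(r), function(rep_)
        aucScore(oobVotes(st$fit(bundle, deriveSeed(s, rep_))@finalModel),
                 y), numeric(1))
    } else {
      recs <- suppressWarnings(repeatedCV(bundle, st, r = r, k = k, seed = s))
      m <- repMeans(recs, recs$strategy[1])
    }
    c(mean(m), sd(m))
  }
  repeat {
    step <- step + 1L
    size <- length(curClin) + length(curLayers)
    if (size == 1L) {
      ev <- evalModel(curClin, curLayers, deriveSeed(seed, step))
      rows[[step]] <- data.frame(size = 1L, removed = NA_character_,
                                 aucMean = ev[1], aucSd = ev[2],
                                 stringsAsFactors = FALSE)
      break
    }
    if (recompute || is.null(fixedOrder)) {
      res <- looCore(bundle, curClin, curLayers, selection, r, k, nTrees,
                     deriveSeed(seed, step), estimator)
      if (step == 1L) { fullMean <- res$fullMean; fullSd <- res$fullSd }
      tab <- res$table
      worst <- tab[order(tab$deltaAUC, tab$feature), ][1, "feature"]
      if (!recompute)
        fixedOrder <- tab[order(tab$deltaAUC, tab$feature), "feature"]
      ev <- c(res$fullMean, res$fullSd)
    } else {
      ev <- evalModel(curClin, curLayers, deriveSeed(seed, step))
      remaining <- c(curClin, syntheticName(curLayers))
      worst <- fixedOrder[fixedOrder %in% remaining][1]
    }
    rows[[step]] <- data.frame(size = size, removed = worst,
                               aucMean = ev[1], aucSd = ev[2],
                               stringsAsFactors = FALSE)
    curClin <- setdiff(curClin, worst)
    curLayers <- curLayers[syntheticName(curLayers) != worst]
  }
  trace <- do.call(rbind, rows)
  ok <- trace$aucMean >= fullMean - fullSd
  recommendedSize <- min(trace$size[ok])
  eliminatedBefore <- trace$removed[trace$size > recommendedSize]
  recommendedFeatures <- setdiff(allFeats, eliminatedBefore)
  structure(list(trace = trace, recommendedSize = recommendedSize,
                 recommendedFeatures = recommendedFeatures,
                 fullMean = fullMean, fullSd = fullSd),
            class = "rfeTrace")
}

#' @export
print.rfeTrace <- function(x, ...) {
  cat(sprintf("RFE trace (full AUC %.3f, sd %.3f); recommended size %d:\n",
              x$fullMean, x$fullSd, x$recommendedSize))
  cat(" ", paste(x$recommendedFeatures, collapse = ", "), "\n")
  print(x$trace, digits = 3)
  invisible(x)
}
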