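#' Stratified k-fold partition
#'
#' @param y binary 0/1 decision vector.
#' @param k number of folds (>= 2).
#' @param stratified preserve the class ratio in every fold (default TRUE).
#' @param seed integer seed.
#' @return A list of `k` integer vectors of test-sample indices covering
#'   `seq_along(y)` exactly once.
#' @export
cvFolds <- function(y, k = 5L, stratified = TRUE, seed = 1L) {
  y <- as.integer(y)
  if (k < 2L) stop("k must be >= 2")
  if (stratified && k > min(table(y)))
    stop("k exceeds the size of the smallest class; reduce k")
  withSeed(seed, {
    fold <- integer(length(y))
    if (stratified) {
      for (cls in unique(y)) {
        idx <- sample(which(y == cls))
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      fold[sample(seq_along(y))] <- rep_len(seq_len(k), length(y))
    }
    lapply(seq_len(k), function(i) which(fold == i))
  })
}

newStrategy <- function(name, fit, predict, cutoff) {
  structure(list(name = name, fit = fit, predict = predict, cutoff = cutoff),
            class = "cvStrategy")
}

#' @export
print.cvStrategy <- function(x, ...) {
  cat("cvStrategy:", x$name, "\n"); invisible(x)
}

constantModel <- function(value = 0.5) {
  structure(list(value = value), class = "constantModel")
}

#' Clinical-data-only modelling strategy
#'
#' Random forest on (a subset of) the clinical features; the baseline of all
#' integration comparisons.
#'
#' @param features clinical feature names to use (NULL = all; typically the
#'   confirmed set from [shadowSelectClinical()], which the protocol fixes
#'   once on the full data set).
#' @param nTrees trees of the forest.
#' @param name strategy label.
#' @return A strategy object for [repeatedCV()].
#' @export
clinicalStrategy <- function(features = NULL, nTrees = 500L, name = "clinical") {
  newStrategy(name,
    fit = function(bundle, seed) {
      x <- clinical(bundle)
      if (!is.null(features)) x <- x[, features, drop = FALSE]
      trainForest(x, decision(bundle), nTrees = nTrees, seed = seed)
    },
    predict = function(model, bundle) {
      x <- clinical(bundle)
      if (!is.null(features)) x <- x[, features, drop = FALSE]
      predict(model, x)
    },
    cutoff = function(model) model@cutoff)
}

#' Single-omics-layer modelling strategy
#'
#' Feature selection ([selectFeatures()]) followed by a random forest on the
#' selected features of one molecular layer. An empty selection yields a
#' constant 0.5 scorer for that fold (with a warning).
#'
#' @param layer layer name.
#' @param selection a [selectionConfig()].
#' @param nTrees trees of the forest.
#' @param name strategy label.
#' @return A strategy object for [repeatedCV()].
#' @export
omicsStrategy <- function(layer, selection = selectionConfig(),
                          nTrees = 500L, name = layer) {
  newStrategy(name,
    fit = function(bundle, seed) {
      x <- omicsLayer(bundle, layer)
      sel <- selectFeatures(x, decision(bundle), selection, seed = seed)
      if (sel@empty) return(constantModel())
      trainForest(x[, sel@features, drop = FALSE], decision(bundle),
                  nTrees = nTrees, seed = seed)
    },
    predict = function(model, bundle) {
      if (inherits(model, "constantModel"))
        return(rep(model$value, nSamples(bundle)))
      predict(model, omicsLayer(bundle, layer))
    },
    cutoff = function(model)
      if (inherits(model, "constantModel")) 0.5 else model@cutoff)
}

#' Early (feature-level) integration strategy
#'
#' Clinical features merged column-wise with the selected top-m features of
#' each molecular layer ([earlyMerge()]), then a single random forest on the
#' merged table.
#'
#' @param layers layer names (NULL = all layers of the bundle).
#' @param selection a [selectionConfig()] applied per layer.
#' @param clinicalFeatures clinical columns to use (NULL = all).
#' @param nTrees trees of the forest.
#' @param name strategy label.
#' @return A strategy object for [repeatedCV()].
#' @export
earlyStrategy <- function(layers = NULL, selection = selectionConfig(),
                          clinicalFeatures = NULL, nTrees = 500L,
                          name = "early") {
  buildX <- function(bundle, seed, selections = NULL) {
    x <- clinical(bundle)
    if (!is.null(clinicalFeatures)) x <- x[, clinicalFeatures, drop = FALSE]
    lys <- layers %||% omicsNames(bundle)
    sels <- list()
    for (ly in lys) {
      xm <- omicsLayer(bundle, ly)
      feats <- if (is.null(selections)) {
        sel <- selectFeatures(xm, decision(bundle), selection,
                              seed = deriveSeed(seed, match(ly, lys)))
        sels[[ly]] <- sel@features
        sel@features
      } else selections[[ly]]
      if (length(feats))
        x <- earlyMerge(x, xm[, feats, drop = FALSE])
    }
    list(x = x, selections = if (is.null(selections)) sels else selections)
  }
  newStrategy(name,
    fit = function(bundle, seed) {
      b <- buildX(bundle, seed)
      model <- trainForest(b$x, decision(bundle), nTrees = nTrees, seed = seed)
      attr(model, "selections") <- b$selections
      model
    },
    predict = function(model, bundle) {
      b <- buildX(bundle, 0L, selections = attr(model, "selections"))
      predict(model, b$x)
    },
    cutoff = function(model) model@cutoff)
}

#' Hybrid integration strategy (clinical + OOB synthetic variables)
#'
#' The package's central method: per molecular layer a forest is trained on
#' selected features and its out-of-bag positive-vote fraction becomes a
#' synthetic variable appended to the clinical table before the final
#' forest. See [hybridFit()].
#'
#' @param layers layer names (NULL = all layers of the bundle).
#' @param selection a [selectionConfig()] (or named list, one per layer).
#' @param clinicalFeatures clinical columns to use (NULL = all).
#' @param nTrees trees per forest.
#' @param syntheticSource "oob" (the method) or "inbag" (deliberately
#'   leaky in-bag vote fractions; diagnostic negative control only).
#' @param name strategy label.
#' @return A strategy object for [repeatedCV()].
#' @export
hybridStrategy <- function(layers = NULL, selection = selectionConfig(),
                           clinicalFeatures = NULL, nTrees = 500L,
                           syntheticSource = c("oob", "inbag"),
                           name = "hybrid") {
  syntheticSource <- match.arg(syntheticSource)
  newStrategy(name,
    fit = function(bundle, seed)
      hybridFit(bundle, layers = layers, selection = selection,
                clinicalFeatures = clinicalFeatures, nTrees = nTrees,
                syntheticSource = syntheticSource, seed = seed),
    predict = function(model, bundle) hybridPredict(model, bundle),
    cutoff = function(model) model@finalModel@cutoff)
}

#' Super learner (late integration) strategy
#'
#' Base models per data set are combined by a second-level model fitted on
#' their internal-cross-validated predictions. See [superLearnerFit()].
#'
#' @param bases list of base strategy objects (default: clinical plus one
#'   [omicsStrategy()] per layer, built at fit time).
#' @param combiner "nnls", "forest" or "best_k".
#' @param loops internal CV loops (the study design uses 30).
#' @param innerK internal CV folds.
#' @param kBest k for the best-k combiner.
#' @param selection default [selectionConfig()] for auto-built omics bases.
#' @param clinicalFeatures clinical columns for the auto-built clinical base.
#' @param nTrees trees per base forest.
#' @param name strategy label.
#' @return A strategy object for [repeatedCV()].
#' @export
superLearnerStrategy <- function(bases = NULL, combiner = "nnls", loops = 30L,
                                 innerK = 5L, kBest = 2L,
                                 selection = selectionConfig(),
                                 clinicalFeatures = NULL, nTrees = 500L,
                                 name = "superlearner") {
  newStrategy(name,
    fit = function(bundle, seed) {
      bs <- bases %||% c(
        list(clinicalStrategy(features = clinicalFeatures, nTrees = nTrees)),
        lapply(omicsNames(bundle), function(ly)
          omicsStrategy(ly, selection = selection, nTrees = nTrees)))
      superLearnerFit(bundle, bases = bs, loops = loops, innerK = innerK,
                      combiner = combiner, kBest = kBest, seed = seed)
    },
    predict = function(model, bundle) superLearnerPredict(model, bundle),
    cutoff = function(model) attr(model, "cutoff") %||% 0.5)
}

#' Repeated stratified cross-validation of modelling strategies
#'
#' Runs `r` repeats of `k`-fold cross validation. Every repeat draws a fresh
#' (seeded, stratified) partition shared by all strategies, so records are
#' exactly paired. Within each fold the entire pipeline of every strategy -
#' feature selection included - sees the training split only; metrics are
#' computed on the held-out fold: AUC from the raw predicted vote fractions,
#' ACC and MCC from labels at the fold's tuned cutoff.
#'
#' @param bundle an [OmicsBundle-class].
#' @param strategies one strategy object or a (preferably named) list.
#' @param r repeats (default 30).
#' @param k folds (default 5).
#' @param stratified stratify folds by class (default TRUE).
#' @param seed master integer seed.
#' @return data.frame with columns strategy, rep, fold, acc, auc, mcc
#'   (r times k rows per strategy).
#' @export
repeatedCV <- function(bundle, strategies, r = 30L, k = 5L,
                       stratified = TRUE, seed = 1L) {
  if (inherits(strategies, "cvStrategy")) strategies <- list(strategies)
  if (is.null(names(strategies)) || any(!nzchar(names(strategies))))
    names(strategies) <- vapply(strategies, `[[`, "", "name")
  if (r < 1L) stop("r must be >= 1")
  y <- decision(bundle)
  out <- vector("list", r * k * length(strategies))
  idx <- 0L
  for (rep_ in seq_len(r)) {
    folds <- cvFolds(y, k = k, stratified = stratified,
                     seed = deriveSeed(seed, rep_))
    for (fold_ in seq_len(k)) {
      test <- folds[[fold_]]
      train <- setdiff(seq_along(y), test)
      if (length(unique(y[train])) < 2L || length(unique(y[test])) < 2L)
        stop("a fold contains a single class; use stratified folds")
      bTrain <- bundle[train]; bTest <- bundle[test]
      # all strategies share one derived seed per (repeat, fold): common
      # random numbers pair the forest randomness and sharpen paired
      # strategy comparisons
      for (si in seq_along(strategies)) {
        st <- strategies[[si]]
        model <- st$fit(bTrain, deriveSeed(seed, rep_, fold_))
        scores <- st$predict(model, bTest)
        ct <- st$cutoff(model)
        cm <- confusionAt(scores, y[test], ct)
        idx <- idx + 1L
        out[[idx]] <- data.frame(
          strategy = names(strategies)[si], rep = rep_, fold = fold_,
          acc = (cm["tp"] + cm["tn"]) / length(test),
          auc = aucScore(scores, y[test]),
          mcc = mccScore(cm["tp"], cm["tn"], cm["fp"], cm["fn"]),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Paired comparison of two cross-validated strategies
#'
#' Aggregates AUC to per-repeat means and applies a one-sided paired t-test
#' (alternative: A better than B), the design used to compare integrated
#' models against the clinical-only baseline. Wins count repeats where A's
#' mean AUC strictly exceeds B's. Degenerate difference variance follows the
#' convention p = 0, 0.5 or 1 for positive, zero or negative mean difference.
#'
#' @param records data.frame from [repeatedCV()] containing both strategies.
#' @param a,b strategy labels (A is the candidate, B the baseline).
#' @param metric metric column to compare (default "auc").
#' @return A list of class `strategyComparison`: labels, per-repeat means,
#'   `meanDiff`, `t`, `p.value`, `wins`, `r`.
#' @export
compareStrategies <- function(records, a, b, metric = "auc") {
  ra <- records[records$strategy == a, ]
  rb <- records[records$strategy == b, ]
  if (!nrow(ra) || !nrow(rb)) stop("strategy labels not found in records")
  ma <- tapply(ra[[metric]], ra$rep, mean)
  mb <- tapply(rb[[metric]], rb$rep, mean)
  if (length(ma) != length(mb) || !all(names(ma) == names(mb)))
    stop("records of the two strategies have mismatched repeat structure")
  d <- ma - mb
  r <- length(d)
  sdd <- sd(d)
  if (r < 2L || is.na(sdd) || sdd == 0) {
    m <- mean(d)
    t <- if (m > 0) Inf else if (m < 0) -Inf else 0
    p <- if (m > 0) 0 else if (m < 0) 1 else 0.5
  } else {
    t <- mean(d) / (sdd / sqrt(r))
    p <- pt(t, df = r - 1, lower.tail = FALSE)
  }
  structure(list(a = a, b = b, meanA = mean(ma), meanB = mean(mb),
                 meanDiff = mean(d), perRepeatDiff = as.numeric(d),
                 t = t, p.value = p, wins = sum(d > 0), r = r,
                 metric = metric),
            class = "strategyComparison")
}

#' @export
print.strategyComparison <- function(x, ...) {
  cat(sprintf("%s vs %s (%s): mean %.4f vs %.4f, diff %+.4f\n",
              x$a, x$b, x$metric, x$meanA, x$meanB, x$meanDiff))
  cat(sprintf("  paired one-sided t = %.2f, p = %.3g, wins %d/%d\n",
              x$t, x$p.value, x$wins, x$r))
  invisible(x)
}
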