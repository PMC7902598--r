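#' Early integration: column-wise merge of clinical and molecular features
#'
#' Concatenates the selected molecular columns to the clinical table,
#' realigning rows by sample ID. Feature-name collisions on the molecular
#' side are suffixed with "_mol".
#'
#' @param clinicalX numeric matrix of clinical features (row names = IDs).
#' @param molecularX numeric matrix of molecular features over the same
#'   sample IDs (any row order).
#' @return Merged matrix in the clinical row order.
#' @export
earlyMerge <- function(clinicalX, molecularX) {
  clinicalX <- asFeatureMatrix(clinicalX)
  molecularX <- asFeatureMatrix(molecularX)
  if (ncol(molecularX) == 0L) return(clinicalX)
  idsC <- rownames(clinicalX); idsM <- rownames(molecularX)
  if (is.null(idsC) || is.null(idsM))
    stop("both tables need sample IDs as row names")
  if (!setequal(idsC, idsM))
    stop("sample mismatch between clinical and molecular tables")
  molecularX <- molecularX[idsC, , drop = FALSE]
  clash <- colnames(molecularX) %in% colnames(clinicalX)
  colnames(molecularX)[clash] <- paste0(colnames(molecularX)[clash], "_mol")
  cbind(clinicalX, molecularX)
}

syntheticName <- function(layer) {
  if (!length(layer)) return(character(0))
  paste0("synthetic_", layer)
}

#' Fit the hybrid integration model
#'
#' For every molecular layer: run the feature-selection cascade on the
#' training data, train a random forest on the selected features, and take
#' its out-of-bag positive-vote fraction as that layer's synthetic variable
#' (a per-patient scalar in \[0,1\] compressing the whole layer). The
#' synthetic columns are appended to the clinical features and a final
#' forest is trained on the extended table, its cutoff tuned on its own OOB
#' votes. Layers with an empty selection are skipped with a warning. With no
#' usable layer the model reduces exactly to the clinical-only forest.
#'
#' @param bundle an [OmicsBundle-class] (training data).
#' @param layers layer names (NULL = all layers).
#' @param selection a [selectionConfig()], a named list with one config per
#'   layer, or NULL to use every feature of each layer (selection already
#'   done upstream).
#' @param clinicalFeatures clinical columns to use (NULL = all).
#' @param nTrees trees per forest.
#' @param syntheticSource "oob" for out-of-bag vote fractions (the method);
#'   "inbag" replaces them with in-bag training predictions - a deliberately
#'   leaky variant kept only as a negative control for leakage diagnostics.
#' @param seed integer seed.
#' @return A [HybridModel-class].
#' @export
hybridFit <- function(bundle, layers = NULL, selection = selectionConfig(),
                      clinicalFeatures = NULL, nTrees = 500L,
                      syntheticSource = c("oob", "inbag"), seed = 1L) {
  syntheticSource <- match.arg(syntheticSource)
  layers <- layers %||% omicsNames(bundle)
  y <- decision(bundle)
  clin <- clinical(bundle)
  if (!is.null(clinicalFeatures))
    clin <- clin[, clinicalFeatures, drop = FALSE]
  fitted <- list(); skipped <- character(0); synth <- NULL
  for (i in seq_along(layers)) {
    ly <- layers[i]
    cfg <- if (inherits(selection, "selectionConfig") || is.null(selection))
      selection else selection[[ly]]
    x <- omicsLayer(bundle, ly)
    if (is.null(cfg)) {  # selection done upstream: use the layer as-is
      sel <- new("SelectedFeatureSet", features = colnames(x),
                 table = data.frame(), nSignificant = ncol(x),
                 nAfterRedundancy = ncol(x), nFinal = ncol(x),
                 method = "none", config = list(), empty = FALSE)
    } else {
      sel <- selectFeatures(x, y, cfg, seed = deriveSeed(seed, i, 1L))
    }
    if (sel@empty) {
      warning("layer '", ly, "' skipped: empty selection")
      skipped <- c(skipped, ly)
      next
    }
    forest <- trainForest(x[, sel@features, drop = FALSE], y,
                          nTrees = nTrees, seed = deriveSeed(seed, i, 2L))
    v <- if (syntheticSource == "oob") forest@oobVotes
         else predict(forest, x)
    fitted[[ly]] <- list(selection = sel, forest = forest)
    synth <- cbind(synth, v)
    colnames(synth)[ncol(synth)] <- syntheticName(ly)
  }
  finalX <- if (is.null(synth)) clin else {
    rownames(synth) <- rownames(clin)
    cbind(clin, synth)
  }
  finalModel <- trainForest(finalX, y, nTrees = nTrees,
                            seed = deriveSeed(seed, 0L, 3L))
  new("HybridModel", layers = fitted, finalModel = finalModel,
      clinicalFeatures = colnames(clin),
      syntheticNames = if (is.null(synth)) character(0) else colnames(synth),
      skipped = skipped, seed = as.integer(seed))
}

#' Predict positive-vote fractions with a hybrid model
#'
#' Each stored layer forest predicts the vote fraction for the new samples,
#' producing their synthetic columns; the final forest then predicts on
#' clinical + synthetic features.
#'
#' @param model a [HybridModel-class].
#' @param bundle an [OmicsBundle-class] of new samples carrying the training
#'   clinical features and the layers the model uses.
#' @return Numeric per-sample positive fraction in \[0,1\].
#' @export
hybridPredict <- function(model, bundle) {
  clin <- clinical(bundle)[, model@clinicalFeatures, drop = FALSE]
  synth <- NULL
  for (ly in names(model@layers)) {
    v <- predict(model@layers[[ly]]$forest, omicsLayer(bundle, ly))
    synth <- cbind(synth, v)
    colnames(synth)[ncol(synth)] <- syntheticName(ly)
  }
  x <- if (is.null(synth)) clin else cbind(clin, synth)
  predict(model@finalModel, x)
}

#' Fit a second-level combiner on base-model meta-features
#'
#' @param meta numeric matrix of per-sample base-model predictions, one
#'   column per base model.
#' @param y binary 0/1 decision vector.
#' @param kind "nnls" (non-negative least squares without intercept, weights
#'   renormalised to sum to one), "forest" (random forest on the
#'   meta-features), or "best_k" (unweighted mean of the k columns with the
#'   highest training AUC).
#' @param k number of columns for "best_k".
#' @param nTrees trees for the "forest" combiner.
#' @param seed integer seed (forest combiner only).
#' @return A `combinerFit` object for [predictCombiner()].
#' @export
fitCombiner <- function(meta, y, kind = c("nnls", "forest", "best_k"),
                        k = 2L, nTrees = 200L, seed = 1L) {
  kind <- match.arg(kind)
  meta <- asFeatureMatrix(meta, "meta-feature matrix")
  y <- stopIfNot01(as.integer(y))
  fitObj <- switch(kind,
    nnls = {
      w <- pracma::lsqnonneg(meta, as.numeric(y))$x
      if (sum(w) > 0) w <- w / sum(w) else w <- rep(1 / ncol(meta), ncol(meta))
      list(weights = stats::setNames(w, colnames(meta)))
    },
    forest = list(model = trainForest(meta, y, nTrees = nTrees, seed = seed)),
    best_k = {
      if (k > ncol(meta))
        stop("k exceeds the number of base models")
      aucs <- apply(meta, 2, aucScore, y = y)
      ord <- order(-aucs, colnames(meta))
      list(cols = colnames(meta)[ord[seq_len(k)]], trainAUC = aucs)
    })
  structure(c(list(kind = kind, features = colnames(meta)), fitObj),
            class = "combinerFit")
}

#' Predict with a fitted combiner
#'
#' NNLS predictions are clipped to \[0,1\] (the meta-features are vote
#' fractions).
#'
#' @param combiner a `combinerFit` from [fitCombiner()].
#' @param meta meta-feature matrix with the training columns.
#' @return Numeric per-sample combined score in \[0,1\].
#' @export
predictCombiner <- function(combiner, meta) {
  meta <- asFeatureMatrix(meta, "meta-feature matrix")
  missing <- setdiff(combiner$features, colnames(meta))
  if (length(missing))
    stop("missing meta-features: ", paste(missing, collapse = ", "))
  meta <- meta[, combiner$features, drop = FALSE]
  switch(combiner$kind,
    nnls = pmin(1, pmax(0, as.numeric(meta %*% combiner$weights))),
    forest = predict(combiner$model, meta),
    best_k = rowMeans(meta[, combiner$cols, drop = FALSE]))
}

#' Fit a super learner over cross-validated base predictions
#'
#' For each of `loops` internal cross-validation rounds, a fresh stratified
#' `innerK`-fold partition produces out-of-fold predictions per base model
#' (each base refits its entire pipeline, feature selection included, inside
#' every fold); a combiner is fitted on the resulting meta-feature matrix.
#' Base models are also fitted once on the full training data to provide
#' meta-features for new samples; the eventual prediction is the average of
#' the loop-level combiners. The first loop's meta-matrix is stored for
#' [bbcEstimate()].
#'
#' @param bundle an [OmicsBundle-class] (training data).
#' @param bases list of base strategy objects (e.g. [clinicalStrategy()],
#'   [omicsStrategy()]); at least 2.
#' @param loops number of internal CV loops (study design: 30).
#' @param innerK internal folds (study design: 5).
#' @param combiner combiner kind, see [fitCombiner()].
#' @param kBest k for the best-k combiner.
#' @param seed integer seed.
#' @return A [SuperLearnerModel-class] carrying a tuned cutoff attribute.
#' @export
superLearnerFit <- function(bundle, bases, loops = 30L, innerK = 5L,
                            combiner = "nnls", kBest = 2L, seed = 1L) {
  if (length(bases) < 1L) stop("at least one base model required")
  y <- decision(bundle)
  n <- nSamples(bundle)
  metaNames <- vapply(bases, `[[`, "", "name")
  if (anyDuplicated(metaNames))
    metaNames <- make.unique(metaNames)
  baseModels <- lapply(seq_along(bases), function(i)
    bases[[i]]$fit(bundle, deriveSeed(seed, 1000L, i)))
  combiners <- vector("list", loops)
  trainPred <- numeric(n)
  metaFirst <- NULL
  for (l in seq_len(loops)) {
    folds <- cvFolds(y, k = innerK, stratified = TRUE,
                     seed = deriveSeed(seed, 2000L, l))
    meta <- matrix(NA_real_, n, length(bases),
                   dimnames = list(sampleIDs(bundle), metaNames))
    for (f in seq_along(folds)) {
      test <- folds[[f]]
      bTrain <- bundle[-test]; bTest <- bundle[test]
      for (i in seq_along(bases)) {
        m <- bases[[i]]$fit(bTrain, deriveSeed(seed, l, f, i))
        meta[test, i] <- bases[[i]]$predict(m, bTest)
      }
    }
    combiners[[l]] <- fitCombiner(meta, y, kind = combiner, k = kBest,
                                  seed = deriveSeed(seed, 3000L, l))
    trainPred <- trainPred + predictCombiner(combiners[[l]], meta)
    if (l == 1L) metaFirst <- meta
  }
  trainPred <- trainPred / loops
  model <- new("SuperLearnerModel", baseStrategies = bases,
               baseModels = baseModels, combiners = combiners,
               combiner = combiner, k = as.integer(kBest),
               metaNames = metaNames, meta = metaFirst,
               decision = y, seed = as.integer(seed))
  attr(model, "cutoff") <- tuneVoteCutoff(trainPred, y)$cutoff
  model
}

#' Predict with a super learner model
#'
#' Full-data base models produce the meta-features of the new samples; each
#' loop-level combiner scores them and the scores are averaged.
#'
#' @param model a [SuperLearnerModel-class].
#' @param bundle an [OmicsBundle-class] of new samples.
#' @param aggregate "mean" (default) or "median" over the loop-level
#'   combiner outputs.
#' @return Numeric per-sample combined score in \[0,1\].
#' @export
superLearnerPredict <- function(model, bundle, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  meta <- matrix(NA_real_, nSamples(bundle), length(model@baseModels),
                 dimnames = list(sampleIDs(bundle), model@metaNames))
  for (i in seq_along(model@baseModels))
    meta[, i] <- model@baseStrategies[[i]]$predict(model@baseModels[[i]],
                                                   bundle)
  preds <- vapply(model@combiners, predictCombiner, numeric(nrow(meta)),
                  meta = meta)
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1L)
  if (aggregate == "mean") rowMeans(preds)
  else apply(preds, 1, median)
}

#' Bootstrap bias-corrected performance of a combiner
#'
#' Estimates the generalisation performance of a second-level combiner from
#' a single internal-CV meta-feature matrix: for each of `B` bootstrap draws
#' of sample indices, the combiner is fitted on the in-bag rows and
#' evaluated on the out-of-bag rows; the bias-corrected estimate is the mean
#' out-of-bag metric over draws. Draws whose out-of-bag part is single-class
#' are redrawn (bounded retries). ACC and MCC use a cutoff tuned on the
#' in-bag predictions of each draw.
#'
#' @param meta meta-feature matrix from one internal CV run (e.g. the `meta`
#'   slot of a [SuperLearnerModel-class]).
#' @param y binary 0/1 decision vector.
#' @param kind combiner kind, see [fitCombiner()].
#' @param B bootstrap draws (>= 10; study design: 30).
#' @param kBest k for the best-k combiner.
#' @param seed integer seed.
#' @return A list with `auc`, `acc`, `mcc` (bias-corrected means) and `B`.
#' @export
bbcEstimate <- function(meta, y, kind = "nnls", B = 30L, kBest = 2L,
                        seed = 1L) {
  if (B < 10L) stop("B must be >= 10")
  meta <- asFeatureMatrix(meta, "meta-feature matrix")
  y <- stopIfNot01(as.integer(y))
  n <- length(y)
  withSeed(seed, {
    aucs <- accs <- mccs <- numeric(B)
    for (b in seq_len(B)) {
      ok <- FALSE
      for (try in seq_len(100L)) {
        idx <- sample.int(n, n, replace = TRUE)
        oob <- setdiff(seq_len(n), unique(idx))
        if (length(oob) >= 2L && length(unique(y[oob])) == 2L &&
            length(unique(y[idx])) == 2L) { ok <- TRUE; break }
      }
      if (!ok) stop("could not draw a bootstrap sample with two-class out-of-bag part")
      comb <- fitCombiner(meta[idx, , drop = FALSE], y[idx], kind = kind,
                          k = kBest, seed = deriveSeed(seed, b))
      inPred <- predictCombiner(comb, meta[idx, , drop = FALSE])
      ct <- tuneVoteCutoff(pmin(1, pmax(0, inPred)), y[idx])$cutoff
      outPred <- predictCombiner(comb, meta[oob, , drop = FALSE])
      cm <- confusionAt(outPred, y[oob], ct)
      aucs[b] <- aucScore(outPred, y[oob])
      accs[b] <- (cm["tp"] + cm["tn"]) / length(oob)
      mccs[b] <- mccScore(cm["tp"], cm["tn"], cm["fp"], cm["fn"])
    }
    list(auc = mean(aucs), acc = mean(accs), mcc = mean(mccs), B = B)
  })
}
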