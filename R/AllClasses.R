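#' Multi-modal cohort container
#'
#' An `OmicsBundle` holds one clinical feature table, zero or more named
#' molecular layers and a binary decision vector, all aligned on the same
#' ordered set of sample identifiers. Samples are rows; features are columns.
#' The decision is coded 0/1 with 1 the positive class (e.g. deceased).
#'
#' @slot clinical numeric matrix of clinical features (samples x features).
#' @slot omics named list of numeric matrices, one per molecular layer.
#' @slot decision integer vector of 0/1 labels, one per sample.
#' @slot sampleIDs character vector of unique sample identifiers.
#' @slot provenance free-form list (seeds, configs, file hashes).
#'
#' @seealso [OmicsBundle()], [clinical()], [omicsLayer()], [decision()]
#' @export
setClass("OmicsBundle",
  slots = c(clinical = "matrix", omics = "list", decision = "integer",
            sampleIDs = "character", provenance = "list"))

setValidity("OmicsBundle", function(object) {
  n <- length(object@sampleIDs)
  msg <- character()
  if (anyDuplicated(object@sampleIDs))
    msg <- c(msg, "duplicate sample IDs")
  if (nrow(object@clinical) != n)
    msg <- c(msg, "clinical table row count != number of sample IDs")
  if (!identical(rownames(object@clinical), object@sampleIDs))
    msg <- c(msg, "clinical rownames must equal sampleIDs")
  if (length(object@decision) != n)
    msg <- c(msg, "decision length != number of sample IDs")
  if (!all(object@decision %in% c(0L, 1L)))
    msg <- c(msg, "decision must be coded 0/1")
  if (length(object@omics) &&
      (is.null(names(object@omics)) || any(!nzchar(names(object@omics)))))
    msg <- c(msg, "omics layers must be named")
  for (nm in names(object@omics)) {
    m <- object@omics[[nm]]
    if (!is.matrix(m) || nrow(m) != n ||
        !identical(rownames(m), object@sampleIDs))
      msg <- c(msg, sprintf("layer '%s' must be a matrix aligned to sampleIDs", nm))
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated cohort
#'
#' Records, per feature of each simulated table, the relevance flag, the
#' class-conditional effect size and (for molecular features) the latent
#' cluster assignment, together with the generating seed and configuration.
#'
#' @slot clinical data.frame with columns feature, relevant, effect.
#' @slot omics named list of data.frames with columns feature, relevant,
#'   effect, cluster.
#' @slot seed integer seed that reproduces the cohort exactly.
#' @slot config the [cohortConfig()] used.
#' @export
setClass("CohortTruth",
  slots = c(clinical = "data.frame", omics = "list", seed = "integer",
            config = "list"))

#' Result of the molecular feature-selection cascade
#'
#' Ordered features surviving ranking, SGoF multiple-testing correction,
#' greedy Spearman redundancy removal and the top-m cap, with the counts
#' after each stage.
#'
#' @slot features character, kept features in ranking order.
#' @slot table data.frame (feature, p.value, score) for the kept features.
#' @slot nSignificant integer, features declared significant by SGoF.
#' @slot nAfterRedundancy integer, features surviving redundancy removal.
#' @slot nFinal integer, final kept count (<= m cap).
#' @slot method character, ranking method tag.
#' @slot config list, the selection configuration used.
#' @slot empty logical, TRUE when no feature was significant.
#' @export
setClass("SelectedFeatureSet",
  slots = c(features = "character", table = "data.frame",
            nSignificant = "integer", nAfterRedundancy = "integer",
            nFinal = "integer", method = "character", config = "list",
            empty = "logical"))

setValidity("SelectedFeatureSet", function(object) {
  if (object@nFinal != length(object@features))
    return("nFinal must equal the number of kept features")
  if (object@nFinal > min(object@nAfterRedundancy, object@nSignificant))
    return("counts must be non-increasing along the cascade")
  TRUE
})

#' Random forest base model with out-of-bag vote fractions
#'
#' Wraps a fitted classification forest together with the per-training-sample
#' out-of-bag (OOB) fraction of votes for the positive class, the per-sample
#' OOB tree count, and the vote cutoff tuned to maximise MCC on the OOB
#' predictions.
#'
#' @slot fit the underlying [randomForest::randomForest] object.
#' @slot nTrees integer number of trees.
#' @slot features character, training feature names.
#' @slot oobVotes numeric in \[0,1\], OOB positive-vote fraction per sample.
#' @slot oobCoverage integer, trees for which each sample was OOB.
#' @slot cutoff numeric in (0,1), MCC-maximising vote cutoff.
#' @slot cutoffMCC numeric, MCC achieved at the tuned cutoff on OOB votes.
#' @slot seed integer training seed.
#' @export
setClass("ForestModel",
  slots = c(fit = "ANY", nTrees = "integer", features = "character",
            oobVotes = "numeric", oobCoverage = "integer",
            cutoff = "numeric", cutoffMCC = "numeric", seed = "integer"))

setValidity("ForestModel", function(object) {
  if (length(object@oobVotes) != length(object@oobCoverage))
    return("oobVotes and oobCoverage must have the same length")
  if (any(object@oobVotes < 0 | object@oobVotes > 1, na.rm = TRUE))
    return("oobVotes must lie in [0,1]")
  if (object@cutoff <= 0 || object@cutoff >= 1)
    return("cutoff must lie in (0,1)")
  TRUE
})

#' Hybrid clinical + synthetic-variable model
#'
#' Per molecular layer: the selected feature set and the layer forest whose
#' OOB positive-vote fraction becomes the layer's synthetic variable. The
#' final forest is trained on clinical features plus the synthetic columns.
#'
#' @slot layers named list; each element has `selection` ([SelectedFeatureSet])
#'   and `forest` ([ForestModel]).
#' @slot finalModel [ForestModel] trained on clinical + synthetic columns.
#' @slot clinicalFeatures character, clinical columns used.
#' @slot syntheticNames character, names of the synthetic columns.
#' @slot skipped character, layers skipped because selection was empty.
#' @slot seed integer.
#' @export
setClass("HybridModel",
  slots = c(layers = "list", finalModel = "ForestModel",
            clinicalFeatures = "character", syntheticNames = "character",
            skipped = "character", seed = "integer"))

#' Super learner (late integration) model
#'
#' Base models fitted on the full training data provide meta-features for new
#' samples; per internal-CV loop, a combiner fitted on out-of-fold base
#' predictions. The prediction is the average of the loop-level combiners
#' applied to the base-model predictions.
#'
#' @slot baseStrategies list of base strategy specifications.
#' @slot baseModels list of base models fitted on the full training data.
#' @slot combiners list of per-loop fitted combiners.
#' @slot combiner character, combiner kind: "nnls", "forest" or "best_k".
#' @slot k integer, k for the best-k combiner.
#' @slot metaNames character, one name per base model.
#' @slot meta numeric matrix, out-of-fold meta-features from the first loop
#'   (input for [bbcEstimate()]).
#' @slot decision integer, training decision vector.
#' @slot seed integer.
#' @export
setClass("SuperLearnerModel",
  slots = c(baseStrategies = "list", baseModels = "list", combiners = "list",
            combiner = "character", k = "integer", metaNames = "character",
            meta = "matrix", decision = "integer", seed = "integer"))
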