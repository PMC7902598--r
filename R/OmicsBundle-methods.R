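#' Construct an OmicsBundle
#'
#' Assembles aligned clinical and molecular tables with a binary decision
#' vector into the container all pipeline functions consume.
#'
#' @param clinical numeric matrix or data.frame, samples in rows. Row names
#'   are used as sample IDs when `sampleIDs` is not given.
#' @param decision binary 0/1 vector (1 = positive class, e.g. deceased),
#'   or a logical/two-level factor.
#' @param omics named list of numeric matrices sharing the clinical samples.
#' @param sampleIDs optional character vector of sample identifiers.
#' @param provenance optional list of provenance metadata.
#' @return An [OmicsBundle-class] object.
#' @examples
#' cl <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("s", 1:10), c("a", "b")))
#' b <- OmicsBundle(cl, rep(0:1, 5))
#' nSamples(b)
#' @export
OmicsBundle <- function(clinical, decision, omics = list(),
                        sampleIDs = NULL, provenance = list()) {
  clinical <- asFeatureMatrix(clinical, "clinical")
  if (is.null(sampleIDs))
    sampleIDs <- rownames(clinical) %||% paste0("sample", seq_len(nrow(clinical)))
  sampleIDs <- as.character(sampleIDs)
  rownames(clinical) <- sampleIDs
  if (is.factor(decision)) decision <- as.integer(decision) - 1L
  if (is.logical(decision)) decision <- as.integer(decision)
  decision <- as.integer(decision)
  stopIfNot01(decision)
  omics <- lapply(omics, function(m) {
    m <- asFeatureMatrix(m, "omics layer")
    if (is.null(rownames(m))) rownames(m) <- sampleIDs
    m[sampleIDs, , drop = FALSE]
  })
  new("OmicsBundle", clinical = clinical, omics = omics,
      decision = decision, sampleIDs = sampleIDs, provenance = provenance)
}

#' @describeIn OmicsBundle clinical feature matrix.
#' @param x an `OmicsBundle`.
#' @export
setMethod("clinical", "OmicsBundle", function(x) x@clinical)

#' @describeIn OmicsBundle names of the molecular layers.
#' @export
setMethod("omicsNames", "OmicsBundle", function(x) names(x@omics))

#' @describeIn OmicsBundle one molecular layer by name.
#' @param name layer name.
#' @export
setMethod("omicsLayer", "OmicsBundle", function(x, name) {
  if (!name %in% names(x@omics))
    stop("unknown omics layer '", name, "'; available: ",
         paste(names(x@omics), collapse = ", "))
  x@omics[[name]]
})

#' @describeIn OmicsBundle binary decision vector (0/1).
#' @export
setMethod("decision", "OmicsBundle", function(x) x@decision)

#' @describeIn OmicsBundle sample identifiers.
#' @export
setMethod("sampleIDs", "OmicsBundle", function(x) x@sampleIDs)

#' @describeIn OmicsBundle number of samples.
#' @export
setMethod("nSamples", "OmicsBundle", function(x) length(x@sampleIDs))

#' Subset an OmicsBundle by sample
#'
#' @param x an `OmicsBundle`.
#' @param i sample indices (integer, logical, or sample IDs).
#' @param j,...,drop ignored.
#' @return An `OmicsBundle` restricted to the selected samples, all tables
#'   kept aligned.
#' @export
setMethod("[", "OmicsBundle", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@sampleIDs)
  new("OmicsBundle",
      clinical = x@clinical[i, , drop = FALSE],
      omics = lapply(x@omics, function(m) m[i, , drop = FALSE]),
      decision = x@decision[i],
      sampleIDs = x@sampleIDs[i],
      provenance = x@provenance)
})

setMethod("show", "OmicsBundle", function(object) {
  cat("OmicsBundle with", length(object@sampleIDs), "samples\n")
  cat("  clinical:", ncol(object@clinical), "features\n")
  for (nm in names(object@omics))
    cat("  layer", nm, ":", ncol(object@omics[[nm]]), "features\n")
  tab <- table(factor(object@decision, levels = 0:1))
  cat("  decision: ", tab[["1"]], " positive / ", tab[["0"]],
      " negative\n", sep = "")
})

setMethod("show", "SelectedFeatureSet", function(object) {
  cat("SelectedFeatureSet (", object@method, "): ", object@nFinal,
      " kept [significant ", object@nSignificant, " -> uncorrelated ",
      object@nAfterRedundancy, " -> capped ", object@nFinal, "]\n", sep = "")
  if (object@nFinal)
    cat("  top:", paste(utils::head(object@features, 5), collapse = ", "), "\n")
})

#' @describeIn SelectedFeatureSet kept feature names in ranking order.
#' @param x a `SelectedFeatureSet`.
#' @export
setMethod("selectedFeatures", "SelectedFeatureSet", function(x) x@features)

setMethod("show", "ForestModel", function(object) {
  cat("ForestModel:", object@nTrees, "trees,", length(object@features),
      "features\n")
  cat(sprintf("  tuned cutoff %.3f (OOB MCC %.3f)\n",
              object@cutoff, object@cutoffMCC))
})

#' @describeIn ForestModel OOB positive-class vote fraction per training sample.
#' @param x a `ForestModel`.
#' @export
setMethod("oobVotes", "ForestModel", function(x) x@oobVotes)

#' @describeIn ForestModel number of trees for which each sample was OOB.
#' @export
setMethod("oobCoverage", "ForestModel", function(x) x@oobCoverage)

#' @describeIn ForestModel MCC-maximising vote cutoff tuned on OOB votes.
#' @export
setMethod("tunedCutoff", "ForestModel", function(x) x@cutoff)

setMethod("show", "HybridModel", function(object) {
  cat("HybridModel:", length(object@layers), "molecular layer(s) ->",
      length(object@syntheticNames), "synthetic variable(s)\n")
  cat("  clinical features:", length(object@clinicalFeatures), "\n")
  if (length(object@skipped))
    cat("  skipped layers (empty selection):",
        paste(object@skipped, collapse = ", "), "\n")
  cat(sprintf("  final cutoff %.3f\n", object@finalModel@cutoff))
})

#' @describeIn HybridModel names of the synthetic molecular columns.
#' @param x a `HybridModel`.
#' @export
setMethod("syntheticNames", "HybridModel", function(x) x@syntheticNames)

#' @describeIn HybridModel cutoff of the final combined forest.
#' @export
setMethod("tunedCutoff", "HybridModel", function(x) x@finalModel@cutoff)

setMethod("show", "SuperLearnerModel", function(object) {
  cat("SuperLearnerModel:", length(object@baseModels), "base models,",
      length(object@combiners), "internal-CV loops, combiner =",
      object@combiner, "\n")
  cat("  meta-features:", paste(object@metaNames, collapse = ", "), "\n")
})
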