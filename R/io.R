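detectSep <- function(path) {
  l1 <- readLines(path, n = 1L)
  if (grepl("\t", l1)) "\t" else ","
}

#' Read a delimited feature table
#'
#' Comma or tab separation is auto-detected; the first column holds sample
#' IDs, the header row feature names. Values are numeric; empty cells and
#' "NA" become missing.
#'
#' @param path file path.
#' @return Numeric matrix, samples in rows, sample IDs as row names.
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = detectSep(path),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate sample IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write a feature table as delimited text
#'
#' @param x numeric matrix with sample IDs as row names.
#' @param path output path.
#' @param sep field separator ("," or "\t").
#' @param idColumn name of the leading sample-ID column.
#' @export
writeFeatureTable <- function(x, path, sep = ",", idColumn = "sample_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- idColumn
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Load and align a multi-modal data bundle from delimited files
#'
#' Reads the clinical table, the molecular layers and the decision file,
#' restricts every table to the intersection of their sample IDs ("complete
#' records" policy), aligns all tables in the clinical ID order and reports
#' the dropped samples per table in the provenance.
#'
#' @param clinicalPath path of the clinical table.
#' @param decisionPath path of the decision table (sample ID column plus the
#'   decision column).
#' @param omicsPaths named character vector/list of layer paths.
#' @param decisionColumn decision column name (default: the first non-ID
#'   column).
#' @param positive value coding the positive class; defaults to 1 for a 0/1
#'   column.
#' @return An [OmicsBundle-class] with provenance (file hashes, drop
#'   counts).
#' @export
loadBundle <- function(clinicalPath, decisionPath, omicsPaths = list(),
                       decisionColumn = NULL, positive = NULL) {
  clin <- readFeatureTable(clinicalPath)
  ddf <- utils::read.table(decisionPath, header = TRUE,
                           sep = detectSep(decisionPath),
                           check.names = FALSE, stringsAsFactors = FALSE)
  dids <- as.character(ddf[[1]])
  if (anyDuplicated(dids)) stop("duplicate sample IDs in decision file")
  decisionColumn <- decisionColumn %||% colnames(ddf)[2]
  dvals <- ddf[[decisionColumn]]
  lv <- sort(unique(dvals))
  if (length(lv) != 2L)
    stop("decision column '", decisionColumn, "' is not binary; levels: ",
         paste(lv, collapse = ", "))
  positive <- positive %||% (if (all(lv %in% c(0, 1))) 1 else
    stop("decision levels ", paste(lv, collapse = "/"),
         " need an explicit 'positive' value"))
  if (!positive %in% lv)
    stop("positive level '", positive, "' not among decision levels")
  yAll <- stats::setNames(as.integer(dvals == positive), dids)

  omics <- lapply(omicsPaths, readFeatureTable)
  ids <- rownames(clin)
  for (m in omics) ids <- intersect(ids, rownames(m))
  ids <- intersect(ids, dids)
  if (!length(ids)) stop("empty sample-ID intersection across tables")
  drops <- c(list(clinical = setdiff(rownames(clin), ids),
                  decision = setdiff(dids, ids)),
             lapply(omics, function(m) setdiff(rownames(m), ids)))
  paths <- c(clinical = clinicalPath, decision = decisionPath,
             unlist(omicsPaths))
  OmicsBundle(clin[ids, , drop = FALSE], yAll[ids],
              omics = lapply(omics, function(m) m[ids, , drop = FALSE]),
              sampleIDs = ids,
              provenance = list(files = as.list(tools::md5sum(paths)),
                                droppedSamples = lapply(drops, length),
                                nSamples = length(ids)))
}

#' Write a bundle (and optional ground truth) as delimited text
#'
#' Emits `clinical.csv`, one `<layer>.csv` per molecular layer,
#' `decision.csv` and `provenance.json` into `dir`; with a
#' [CohortTruth-class] also `truth.json`.
#'
#' @param bundle an [OmicsBundle-class].
#' @param dir output directory (created if needed).
#' @param truth optional [CohortTruth-class] sidecar.
#' @param sep field separator.
#' @return `dir`, invisibly.
#' @export
writeBundle <- function(bundle, dir, truth = NULL, sep = ",") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeFeatureTable(clinical(bundle), file.path(dir, "clinical.csv"), sep)
  for (nm in omicsNames(bundle))
    writeFeatureTable(omicsLayer(bundle, nm),
                      file.path(dir, paste0(nm, ".csv")), sep)
  utils::write.table(
    data.frame(sample_id = sampleIDs(bundle), decision = decision(bundle)),
    file.path(dir, "decision.csv"), sep = sep, row.names = FALSE,
    quote = FALSE)
  jsonlite::write_json(bundle@provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(truth))
    jsonlite::write_json(
      list(seed = truth@seed, clinical = truth@clinical,
           omics = truth@omics, config = truth@config),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read back a bundle written by [writeBundle()]
#'
#' @param dir directory containing `clinical.csv`, `decision.csv` and any
#'   layer CSVs.
#' @return An [OmicsBundle-class].
#' @export
readBundle <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  layerFiles <- files[!basename(files) %in% c("clinical.csv", "decision.csv")]
  names(layerFiles) <- sub("\\.csv$", "", basename(layerFiles))
  loadBundle(file.path(dir, "clinical.csv"), file.path(dir, "decision.csv"),
             as.list(layerFiles))
}
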