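# Accessors and show methods.

#' Construct a PGxGenotypes object
#'
#' @param dosage variants x samples matrix of alternate-allele dosages
#'   (0/1/2, `NA` missing). Row order defines variant order.
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `rsid`. One row per dosage row.
#' @param sampleIds character vector, one per dosage column.
#' @param groups optional per-sample group labels (recycled into
#'   `colData()$group`).
#' @return A [PGxGenotypes] object.
#' @export
PGxGenotypes <- function(dosage, variants, sampleIds = colnames(dosage),
                         groups = NULL) {
  dosage <- as.matrix(dosage)
  stopifnot(nrow(variants) == nrow(dosage))
  if (is.null(sampleIds))
    sampleIds <- paste0("sample", seq_len(ncol(dosage)))
  vid <- paste(variants$chrom, variants$pos, variants$ref, variants$alt,
               sep = ":")
  rr <- GRanges(variants$chrom, IRanges(variants$pos, width = nchar(variants$ref)))
  mcols(rr) <- DataFrame(ref = variants$ref, alt = variants$alt,
                         rsid = as.character(variants$rsid), variant_id = vid)
  names(rr) <- vid
  dimnames(dosage) <- list(vid, sampleIds)
  cd <- DataFrame(row.names = sampleIds)
  if (!is.null(groups)) cd$group <- as.character(groups)
  new("PGxGenotypes",
      SummarizedExperiment(assays = list(dosage = dosage),
                           rowRanges = rr, colData = cd))
}

#' @rdname pgxStrat-accessors
#' @export
setMethod("dosages", "PGxGenotypes", function(x) assay(x, "dosage"))

#' @rdname pgxStrat-accessors
#' @export
setMethod("variantIds", "PGxGenotypes",
          function(x) mcols(rowRanges(x))$variant_id)

#' @rdname pgxStrat-accessors
#' @export
setMethod("groupLabels", "PGxGenotypes", function(x) {
  g <- colData(x)$group
  if (is.null(g)) return(NULL)
  stats::setNames(g, colnames(x))
})

#' @rdname pgxStrat-accessors
#' @export
setReplaceMethod("groupLabels", "PGxGenotypes", function(x, value) {
  if (!is.null(names(value))) value <- value[colnames(x)]
  colData(x)$group <- as.character(value)
  validObject(x)
  x
})

setMethod("show", "PGxGenotypes", function(object) {
  d <- dosages(object)
  cat("PGxGenotypes:", nrow(d), "variants x", ncol(d), "samples\n")
  g <- groupLabels(object)
  if (!is.null(g)) {
    tab <- table(g)
    cat("groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
        "\n")
  }
  nm <- sum(is.na(d))
  cat(sprintf("missing calls: %d (%.2f%%)\n", nm, 100 * nm / length(d)))
})

#' @rdname pgxStrat-accessors
#' @export
setMethod("pcScores", "PGxPCA", function(x) x@scores)

#' @rdname pgxStrat-accessors
#' @export
setMethod("alleleWeights", "PGxPCA", function(x) x@alleleWeights)

#' @rdname pgxStrat-accessors
#' @export
setMethod("explainedVariance", "PGxPCA", function(x) x@explainedVariance)

#' @rdname pgxStrat-accessors
#' @export
setMethod("variantIds", "PGxPCA", function(x) rownames(x@alleleWeights))

setMethod("show", "PGxPCA", function(object) {
  cat("PGxPCA:", ncol(object@scores), "PCs,",
      nrow(object@scores), "samples,",
      nrow(object@alleleWeights), "variants (", object@method, ")\n")
  ev <- object@explainedVariance
  k <- min(5L, length(ev))
  cat("explained variance:",
      paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * ev[seq_len(k)]),
            collapse = ", "),
      if (length(ev) > k) "...", "\n")
  if (object@nDropped > 0L)
    cat("monomorphic variants dropped:", object@nDropped, "\n")
})

#' @rdname pgxStrat-accessors
#' @export
setMethod("foldAccuracy", "ClassificationReport", function(x) x@foldAccuracy)

#' @rdname pgxStrat-accessors
#' @export
setMethod("meanAccuracy", "ClassificationReport",
          function(x) mean(x@foldAccuracy))

#' @rdname pgxStrat-accessors
#' @export
setMethod("sdAccuracy", "ClassificationReport",
          function(x) stats::sd(x@foldAccuracy))

#' @rdname pgxStrat-accessors
#' @export
setMethod("confusionMatrix", "ClassificationReport", function(x) x@confusion)

#' @rdname pgxStrat-accessors
#' @export
setMethod("misclassifiedIds", "ClassificationReport",
          function(x) x@misclassified)

#' @rdname pgxStrat-accessors
#' @export
setMethod("bestParams", "ClassificationReport", function(x) x@bestParams)

setMethod("show", "ClassificationReport", function(object) {
  cat(sprintf("ClassificationReport: %s, %d PCs\n", object@method,
              object@nPCs))
  cat(sprintf("mean accuracy %.1f%% +/- %.1f%% over %d folds\n",
              meanAccuracy(object), sdAccuracy(object),
              length(object@foldAccuracy)))
  cat("groups:", paste(rownames(object@confusion), collapse = ", "), "\n")
})

#' @rdname pgxStrat-accessors
#' @export
setMethod("groupFrequencies", "GroundTruth", function(x) x@groupFreqs)

#' @rdname pgxStrat-accessors
#' @export
setMethod("divergentVariantIds", "GroundTruth", function(x) x@divergentVariants)

#' @rdname pgxStrat-accessors
#' @export
setMethod("ancestryProportions", "GroundTruth", function(x) x@ancestry)

#' @rdname pgxStrat-accessors
#' @export
setMethod("variantIds", "GroundTruth", function(x) x@variantIds)

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", length(object@variantIds), "variants,",
      ncol(object@groupFreqs), "non-admixed groups,",
      length(object@divergentVariants), "planted divergent variants\n")
  if (nrow(object@ancestry))
    cat("admixed samples with ancestry proportions:", nrow(object@ancestry),
        "\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nVariants, "variants (",
      object@nDivergent, "planted divergent), seed", object@seed, "\n")
  g <- object@groups
  cat("groups:", paste(sprintf("%s n=%d F=%.3g", g$name, g$size, g$fst),
                       collapse = "; "), "\n")
  for (a in object@admixedGroups)
    cat(sprintf("admixed: %s n=%d parents [%s]\n", a$name, a$size,
                paste(sprintf("%s=%.2f", names(a$weights), a$weights),
                      collapse = ", ")))
})
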