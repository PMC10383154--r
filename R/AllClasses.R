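#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowRanges colData<-
NULL

.EVIDENCE_LEVELS <- c("1A", "1B", "2A", "2B", "3", "4")
.ASSOCIATION_TYPES <- c("efficacy", "dosage", "toxicity", "other")
.EFFECT_MODES <- c("dominant", "recessive", "unknown")

.ANNOTATION_COLS <- c(
  "variant_id", "rsid", "gene", "drugs", "evidence_level",
  "association_type", "mode_of_effect", "effect_allele"
)

.FREQ_COLS <- c("variant_id", "rsid", "group", "allele", "freq", "n_called")

#' PGxGenotypes: a diploid dosage matrix with variant coordinates
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] subclass holding one
#' `"dosage"` assay (variants x samples) of alternate-allele counts 0/1/2
#' (`NA` = missing call). `rowRanges()` carries the variant coordinates with
#' `ref`, `alt`, `rsid` and `variant_id` metadata columns; `colData()$group`
#' optionally carries per-sample group labels.
#'
#' @export
setClass("PGxGenotypes", contains = "RangedSummarizedExperiment")

setValidity("PGxGenotypes", function(object) {
  msg <- character()
  if (!"dosage" %in% names(assays(object)))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- assay(object, "dosage")
    bad <- d[!is.na(d)]
    if (length(bad) && !all(bad %in% 0:2))
      msg <- c(msg, "dosage values must be 0, 1, 2 or NA")
  }
  needed <- c("ref", "alt", "rsid", "variant_id")
  miss <- setdiff(needed, colnames(mcols(rowRanges(object))))
  if (length(miss))
    msg <- c(msg, paste0("rowRanges mcols missing: ", paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' PGxAnnotation: a pharmacogenomic variant annotation table
#'
#' A `DFrame` subclass with one row per variant-drug annotation: columns
#' `variant_id` (chr:pos:ref:alt), `rsid`, `gene`, `drugs`, `evidence_level`
#' (1A/1B/2A/2B/3/4), `association_type` (efficacy/dosage/toxicity/other),
#' `mode_of_effect` (dominant/recessive/unknown) and `effect_allele`.
#' Duplicate rsIDs with distinct drugs are permitted.
#'
#' @export
setClass("PGxAnnotation", contains = "DFrame")

setValidity("PGxAnnotation", function(object) {
  msg <- character()
  miss <- setdiff(.ANNOTATION_COLS, colnames(object))
  if (length(miss))
    return(paste0("missing annotation columns: ", paste(miss, collapse = ", ")))
  if (nrow(object)) {
    if (!all(object$evidence_level %in% .EVIDENCE_LEVELS))
      msg <- c(msg, "evidence_level outside {1A,1B,2A,2B,3,4}")
    if (!all(object$association_type %in% .ASSOCIATION_TYPES))
      msg <- c(msg, "association_type outside {efficacy,dosage,toxicity,other}")
    if (!all(object$mode_of_effect %in% .EFFECT_MODES))
      msg <- c(msg, "mode_of_effect outside {dominant,recessive,unknown}")
  }
  if (length(msg)) msg else TRUE
})

#' GroupFrequencyTable: per-group allele frequencies
#'
#' A `DFrame` subclass with columns `variant_id`, `rsid`, `group`, `allele`
#' (the counted allele, normally the alternate allele), `freq` in \[0, 1\]
#' (`NA` when no calls) and `n_called` (samples with a non-missing genotype).
#' (variant, group) pairs are unique.
#'
#' @export
setClass("GroupFrequencyTable", contains = "DFrame")

setValidity("GroupFrequencyTable", function(object) {
  miss <- setdiff(.FREQ_COLS, colnames(object))
  if (length(miss))
    return(paste0("missing frequency columns: ", paste(miss, collapse = ", ")))
  msg <- character()
  if (nrow(object)) {
    f <- object$freq
    if (any(!is.na(f) & (f < 0 | f > 1)))
      msg <- c(msg, "freq outside [0, 1]")
    if (anyDuplicated(paste(object$variant_id, object$group, sep = "\r")))
      msg <- c(msg, "(variant_id, group) pairs must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: parameters of the synthetic cohort generator
#'
#' @slot nVariants total number of biallelic variants.
#' @slot nDivergent number of planted strongly group-divergent variants.
#' @slot groups data.frame with columns `name`, `size`, `fst`; one row per
#'   non-admixed group. `fst` in (0, 1) indexes Balding-Nichols divergence
#'   from the shared ancestral frequency.
#' @slot admixedGroups list of lists with elements `name`, `size`, `weights`
#'   (named, nonnegative, sums to 1 over parental group names) and
#'   `concentration` (Dirichlet concentration scaling for per-sample
#'   ancestry proportions).
#' @slot ancestralFreqRange interval within (0, 1) for ancestral frequencies.
#' @slot divergentDelta minimum max-pairwise group frequency difference for
#'   planted variants.
#' @slot seed integer seed.
#' @export
setClass("SimulationConfig", representation(
  nVariants = "integer",
  nDivergent = "integer",
  groups = "data.frame",
  admixedGroups = "list",
  ancestralFreqRange = "numeric",
  divergentDelta = "numeric",
  seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  g <- object@groups
  if (!all(c("name", "size", "fst") %in% colnames(g)))
    return("groups needs columns name, size, fst")
  if (object@nVariants < 1L) msg <- c(msg, "nVariants must be >= 1")
  if (object@nDivergent < 0L || object@nDivergent > object@nVariants)
    msg <- c(msg, "nDivergent must be in [0, nVariants]")
  if (nrow(g) < 1L) msg <- c(msg, "at least one non-admixed group required")
  if (any(g$size < 1L)) msg <- c(msg, "all group sizes must be >= 1")
  if (any(g$fst <= 0 | g$fst >= 1)) msg <- c(msg, "all fst must be in (0, 1)")
  r <- object@ancestralFreqRange
  if (length(r) != 2L || r[1] <= 0 || r[2] >= 1 || r[1] > r[2])
    msg <- c(msg, "ancestralFreqRange must be an interval within (0, 1)")
  if (object@divergentDelta < 0 || object@divergentDelta >= 1)
    msg <- c(msg, "divergentDelta must be in [0, 1)")
  for (a in object@admixedGroups) {
    if (!all(c("name", "size", "weights") %in% names(a)))
      msg <- c(msg, "each admixed group needs name, size, weights")
    else {
      w <- a$weights
      if (is.null(names(w)) || !all(names(w) %in% g$name))
        msg <- c(msg, "admixed weights must be named by parental groups")
      if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
        msg <- c(msg, "admixed weights must be nonnegative and sum to 1")
      if (a$size < 1L) msg <- c(msg, "admixed group size must be >= 1")
    }
  }
  if (length(msg)) msg else TRUE
})

#' GroundTruth: the latent state of a simulated cohort
#'
#' @slot ancestralFreqs per-variant ancestral effect-allele frequency.
#' @slot groupFreqs variants x non-admixed-groups matrix of group
#'   allele frequencies in \[0, 1\].
#' @slot divergentVariants ids of the planted divergent variants.
#' @slot ancestry admixed-samples x parental-groups matrix of per-sample
#'   ancestry proportions (zero rows when no admixed groups).
#' @slot variantIds,variantTable variant identifiers and coordinate table.
#' @export
setClass("GroundTruth", representation(
  ancestralFreqs = "numeric",
  groupFreqs = "matrix",
  divergentVariants = "character",
  ancestry = "matrix",
  variantIds = "character",
  variantTable = "data.frame"
))

setValidity("GroundTruth", function(object) {
  msg <- character()
  f <- object@groupFreqs
  if (any(f < 0 | f > 1)) msg <- c(msg, "group frequencies must lie in [0, 1]")
  if (!all(object@divergentVariants %in% object@variantIds))
    msg <- c(msg, "divergentVariants must be a subset of variantIds")
  if (length(object@variantIds) != nrow(f))
    msg <- c(msg, "variantIds length must match groupFreqs rows")
  if (length(msg)) msg else TRUE
})

#' PGxPCA: a fitted genotype principal component model
#'
#' Scores satisfy the reconstruction identity
#' `scores = standardized dosages \%*\% alleleWeights`: each sample's PC value
#' is the allele-weight-weighted sum of its standardized dosages.
#'
#' @slot scores samples x PCs score matrix.
#' @slot alleleWeights variants x PCs allele-weight (loading) matrix.
#' @slot center,scale per-variant standardization parameters (center = twice
#'   the estimated allele frequency; scale = sqrt(2p(1-p))).
#' @slot explainedVariance share of total variance per PC, non-increasing.
#' @slot nDropped number of monomorphic variants dropped before fitting.
#' @slot method "exact" or "randomized".
#' @export
setClass("PGxPCA", representation(
  scores = "matrix",
  alleleWeights = "matrix",
  center = "numeric",
  scale = "numeric",
  explainedVariance = "numeric",
  nDropped = "integer",
  method = "character"
))

setValidity("PGxPCA", function(object) {
  msg <- character()
  ev <- object@explainedVariance
  if (length(ev) != ncol(object@scores))
    msg <- c(msg, "explainedVariance length must equal number of PCs")
  if (any(ev < -1e-12 | ev > 1 + 1e-12))
    msg <- c(msg, "explainedVariance shares must lie in [0, 1]")
  if (length(ev) > 1 && any(diff(ev) > 1e-8))
    msg <- c(msg, "explainedVariance must be non-increasing")
  if (ncol(object@scores) != ncol(object@alleleWeights))
    msg <- c(msg, "scores and alleleWeights must agree on the number of PCs")
  if (length(msg)) msg else TRUE
})

#' ClassifierSpec: classifier choice and search settings
#'
#' @slot method one of "knn", "random_forest", "svm".
#' @slot searchSpace named list of hyperparameter sampling rules (see
#'   [classifierSpec()] for the defaults per method).
#' @slot nSearchDraws randomized-search draws per training fold.
#' @slot cvFolds outer cross-validation folds (default 5).
#' @slot innerFolds folds of the nested search within each training fold.
#' @slot seed integer seed.
#' @export
setClass("ClassifierSpec", representation(
  method = "character",
  searchSpace = "list",
  nSearchDraws = "integer",
  cvFolds = "integer",
  innerFolds = "integer",
  seed = "integer"
))

setValidity("ClassifierSpec", function(object) {
  msg <- character()
  if (!object@method %in% c("knn", "random_forest", "svm"))
    msg <- c(msg, "method must be knn, random_forest or svm")
  if (object@cvFolds < 2L) msg <- c(msg, "cvFolds must be >= 2")
  if (object@innerFolds < 2L) msg <- c(msg, "innerFolds must be >= 2")
  if (object@nSearchDraws < 1L) msg <- c(msg, "nSearchDraws must be >= 1")
  if (length(msg)) msg else TRUE
})

#' ClassificationReport: cross-validated prediction results
#'
#' @slot method classifier used.
#' @slot nPCs number of principal components in the feature vector.
#' @slot foldAccuracy per-fold percent-correct accuracies.
#' @slot bestParams hyperparameters chosen by the randomized search, per fold.
#' @slot confusion true-group x predicted-group count matrix pooled over the
#'   test folds.
#' @slot misclassified ids of misclassified samples.
#' @export
setClass("ClassificationReport", representation(
  method = "character",
  nPCs = "integer",
  foldAccuracy = "numeric",
  bestParams = "list",
  confusion = "matrix",
  misclassified = "character"
))

setValidity("ClassificationReport", function(object) {
  msg <- character()
  if (any(object@foldAccuracy < 0 | object@foldAccuracy > 100))
    msg <- c(msg, "fold accuracies must lie in [0, 100]")
  cm <- object@confusion
  if (nrow(cm) != ncol(cm))
    msg <- c(msg, "confusion matrix must be square")
  if (length(msg)) msg else TRUE
})
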