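# End-to-end orchestration: simulate or read genotypes, intersect with the
# annotation, compute frequencies, PCA, classification, divergence ranking
# and the excess-ADR table, with one global seed deriving per-stage seeds.

#' Configure an end-to-end pipeline run
#'
#' Exactly one genotype source must be given: either `simulate` (a
#' [SimulationConfig]) or `vcf` (+ `labels`). When simulating without an
#' annotation, a synthetic annotation is generated from the ground truth:
#' planted divergent variants become toxicity annotations with alternating
#' dominant/recessive modes (effect allele = alternate), background
#' variants become "other"/"unknown" rows, so every stage has coherent
#' inputs.
#'
#' @param outDir output directory (created if needed).
#' @param simulate optional [SimulationConfig].
#' @param vcf,labels optional VCF and label-TSV paths.
#' @param annotation optional annotation TSV path.
#' @param nPCs PCs to fit.
#' @param classifier a [ClassifierSpec].
#' @param pcRange optional contiguous PC-count range to sweep; `NULL`
#'   evaluates only at `nPCs`.
#' @param divergencePCs PCs used for divergence ranking.
#' @param referenceGroup reference group for the ADR table (default: the
#'   largest group).
#' @param seed global seed; per-stage seeds are derived from it by stable
#'   hashing of stage names so stages can be re-run in isolation.
#' @return A validated pipeline config (list).
#' @export
pipelineConfig <- function(outDir, simulate = NULL, vcf = NULL, labels = NULL,
                           annotation = NULL, nPCs = 10L,
                           classifier = classifierSpec("random_forest"),
                           pcRange = NULL, divergencePCs = c(1L, 2L),
                           referenceGroup = NULL, seed = 1L) {
  if (is.null(simulate) == is.null(vcf))
    stop("exactly one genotype source required: simulate xor vcf")
  if (!is.null(vcf) && is.null(labels))
    stop("a label table is required with a supplied VCF")
  cfg <- list(outDir = outDir, simulate = simulate, vcf = vcf,
              labels = labels, annotation = annotation,
              nPCs = as.integer(nPCs), classifier = classifier,
              pcRange = pcRange, divergencePCs = as.integer(divergencePCs),
              referenceGroup = referenceGroup, seed = as.integer(seed))
  class(cfg) <- "pgxPipelineConfig"
  cfg
}

# synthetic annotation covering all simulated variants
.synthetic_annotation <- function(truth) {
  vt <- truth@variantTable
  vids <- truth@variantIds
  div <- vids %in% truth@divergentVariants
  mode <- rep("unknown", length(vids))
  mode[div] <- rep(c("dominant", "recessive"), length.out = sum(div))
  new("PGxAnnotation", DataFrame(
    variant_id = vids, rsid = vt$rsid, gene = "synthetic",
    drugs = "synthetic", evidence_level = "3",
    association_type = ifelse(div, "toxicity", "other"),
    mode_of_effect = mode, effect_allele = vt$alt))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate/read genotypes, intersect with the
#' annotation, per-group allele frequencies, PCA, classification,
#' divergence ranking and the excess-ADR table; writes each stage's output
#' under `outDir` plus a machine-readable `summary.json`. Reruns with the
#' same config and seed produce identical TSV outputs.
#'
#' @param config from [pipelineConfig()].
#' @return The summary list, invisibly.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pgxPipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outDir, f)
  summary <- list(package = as.character(utils::packageVersion("pgxStrat")),
                  seed = config$seed, stages = list())

  # --- genotypes
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    truth <- .stage("simulate", simulateGroupFrequencies(sim))
    gt <- .stage("simulate", simulateGenotypes(truth, sim))
    writeGenotypeVCF(gt, out("genotypes.vcf"))
    writeGroupLabels(groupLabels(gt), out("labels.tsv"))
    utils::write.table(
      data.frame(variant_id = truth@variantIds,
                 divergent = truth@variantIds %in% truth@divergentVariants,
                 round(truth@groupFreqs, 6)),
      out("ground_truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    ann <- if (is.null(config$annotation)) .synthetic_annotation(truth)
           else readPGxAnnotation(config$annotation)
  } else {
    gt <- .stage("read", readGenotypeVCF(config$vcf))
    groupLabels(gt) <- .stage("read", readGroupLabels(config$labels))
    if (is.null(config$annotation))
      stop("an annotation table is required with a supplied VCF")
    ann <- readPGxAnnotation(config$annotation)
  }
  summary$stages$genotypes <- list(n_variants = nrow(gt),
                                   n_samples = ncol(gt))

  # --- intersect
  gt <- .stage("intersect", intersectVariants(gt, ann))
  summary$stages$intersect <- metadata(gt)$intersect

  # --- frequencies
  freqs <- .stage("frequencies", groupAlleleFrequencies(gt))
  writeGroupFrequencies(freqs, out("frequencies.tsv"))
  summary$stages$frequencies <- list(n_rows = nrow(freqs))

  # --- pca
  pca <- .stage("pca", fitGenotypePCA(
    gt, nPCs = min(config$nPCs, ncol(gt) - 1L),
    seed = .derive_seed(config$seed, "pca")))
  utils::write.table(
    data.frame(sample_id = rownames(pcScores(pca)),
               round(pcScores(pca), 6)),
    out("scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(variant_id = rownames(alleleWeights(pca)),
               round(alleleWeights(pca), 6)),
    out("weights.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(pc = seq_along(explainedVariance(pca)),
               share = round(explainedVariance(pca), 6)),
    out("explained_variance.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  summary$stages$pca <- list(n_pcs = ncol(pcScores(pca)),
                             explained = explainedVariance(pca))

  # --- classification
  labels <- groupLabels(gt)
  spec <- config$classifier
  spec@seed <- .derive_seed(config$seed, "classify")
  if (!is.null(config$pcRange)) {
    sw <- .stage("classify", sweepPCs(pca, labels, spec, config$pcRange))
    best <- sw$reports[[paste0("PC", sw$bestNPCs)]]
    utils::write.table(sw$summary, out("pc_sweep.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    best <- .stage("classify",
                   trainEval(pca, labels, spec, ncol(pcScores(pca))))
  }
  utils::write.table(
    as.data.frame.matrix(confusionMatrix(best)),
    out("confusion.tsv"), sep = "\t", quote = FALSE)
  summary$stages$classification <- list(
    method = best@method, n_pcs = best@nPCs,
    mean_accuracy = meanAccuracy(best), sd_accuracy = sdAccuracy(best),
    per_group_accuracy = as.list(stats::setNames(
      confusionAnalysis(best)$perGroup$accuracy,
      confusionAnalysis(best)$perGroup$group)))

  # --- divergence ranking
  rsids <- stats::setNames(mcols(rowRanges(gt))$rsid, variantIds(gt))
  ranked <- .stage("divergence",
                   rankDivergentVariants(pca, ann, config$divergencePCs,
                                         rsids = rsids))
  utils::write.table(as.data.frame(ranked), out("divergence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary$stages$divergence <- list(
    top_variants = utils::head(ranked$variant_id, 10))

  # --- adr
  refg <- config$referenceGroup
  if (is.null(refg)) refg <- names(which.max(table(labels)))
  adr <- .stage("adr", adrTable(freqs, ann, refg))
  utils::write.table(as.data.frame(adr), out("adr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summary$stages$adr <- list(n_predictions = nrow(adr), reference = refg)

  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror [pipelineConfig()] arguments; `simulate` holds
#' [simulationConfig()] arguments (`groups` as a list of name/size/fst
#' records, `admixed_groups` as name/size/weights records), `classifier`
#' holds [classifierSpec()] arguments.
#'
#' @param path YAML file path.
#' @param outDir overrides the config's output directory if non-NULL.
#' @return A pipeline config list.
#' @export
readPipelineConfig <- function(path, outDir = NULL) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulate)) {
    s <- y$simulate
    g <- do.call(rbind, lapply(s$groups, as.data.frame))
    adm <- lapply(s$admixed_groups, function(a) {
      a$weights <- unlist(a$weights)
      a
    })
    sim <- simulationConfig(
      nVariants = s$n_variants %||% 1000L,
      nDivergent = s$n_divergent %||% 0L,
      groups = g, admixedGroups = adm %||% list(),
      ancestralFreqRange = unlist(s$ancestral_freq_range) %||% c(0.05, 0.95),
      divergentDelta = s$divergent_delta %||% 0.5,
      seed = s$seed %||% y$seed %||% 1L)
  }
  cls <- y$classifier %||% list()
  spec <- classifierSpec(
    method = cls$method %||% "random_forest",
    nSearchDraws = cls$n_search_draws %||% 10L,
    cvFolds = cls$cv_folds %||% 5L,
    seed = y$seed %||% 1L)
  pipelineConfig(
    outDir = outDir %||% y$out_dir %||% "pgx_run",
    simulate = sim, vcf = y$vcf, labels = y$labels,
    annotation = y$annotation, nPCs = y$n_pcs %||% 10L,
    classifier = spec, pcRange = y$pc_range,
    divergencePCs = unlist(y$divergence_pcs) %||% c(1L, 2L),
    referenceGroup = y$reference_group, seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
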