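test_that("opposite fixed groups collapse onto a single dominant PC", {
  d <- cbind(matrix(0, 20, 10), matrix(2, 20, 10))  # variants x samples
  variants <- data.frame(chrom = "chr1", pos = 1:20 * 50, ref = "A",
                         alt = "G", rsid = sprintf("rs%d", 1:20))
  gt <- PGxGenotypes(d, variants, sampleIds = sprintf("s%02d", 1:20))
  fit <- fitGenotypePCA(gt, nPCs = 3)
  sc <- pcScores(fit)
  # two point masses on PC1
  expect_equal(length(unique(round(sc[, 1], 8))), 2L)
  expect_gt(explainedVariance(fit)[1], 0.999)
  # tie case: every variant contributes identically on PC1
  r <- rankDivergentVariants(fit, pcs = 1L)
  expect_lt(diff(range(r$divergence)), 1e-10)
  expect_setequal(r$variant_id, variantIds(gt))
  # exact ties keep input order (stable sort)
  fitt <- new("PGxPCA", scores = matrix(0, 2, 1),
              alleleWeights = matrix(c(0.5, 0.5, 0.5), 3, 1,
                                     dimnames = list(c("a", "b", "c"), NULL)),
              center = numeric(3), scale = rep(1, 3),
              explainedVariance = 1, nDropped = 0L, method = "exact")
  expect_identical(rankDivergentVariants(fitt, pcs = 1L)$variant_id,
                   c("a", "b", "c"))
})

test_that("truncated fit matches an independent eigendecomposition oracle", {
  set.seed(31)
  for (dims in list(c(30, 50), c(100, 100))) {
    d <- matrix(rbinom(dims[1] * dims[2], 2, 0.4), dims[1], dims[2])
    variants <- data.frame(chrom = "chr1", pos = seq_len(dims[1]) * 10,
                           ref = "A", alt = "G",
                           rsid = sprintf("rs%d", seq_len(dims[1])))
    gt <- PGxGenotypes(d, variants,
                       sampleIds = sprintf("s%03d", seq_len(dims[2])))
    k <- 5L
    fit <- suppressMessages(fitGenotypePCA(gt, nPCs = k))

    # oracle: full eigendecomposition of the standardized cross-product
    x <- t(dosages(gt))
    p <- colMeans(x) / 2
    keep <- p > 0 & p < 1
    xs <- sweep(sweep(x[, keep], 2, 2 * p[keep]), 2,
                sqrt(2 * p[keep] * (1 - p[keep])), "/")
    eg <- eigen(crossprod(xs), symmetric = TRUE)
    v_or <- eg$vectors[, seq_len(k)]
    sc_or <- xs %*% v_or

    expect_lt(max(abs(abs(pcScores(fit)) - abs(sc_or))), 1e-6)
    expect_lt(max(abs(abs(alleleWeights(fit)) - abs(v_or))), 1e-6)
    ev_or <- eg$values[seq_len(k)] / sum(eg$values)
    expect_equal(unname(explainedVariance(fit)), ev_or, tolerance = 1e-8)

    # reconstruction identity: scores are weight-weighted standardized dosages
    expect_lt(max(abs(pcScores(fit) - xs %*% alleleWeights(fit))), 1e-6)
    # orthogonality of score columns
    cc <- cor(pcScores(fit))
    expect_lt(max(abs(cc[upper.tri(cc)])), 1e-6)
  }
})

test_that("randomized solver agrees with the exact solver on leading PCs", {
  cfg <- two_group_config(nVariants = 300, n = 60, fst = 0.3, seed = 41)
  gt <- simulateGenotypes(simulateGroupFrequencies(cfg), cfg)
  exact <- suppressMessages(fitGenotypePCA(gt, nPCs = 3))
  rand <- suppressMessages(fitGenotypePCA(gt, nPCs = 3, exactLimit = 10L))
  expect_identical(rand@method, "randomized")
  # leading structure is well separated here; compare up to sign
  # (the randomized solver is approximate: tolerance relative to the
  # score spread)
  expect_lt(max(abs(abs(pcScores(rand)[, 1]) - abs(pcScores(exact)[, 1]))),
            1e-3 * diff(range(pcScores(exact)[, 1])))
  rand2 <- suppressMessages(fitGenotypePCA(gt, nPCs = 3, exactLimit = 10L))
  expect_identical(pcScores(rand), pcScores(rand2))  # seeded determinism
})

test_that("degenerate PCA inputs are handled", {
  d <- rbind(rep(1, 6), c(0, 1, 2, 0, 1, 2), rep(0, 6))
  variants <- data.frame(chrom = "chr1", pos = c(10, 20, 30), ref = "A",
                         alt = "G", rsid = c("rs1", "rs2", "rs3"))
  gt <- PGxGenotypes(d, variants, sampleIds = paste0("s", 1:6))
  # monomorphic variants dropped with a message; too few left -> error
  expect_message(fit <- fitGenotypePCA(gt, nPCs = 1), "monomorphic")
  expect_equal(nrow(alleleWeights(fit)), 2L)
  expect_error(suppressMessages(fitGenotypePCA(gt, nPCs = 3)),
               "fewer usable variants")
  expect_error(rankDivergentVariants(fit, pcs = integer(0)), "nonempty")
  expect_error(rankDivergentVariants(fit, pcs = 5L), "outside")
})

test_that("ranking orders by max absolute weight and joins annotation", {
  fit <- new("PGxPCA",
             scores = matrix(0, 2, 2),
             alleleWeights = matrix(c(3, 0.2, 0.1, 0.4), 2, 2,
                                    dimnames = list(c("v1", "v2"), NULL)),
             center = c(0, 0), scale = c(1, 1),
             explainedVariance = c(0.5, 0.3), nDropped = 0L,
             method = "exact")
  r <- rankDivergentVariants(fit)
  expect_identical(r$variant_id, c("v1", "v2"))
  expect_equal(r$divergence, c(3, 0.4))

  ann <- new("PGxAnnotation", S4Vectors::DataFrame(data.frame(
    variant_id = "x", rsid = "rs77", gene = "GENE1", drugs = "drugA",
    evidence_level = "1A", association_type = "toxicity",
    mode_of_effect = "dominant", effect_allele = "G")))
  r2 <- rankDivergentVariants(fit, ann, rsids = c(v1 = "rs77", v2 = ""))
  expect_identical(r2$gene[1], "GENE1")
  expect_true(is.na(r2$gene[2]))
})

test_that("stronger planted divergence yields better mean ranks", {
  mean_rank <- function(delta) {
    cfg <- simulationConfig(
      nVariants = 200, nDivergent = 10,
      groups = data.frame(name = c("A", "B"), size = c(80L, 80L),
                          fst = c(0.05, 0.05)),
      divergentDelta = delta, seed = 51)
    tr <- simulateGroupFrequencies(cfg)
    gt <- simulateGenotypes(tr, cfg)
    fit <- suppressMessages(fitGenotypePCA(gt, nPCs = 2))
    r <- rankDivergentVariants(fit)
    mean(r$rank[r$variant_id %in% divergentVariantIds(tr)])
  }
  ranks <- vapply(c(0.2, 0.4, 0.6, 0.8), mean_rank, numeric(1))
  expect_lt(cor(c(0.2, 0.4, 0.6, 0.8), ranks, method = "spearman"), 0)
  expect_true(ranks[4] < ranks[1])
})
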