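# In-code fixtures shared across test files.

suppressPackageStartupMessages({
  library(SummarizedExperiment)  # mcols, rowRanges, metadata in tests
  library(withr)
})

# tiny genotype object with hand-chosen dosages
toy_genotypes <- function(dosage = rbind(c(0, 1, 2), c(2, NA, 0)),
                          groups = NULL) {
  m <- nrow(dosage)
  variants <- data.frame(
    chrom = "chr1", pos = 1000L + seq_len(m), ref = "A", alt = "G",
    rsid = sprintf("rs%d", seq_len(m)))
  PGxGenotypes(dosage, variants,
               sampleIds = paste0("s", seq_len(ncol(dosage))),
               groups = groups)
}

# perfectly separated point clusters in PC space: one cluster per group at
# PC1 = centers[g], small isotropic noise, extra uninformative PCs
separable_scores <- function(n_per = 30, centers = c(-5, 5), n_pcs = 4,
                             sd = 0.1, seed = 42) {
  set.seed(seed)
  k <- length(centers)
  n <- n_per * k
  x <- matrix(rnorm(n * n_pcs, sd = sd), n, n_pcs)
  x[, 1] <- x[, 1] + rep(centers, each = n_per)
  rownames(x) <- sprintf("s%03d", seq_len(n))
  colnames(x) <- paste0("PC", seq_len(n_pcs))
  labels <- setNames(rep(LETTERS[seq_len(k)], each = n_per), rownames(x))
  list(scores = x, labels = labels)
}

# two-group cohort config for simulator tests
two_group_config <- function(nVariants = 500, n = 100, fst = 0.1,
                             nDivergent = 0, seed = 1) {
  simulationConfig(
    nVariants = nVariants, nDivergent = nDivergent,
    groups = data.frame(name = c("G1", "G2"), size = c(n, n),
                        fst = c(fst, fst)),
    seed = seed)
}
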