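# Synthetic multi-group cohort generator.
#
# Group allele frequencies follow the Balding-Nichols model: for ancestral
# frequency p and divergence F in (0,1), a group's frequency is drawn
# Beta(p(1-F)/F, (1-p)(1-F)/F), so E = p and Var = F p(1-p). Admixed samples
# draw each of their two allele copies from a parental group chosen by
# per-sample ancestry proportions. Variants are independent (no linkage
# disequilibrium).

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# stable per-stage seed derivation from one global seed
.derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 10007 + h * 7919) %% 2147483647)
}

#' Configure a synthetic cohort simulation
#'
#' @param nVariants number of independent biallelic variants.
#' @param nDivergent number of planted strongly group-divergent variants
#'   among them.
#' @param groups data.frame with columns `name`, `size`, `fst` (one row per
#'   non-admixed group; `fst` in (0,1)).
#' @param admixedGroups list of admixed group definitions, each a list with
#'   `name`, `size`, `weights` (named parental mixture weights summing to 1)
#'   and optionally `concentration` (Dirichlet concentration, default 10;
#'   larger values concentrate per-sample ancestry around `weights`).
#' @param ancestralFreqRange interval in (0,1) from which ancestral
#'   frequencies are drawn uniformly; the default (0.05, 0.95) avoids
#'   near-monomorphic background variants.
#' @param divergentDelta minimum max-pairwise group frequency difference
#'   enforced for planted variants.
#' @param seed integer seed; all outputs are deterministic given the config.
#' @return A validated [SimulationConfig] object.
#' @export
simulationConfig <- function(nVariants = 1000L, nDivergent = 0L,
                             groups = data.frame(
                               name = c("A", "B"),
                               size = c(100L, 100L),
                               fst = c(0.1, 0.1)),
                             admixedGroups = list(),
                             ancestralFreqRange = c(0.05, 0.95),
                             divergentDelta = 0.5,
                             seed = 1L) {
  groups <- as.data.frame(groups)
  groups$name <- as.character(groups$name)
  groups$size <- as.integer(groups$size)
  admixedGroups <- lapply(admixedGroups, function(a) {
    if (is.null(a$concentration)) a$concentration <- 10
    a$size <- as.integer(a$size)
    a
  })
  new("SimulationConfig", nVariants = as.integer(nVariants),
      nDivergent = as.integer(nDivergent), groups = groups,
      admixedGroups = admixedGroups,
      ancestralFreqRange = as.numeric(ancestralFreqRange),
      divergentDelta = as.numeric(divergentDelta), seed = as.integer(seed))
}

#' Default five-group cohort configuration
#'
#' A cohort with the structure of a large, diverse US biobank: four
#' non-admixed groups of unequal size (White majority, Black, Hispanic,
#' Asian) plus one broad admixed group, with moderate divergence and a
#' minority of strongly divergent variants among the background. Group
#' proportions mirror a 54/20/16/3/4 percent split; `scale` multiplies all
#' sample sizes (scale = 1 is approximately a 1/10-scale cohort of such a
#' biobank).
#'
#' @param scale multiplier on group sample sizes.
#' @param nVariants,nDivergent variant counts.
#' @param seed integer seed.
#' @return A [SimulationConfig].
#' @export
defaultCohortConfig <- function(scale = 1, nVariants = 2000L,
                                nDivergent = 40L, seed = 1L) {
  sz <- function(n) max(25L, as.integer(round(n * scale)))
  simulationConfig(
    nVariants = nVariants, nDivergent = nDivergent,
    groups = data.frame(
      name = c("White", "Black", "Hispanic", "Asian"),
      size = c(sz(2000), sz(2128), sz(1730), sz(297)),
      fst = c(0.10, 0.12, 0.05, 0.12)),
    admixedGroups = list(list(
      name = "MoreThanOne", size = sz(357),
      weights = c(White = 0.4, Black = 0.3, Hispanic = 0.3),
      concentration = 3)),
    divergentDelta = 0.5, seed = seed)
}

#' Draw latent group allele frequencies and sample ancestries
#'
#' Draws per-variant ancestral frequencies uniformly on the configured
#' range, then per-group frequencies from the Balding-Nichols Beta
#' distribution indexed by each group's `fst`. For the `nDivergent` planted
#' variants, group frequencies are rejection-sampled (up to 1000 attempts)
#' until the maximum pairwise difference reaches `divergentDelta`; on
#' failure the first and last groups are assigned frequencies 0.1 and 0.9
#' directly. Per-sample ancestry proportions for admixed samples are drawn
#' from a Dirichlet distribution centred on the group's parental weights.
#'
#' @param config a [SimulationConfig].
#' @return A [GroundTruth] object.
#' @export
simulateGroupFrequencies <- function(config) {
  validObject(config)
  .with_seed(.derive_seed(config@seed, "frequencies"), {
    m <- config@nVariants
    g <- config@groups
    k <- nrow(g)
    r <- config@ancestralFreqRange
    p_anc <- stats::runif(m, r[1], r[2])

    draw_group <- function(p, fst) {
      a <- p * (1 - fst) / fst
      b <- (1 - p) * (1 - fst) / fst
      stats::rbeta(length(p), a, b)
    }
    freqs <- vapply(seq_len(k),
                    function(i) draw_group(p_anc, g$fst[i]),
                    numeric(m))
    colnames(freqs) <- g$name

    # variant identifiers: evenly spaced synthetic chr1 coordinates
    pos <- 10000L + 100L * seq_len(m)
    refalt <- matrix(c("A", "G", "C", "T", "G", "A", "T", "C"),
                     ncol = 2, byrow = TRUE)
    ra <- refalt[(seq_len(m) - 1L) %% 4L + 1L, , drop = FALSE]
    vtab <- data.frame(chrom = "chr1", pos = pos, ref = ra[, 1],
                       alt = ra[, 2],
                       rsid = sprintf("rs9%07d", seq_len(m)))
    vids <- paste(vtab$chrom, vtab$pos, vtab$ref, vtab$alt, sep = ":")

    div_idx <- integer(0)
    if (config@nDivergent > 0L) {
      div_idx <- sort(sample.int(m, config@nDivergent))
      delta <- config@divergentDelta
      for (j in div_idx) {
        ok <- FALSE
        for (try in seq_len(1000L)) {
          cand <- vapply(seq_len(k),
                         function(i) draw_group(p_anc[j], g$fst[i]),
                         numeric(1))
          if (max(cand) - min(cand) >= delta) {
            freqs[j, ] <- cand
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          freqs[j, ] <- stats::runif(k, 0.4, 0.6)
          freqs[j, 1] <- 0.1
          freqs[j, k] <- 0.9
        }
      }
    }

    # per-sample ancestry for admixed samples
    anc_rows <- list()
    for (a in config@admixedGroups) {
      alpha <- a$weights * a$concentration
      gm <- matrix(stats::rgamma(a$size * length(alpha), shape = rep(alpha, each = a$size)),
                   nrow = a$size)
      gm <- gm / rowSums(gm)
      colnames(gm) <- names(a$weights)
      rownames(gm) <- sprintf("%s_%04d", a$name, seq_len(a$size))
      anc_rows[[a$name]] <- gm
    }
    if (length(anc_rows)) {
      parents <- unique(unlist(lapply(anc_rows, colnames)))
      ancestry <- do.call(rbind, lapply(anc_rows, function(gm) {
        out <- matrix(0, nrow(gm), length(parents),
                      dimnames = list(rownames(gm), parents))
        out[, colnames(gm)] <- gm
        out
      }))
    } else {
      ancestry <- matrix(numeric(0), 0, 0)
    }

    rownames(freqs) <- vids
    new("GroundTruth", ancestralFreqs = stats::setNames(p_anc, vids),
        groupFreqs = freqs, divergentVariants = vids[div_idx],
        ancestry = ancestry, variantIds = vids, variantTable = vtab)
  })
}

#' Simulate diploid genotypes from a ground truth
#'
#' Non-admixed samples draw dosages Binomial(2, p) at each variant from
#' their group's frequency. Admixed samples draw each of their two allele
#' copies independently: a parental group is chosen by the sample's
#' ancestry proportions, then the copy is Bernoulli with that group's
#' frequency.
#'
#' @param truth a [GroundTruth] from [simulateGroupFrequencies()].
#' @param config the same [SimulationConfig].
#' @return A [PGxGenotypes] with `colData()$group` labels.
#' @export
simulateGenotypes <- function(truth, config) {
  validObject(config)
  stopifnot(identical(truth@variantIds, rownames(truth@groupFreqs)))
  .with_seed(.derive_seed(config@seed, "genotypes"), {
    m <- config@nVariants
    g <- config@groups
    freqs <- truth@groupFreqs

    blocks <- list()
    labels <- character(0)
    ids <- character(0)
    for (i in seq_len(nrow(g))) {
      n <- g$size[i]
      p <- freqs[, g$name[i]]
      block <- matrix(stats::rbinom(m * n, 2L, rep(p, times = n)), nrow = m)
      blocks[[length(blocks) + 1L]] <- block
      ids <- c(ids, sprintf("%s_%04d", g$name[i], seq_len(n)))
      labels <- c(labels, rep(g$name[i], n))
    }
    for (a in config@admixedGroups) {
      anc <- truth@ancestry
      snames <- sprintf("%s_%04d", a$name, seq_len(a$size))
      block <- matrix(0L, nrow = m, ncol = a$size)
      parents <- colnames(anc)
      for (s in seq_len(a$size)) {
        w <- anc[snames[s], ]
        d <- integer(m)
        for (copy in 1:2) {
          par <- sample(parents, m, replace = TRUE, prob = w)
          d <- d + stats::rbinom(m, 1L, freqs[cbind(seq_len(m), match(par, colnames(freqs)))])
        }
        block[, s] <- d
      }
      blocks[[length(blocks) + 1L]] <- block
      ids <- c(ids, snames)
      labels <- c(labels, rep(a$name, a$size))
    }

    dosage <- do.call(cbind, blocks)
    colnames(dosage) <- ids
    PGxGenotypes(dosage, truth@variantTable, sampleIds = ids, groups = labels)
  })
}

#' Hudson-style FST estimate from group allele frequencies
#'
#' Ratio-of-averages estimator over variants for two groups:
#' `1 - mean(Hw) / mean(Hb)` with within-group heterozygosity
#' `Hw = p1(1-p1) + p2(1-p2)` and between-group `Hb = p1(1-p2) + p2(1-p1)`.
#' Used to verify simulator calibration against the target divergence.
#'
#' @param p1,p2 per-variant allele frequencies for the two groups.
#' @return A single FST estimate.
#' @export
hudsonFst <- function(p1, p2) {
  stopifnot(length(p1) == length(p2))
  hw <- p1 * (1 - p1) + p2 * (1 - p2)
  hb <- p1 * (1 - p2) + p2 * (1 - p1)
  1 - mean(hw) / mean(hb)
}
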