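# Genotype PCA with per-variant allele weights, and divergent-variant
# ranking by allele-weight magnitude.

.randomized_svd <- function(x, k, seed, oversample = 10L, power = 2L) {
  .with_seed(seed, {
    l <- min(ncol(x), k + oversample)
    omega <- matrix(stats::rnorm(ncol(x) * l), ncol(x), l)
    y <- x %*% omega
    q <- qr.Q(qr(y))
    for (i in seq_len(power)) {
      q <- qr.Q(qr(crossprod(x, q)))
      q <- qr.Q(qr(x %*% q))
    }
    b <- crossprod(q, x)
    s <- svd(b, nu = k, nv = k)
    list(u = q %*% s$u, d = s$d[seq_len(k)], v = s$v)
  })
}

#' Fit a genotype principal component analysis
#'
#' Dosages are standardized per variant: centred at twice the estimated
#' allele frequency and scaled by `sqrt(2 p (1-p))` — the
#' EIGENSTRAT/smartpca convention, under which each variant's expected
#' binomial variance is 1. Missing dosages are mean-imputed after frequency
#' estimation (so they contribute zero after centring). Monomorphic
#' variants are dropped with a message. The decomposition is exact
#' (truncated SVD of the standardized matrix) for cohorts up to
#' `exactLimit` samples and a seeded randomized truncated SVD above that.
#' The sign of each PC is fixed so that its largest-magnitude allele weight
#' is positive.
#'
#' Allele weights are the right singular vectors: per-variant dosage
#' coefficients such that each sample's PC score is the weighted sum of its
#' standardized dosages. A weight's magnitude measures how much that
#' variant contributes to between-sample divergence along the PC.
#'
#' @param gt a [PGxGenotypes].
#' @param nPCs number of components (at most 25 by convention; must not
#'   exceed samples - 1 or the number of usable variants).
#' @param seed seed for the randomized solver.
#' @param exactLimit sample count above which the randomized solver is
#'   used.
#' @return A [PGxPCA].
#' @export
fitGenotypePCA <- function(gt, nPCs = 25L, seed = 1L, exactLimit = 2000L) {
  d <- dosages(gt)
  if (any(rowSums(!is.na(d)) == 0L))
    stop("variants with no called genotypes present; remove them first")
  x <- t(d)  # samples x variants
  n <- nrow(x)
  p <- colMeans(x, na.rm = TRUE) / 2
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    message(sum(mono), " monomorphic variant(s) dropped")
    x <- x[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  nPCs <- as.integer(nPCs)
  if (ncol(x) < nPCs)
    stop("fewer usable variants (", ncol(x), ") than requested PCs (",
         nPCs, ")")
  if (n < nPCs + 1L)
    stop("need at least nPCs + 1 samples")
  center <- 2 * p
  scale <- sqrt(2 * p * (1 - p))
  xs <- sweep(x, 2L, center)
  xs[is.na(xs)] <- 0  # mean imputation after centring
  xs <- sweep(xs, 2L, scale, "/")

  if (n <= exactLimit) {
    sv <- svd(xs, nu = nPCs, nv = nPCs)
    d_sv <- sv$d[seq_len(nPCs)]
    v <- sv$v
    method <- "exact"
  } else {
    rs <- .randomized_svd(xs, nPCs, seed = seed)
    d_sv <- rs$d
    v <- rs$v
    method <- "randomized"
  }
  # fix signs: largest-magnitude weight per PC is positive
  for (i in seq_len(nPCs)) {
    j <- which.max(abs(v[, i]))
    if (v[j, i] < 0) v[, i] <- -v[, i]
  }
  scores <- xs %*% v
  total_var <- sum(xs^2)
  ev <- d_sv^2 / total_var
  dimnames(v) <- list(colnames(x), paste0("PC", seq_len(nPCs)))
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(nPCs)))
  new("PGxPCA", scores = scores, alleleWeights = v, center = center,
      scale = scale, explainedVariance = ev, nDropped = as.integer(sum(mono)),
      method = method)
}

#' Rank variants by allele-weight divergence
#'
#' The divergence score of a variant is the maximum absolute allele weight
#' over the selected PCs (PC1 and PC2 by default, where population
#' structure concentrates). Variants are returned in non-increasing score
#' order, ties keeping input order, with per-PC weights and any matching
#' annotation fields (joined by rsID, falling back to the positional
#' variant id).
#'
#' @param model a [PGxPCA].
#' @param annotation optional [PGxAnnotation] to join.
#' @param pcs PC indices to score over (nonempty, within the fitted PCs).
#' @param rsids optional named character vector mapping variant ids to
#'   rsIDs (e.g. built from the genotypes' row metadata), used as the
#'   primary annotation join key.
#' @return A `DFrame` with columns `variant_id`, per-PC `weight_PC*`,
#'   `divergence`, `rank` and annotation columns where joined.
#' @export
rankDivergentVariants <- function(model, annotation = NULL, pcs = c(1L, 2L),
                                  rsids = NULL) {
  w <- alleleWeights(model)
  if (!length(pcs)) stop("pcs must be a nonempty set of PC indices")
  if (any(pcs < 1L | pcs > ncol(w)))
    stop("pcs outside the fitted PCs (1..", ncol(w), ")")
  sub <- abs(w[, pcs, drop = FALSE])
  score <- unname(apply(sub, 1L, max))
  o <- order(-score)  # stable: ties keep input order
  out <- DataFrame(variant_id = rownames(w)[o])
  for (i in pcs) out[[paste0("weight_PC", i)]] <- w[o, i]
  out$divergence <- score[o]
  out$rank <- seq_len(nrow(out))
  if (!is.null(annotation) && nrow(annotation)) {
    ann <- as.data.frame(annotation)
    vid <- out$variant_id
    rs <- if (!is.null(rsids)) unname(rsids[vid]) else rep(NA_character_, length(vid))
    idx <- match(rs, ann$rsid)  # rsID is the primary join key
    na <- is.na(idx)
    idx[na] <- match(vid[na], ann$variant_id)
    for (col in c("rsid", "gene", "drugs", "evidence_level",
                  "association_type", "mode_of_effect", "effect_allele"))
      out[[col]] <- ifelse(is.na(idx), NA_character_, ann[[col]][idx])
  }
  out
}
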