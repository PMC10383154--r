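# Per-group allele frequencies and Hardy-Weinberg genotype fractions.

#' Per-group alternate-allele frequencies
#'
#' For each (variant, group) cell, the frequency is the sum of dosages over
#' samples with a non-missing call divided by twice the number of such
#' samples (missing calls are excluded from the denominator). Cells with no
#' called samples get `freq = NA`, `n_called = 0`. Samples without a label
#' are excluded with a message.
#'
#' @param gt a [PGxGenotypes].
#' @param labels optional named group labels; defaults to
#'   `groupLabels(gt)`.
#' @return A [GroupFrequencyTable] ordered by variant then group.
#' @export
groupAlleleFrequencies <- function(gt, labels = groupLabels(gt)) {
  if (is.null(labels)) stop("no group labels supplied or attached")
  d <- dosages(gt)
  lab <- labels[colnames(d)]
  unl <- is.na(lab)
  if (any(unl)) {
    message(sum(unl), " unlabeled sample(s) excluded")
    d <- d[, !unl, drop = FALSE]
    lab <- lab[!unl]
  }
  groups <- sort(unique(unname(lab)))
  if (!length(groups)) stop("no labeled samples")
  m <- mcols(rowRanges(gt))
  res <- lapply(groups, function(g) {
    sub <- d[, lab == g, drop = FALSE]
    n_called <- unname(rowSums(!is.na(sub)))
    s <- unname(rowSums(sub, na.rm = TRUE))
    freq <- ifelse(n_called > 0L, s / (2 * n_called), NA_real_)
    DataFrame(variant_id = m$variant_id, rsid = m$rsid, group = g,
              allele = m$alt, freq = freq, n_called = as.integer(n_called))
  })
  out <- do.call(rbind, res)
  o <- order(match(out$variant_id, m$variant_id), out$group)
  new("GroupFrequencyTable", out[o, ])
}

#' Hardy-Weinberg genotype fractions
#'
#' For effect-allele frequency `p`, the expected genotype fractions under
#' Hardy-Weinberg equilibrium: homozygous effect `p^2`, heterozygous
#' `2p(1-p)`, homozygous other `(1-p)^2`. Vectorized over `p`.
#'
#' @param p allele frequency (or vector), each in \[0, 1\].
#' @return A data.frame with columns `hom`, `het`, `other` summing to 1.
#' @export
hwFractions <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("allele frequency must lie in [0, 1]")
  data.frame(hom = p^2, het = 2 * p * (1 - p), other = (1 - p)^2)
}
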