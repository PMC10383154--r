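# Predicted excess adverse drug reactions per 1000 treated between two
# groups, from effect-allele frequencies under Hardy-Weinberg genotype
# fractions.
#
# Recessive toxicity (two effect-allele copies needed): the affected
# fraction is the homozygote fraction p^2, so the signed excess is
#   1000 * (p_a^2 - p_b^2).
# Dominant toxicity (one or two copies): the affected fraction is the
# carrier fraction p^2 + 2p(1-p) = 1 - (1-p)^2, so the signed excess is
#   1000 * [(p_a^2 - p_b^2) + (2 p_a (1-p_a) - 2 p_b (1-p_b))].

#' Excess adverse drug reactions per 1000 treated
#'
#' Signed difference between two groups in the expected fraction of
#' treated patients affected by a toxicity allele, per 1000, under
#' Hardy-Weinberg genotype fractions. Positive values mean more predicted
#' reactions in group a. Antisymmetric in (a, b); zero when the
#' frequencies are equal. Vectorized over frequencies.
#'
#' @param pA,pB effect-allele frequencies in \[0, 1\] for groups a and b.
#' @param mode "dominant" (carriers affected) or "recessive" (homozygotes
#'   affected).
#' @return Signed excess reactions per 1000 treated, in \[-1000, 1000\].
#' @export
excessADR <- function(pA, pB, mode = c("dominant", "recessive")) {
  mode <- match.arg(mode)
  for (p in list(pA, pB))
    if (any(!is.finite(p)) || any(p < 0 | p > 1))
      stop("effect-allele frequencies must lie in [0, 1]")
  if (mode == "recessive") {
    1000 * (pA^2 - pB^2)
  } else {
    1000 * ((pA^2 - pB^2) + (2 * pA * (1 - pA) - 2 * pB * (1 - pB)))
  }
}

#' Round a reported excess-ADR value
#'
#' Reporting-layer rounding: half away from zero on the magnitude, sign
#' preserved. The continuous value should always be kept alongside.
#'
#' @param x signed excess per 1000.
#' @return Integer-valued numeric.
#' @export
roundADR <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Excess-ADR table for all toxicity variants and groups
#'
#' For every annotation row with `association_type == "toxicity"` and a
#' known mode of effect, and every group in the frequency table other than
#' the reference, computes the signed excess adverse reactions per 1000
#' treated (group vs reference). Frequencies are oriented to the
#' annotation's effect allele: when the frequency table's counted allele
#' differs from the effect allele, `1 - freq` is used. Rows with unknown
#' mode are skipped with a message; variants or groups absent from the
#' frequency table are skipped with a warning.
#'
#' @param freqs a [GroupFrequencyTable].
#' @param annotation a [PGxAnnotation].
#' @param referenceGroup the comparison group (e.g. the majority group).
#' @return A `DFrame` with columns `variant_id`, `rsid`, `drug`, `mode`,
#'   `group`, `reference`, `p_group`, `p_reference`,
#'   `excess_per_1000` (continuous, signed), `excess_reported` (rounded
#'   magnitude) and `direction` (which group bears the predicted excess;
#'   `"none"` at exact equality).
#' @export
adrTable <- function(freqs, annotation, referenceGroup) {
  if (!referenceGroup %in% freqs$group)
    stop("reference group '", referenceGroup, "' absent from frequency table")
  tox <- annotation[annotation$association_type == "toxicity", , drop = FALSE]
  unknown <- tox$mode_of_effect == "unknown"
  if (any(unknown))
    message(sum(unknown), " toxicity annotation(s) with unknown mode skipped")
  tox <- tox[!unknown, , drop = FALSE]
  groups <- setdiff(unique(freqs$group), referenceGroup)

  lookup <- function(variant_id, rsid, group) {
    hit <- which((freqs$rsid == rsid & rsid != "") |
                   freqs$variant_id == variant_id)
    hit <- hit[freqs$group[hit] == group]
    if (!length(hit)) return(NULL)
    freqs[hit[1], ]
  }

  out <- list()
  for (i in seq_len(nrow(tox))) {
    ref_row <- lookup(tox$variant_id[i], tox$rsid[i], referenceGroup)
    if (is.null(ref_row) || is.na(ref_row$freq)) {
      warning("no reference-group frequency for ", tox$rsid[i],
              "; variant skipped", call. = FALSE)
      next
    }
    orient <- function(row) {
      if (row$allele == tox$effect_allele[i]) row$freq else 1 - row$freq
    }
    p_ref <- orient(ref_row)
    for (g in groups) {
      row <- lookup(tox$variant_id[i], tox$rsid[i], g)
      if (is.null(row) || is.na(row$freq)) next
      p_g <- orient(row)
      ex <- excessADR(p_g, p_ref, tox$mode_of_effect[i])
      out[[length(out) + 1L]] <- DataFrame(
        variant_id = tox$variant_id[i], rsid = tox$rsid[i],
        drug = tox$drugs[i], mode = tox$mode_of_effect[i], group = g,
        reference = referenceGroup, p_group = p_g, p_reference = p_ref,
        excess_per_1000 = ex, excess_reported = abs(roundADR(ex)),
        direction = if (ex > 0) g else if (ex < 0) referenceGroup else "none")
    }
  }
  if (!length(out))
    return(DataFrame(variant_id = character(0), rsid = character(0),
                     drug = character(0), mode = character(0),
                     group = character(0), reference = character(0),
                     p_group = numeric(0), p_reference = numeric(0),
                     excess_per_1000 = numeric(0),
                     excess_reported = numeric(0), direction = character(0)))
  do.call(rbind, out)
}
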