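# Readers and writers for the formats the pipeline touches: VCF genotypes
# (GT-only subset of VCF 4.2), group label TSV, annotation TSV, frequency
# TSV. Missing genotypes stay missing at this layer; imputation happens only
# inside the PCA fit.

#' Read diploid genotypes from a VCF file
#'
#' Parses the GT field of a VCF (4.x, plain text or bgzipped) into
#' alternate-allele dosages. `./.` (or `.|.`) becomes a missing call.
#' Multiallelic records are rejected by default, with a count of affected
#' records; with `multiallelic = "split"` each alternate allele becomes its
#' own biallelic row and dosage counts copies of that allele.
#'
#' @param path VCF file path.
#' @param multiallelic one of "error", "drop", "split".
#' @return A [PGxGenotypes].
#' @export
readGenotypeVCF <- function(path, multiallelic = c("error", "drop", "split")) {
  multiallelic <- match.arg(multiallelic)
  head1 <- readLines(path, n = 1L)
  if (!startsWith(head1, "##fileformat=VCF"))
    stop("malformed VCF header at line 1: expected ##fileformat=VCF...")
  vcf <- VariantAnnotation::readVcf(path)
  if (!"GT" %in% names(VariantAnnotation::geno(vcf)))
    stop("VCF has no GT genotype field")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(altl)
  gt <- VariantAnnotation::geno(vcf)$GT

  multi <- which(n_alt > 1L)
  if (length(multi) && multiallelic == "error")
    stop(length(multi), " multiallelic record(s) found; ",
         "use multiallelic = 'drop' or 'split'")

  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  rsid <- names(rr)
  rsid <- ifelse(is.na(rsid) | !grepl("^rs", rsid), "", rsid)

  parse_gt <- function(gstr, allele_index) {
    # dosage of a specific alt allele index from "a/b" or "a|b"
    miss <- gstr %in% c("./.", ".|.", ".")
    parts <- strsplit(gstr, "[/|]")
    bad <- !miss & lengths(parts) != 2L
    if (any(bad))
      stop("non-diploid GT in record(s): ",
           paste(utils::head(which(bad), 3), collapse = ", "))
    a <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    b <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
    d <- (a == allele_index) + (b == allele_index)
    d[miss] <- NA_integer_
    d
  }

  rows <- list()
  vt <- list()
  for (i in seq_len(nrow(gt))) {
    if (n_alt[i] > 1L) {
      if (multiallelic == "drop") next
      for (k in seq_len(n_alt[i])) {
        rows[[length(rows) + 1L]] <- parse_gt(gt[i, ], k)
        vt[[length(vt) + 1L]] <- data.frame(
          chrom = chrom[i], pos = pos[i], ref = ref[i],
          alt = as.character(altl[[i]][k]), rsid = rsid[i])
      }
    } else {
      rows[[length(rows) + 1L]] <- parse_gt(gt[i, ], 1L)
      vt[[length(vt) + 1L]] <- data.frame(
        chrom = chrom[i], pos = pos[i], ref = ref[i],
        alt = as.character(altl[[i]][1]), rsid = rsid[i])
    }
  }
  if (length(multi) && multiallelic == "drop")
    message(length(multi), " multiallelic record(s) dropped")
  dosage <- do.call(rbind, rows)
  variants <- do.call(rbind, vt)
  PGxGenotypes(dosage, variants, sampleIds = colnames(gt))
}

#' Write genotypes as a GT-only VCF 4.2 file
#'
#' @param gt a [PGxGenotypes].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenotypeVCF <- function(gt, path) {
  rr <- rowRanges(gt)
  m <- mcols(rr)
  d <- dosages(gt)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=pgxStrat",
    paste0("##contig=<ID=", unique(chrom), ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(d)), collapse = "\t"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[d + 1L], nrow = nrow(d))
  gt_str[is.na(d)] <- "./."
  id <- ifelse(m$rsid == "" | is.na(m$rsid), ".", m$rsid)
  body <- paste(chrom, GenomicRanges::start(rr), id, m$ref, m$alt, ".",
                "PASS", ".", "GT",
                apply(gt_str, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read or write a two-column sample-to-group label table
#'
#' TSV with header `sample_id<TAB>group`.
#'
#' @param path file path.
#' @return `readGroupLabels`: named character vector of group labels.
#' @export
readGroupLabels <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  if (!all(c("sample_id", "group") %in% colnames(df)))
    stop("label table needs columns sample_id, group")
  stats::setNames(df$group, df$sample_id)
}

#' @rdname readGroupLabels
#' @param labels named character vector (names = sample ids).
#' @export
writeGroupLabels <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), group = unname(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pharmacogenomic variant annotation table
#'
#' TSV with columns `variant_id`, `rsid`, `gene`, `drugs`, `evidence_level`,
#' `association_type`, `mode_of_effect`, `effect_allele`. Controlled
#' vocabularies are enforced: evidence level in 1A/1B/2A/2B/3/4,
#' association type in efficacy/dosage/toxicity/other, mode of effect in
#' dominant/recessive/unknown.
#'
#' @param path TSV path.
#' @return A [PGxAnnotation].
#' @export
readPGxAnnotation <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  miss <- setdiff(.ANNOTATION_COLS, colnames(df))
  if (length(miss))
    stop("annotation schema error: missing column(s) ",
         paste(miss, collapse = ", "))
  check_vocab <- function(col, vocab) {
    bad <- which(!df[[col]] %in% vocab)
    if (length(bad))
      stop("annotation row ", bad[1], ": invalid ", col, " '",
           df[[col]][bad[1]], "' (allowed: ", paste(vocab, collapse = ", "),
           ")")
  }
  if (nrow(df)) {
    check_vocab("evidence_level", .EVIDENCE_LEVELS)
    check_vocab("association_type", .ASSOCIATION_TYPES)
    check_vocab("mode_of_effect", .EFFECT_MODES)
  }
  new("PGxAnnotation", DataFrame(df))
}

#' @rdname readPGxAnnotation
#' @param annotation a [PGxAnnotation].
#' @export
writePGxAnnotation <- function(annotation, path) {
  utils::write.table(as.data.frame(annotation), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a per-group allele frequency table
#'
#' TSV with columns `variant_id`, `rsid`, `group`, `allele`, `freq`,
#' `n_called`; frequencies written to 6 decimal places.
#'
#' @param path TSV path.
#' @return `readGroupFrequencies`: a [GroupFrequencyTable].
#' @export
readGroupFrequencies <- function(path) {
  df <- utils::read.delim(path, colClasses = c(
    variant_id = "character", rsid = "character", group = "character",
    allele = "character", freq = "numeric", n_called = "integer"))
  new("GroupFrequencyTable", DataFrame(df))
}

#' @rdname readGroupFrequencies
#' @param freqs a [GroupFrequencyTable].
#' @export
writeGroupFrequencies <- function(freqs, path) {
  df <- as.data.frame(freqs)
  df$freq <- ifelse(is.na(df$freq), NA, sprintf("%.6f", df$freq))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Restrict genotypes to annotated variants
#'
#' Matches primarily on rsID, falling back to the positional
#' chr:pos:ref:alt identifier for variants without an rsID match. The
#' numbers of kept and dropped variants are reported via `message()` and
#' recorded in `metadata(x)$intersect`.
#'
#' @param gt a [PGxGenotypes].
#' @param annotation a [PGxAnnotation].
#' @return The genotype submatrix of annotated variants.
#' @export
intersectVariants <- function(gt, annotation) {
  if (nrow(gt) == 0L || nrow(annotation) == 0L)
    stop("both genotypes and annotation must be nonempty")
  m <- mcols(rowRanges(gt))
  ann_rsid <- unique(annotation$rsid[annotation$rsid != ""])
  keep <- m$rsid %in% ann_rsid | m$variant_id %in% annotation$variant_id
  n_keep <- sum(keep)
  if (n_keep == 0L)
    stop("empty intersection: no genotype variant matches the annotation")
  message("intersectVariants: kept ", n_keep, ", dropped ",
          sum(!keep), " variant(s)")
  out <- gt[keep, ]
  metadata(out)$intersect <- list(kept = n_keep, dropped = sum(!keep))
  out
}
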