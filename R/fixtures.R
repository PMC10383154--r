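# Bundled example tables.

#' Bundled example annotation and frequency tables
#'
#' Returns a curated 20-record pharmacogenomic annotation table of highly
#' group-divergent variants with their gene-drug associations and evidence
#' levels, plus a per-group effect-allele frequency table for the four
#' toxicity variants with a known mode of effect (warfarin/VKORC1
#' rs9923231, tacrolimus-metabolism CYP3A4 rs4646437, methotrexate/MTHFR
#' rs1801133, gefitinib/IKBKB rs9694958). Together they drive the worked
#' excess-ADR examples in the package documentation.
#'
#' @return A list with elements `annotation` ([PGxAnnotation]) and
#'   `frequencies` ([GroupFrequencyTable]).
#' @export
examplePGxData <- function() {
  ann <- readPGxAnnotation(system.file("extdata",
                                       "divergent_pgx_annotation.tsv",
                                       package = "pgxStrat"))
  fr <- readGroupFrequencies(system.file("extdata",
                                         "example_group_frequencies.tsv",
                                         package = "pgxStrat"))
  list(annotation = ann, frequencies = fr)
}
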