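#' Paths to the curated example tables shipped with the package
#'
#' The package ships three small tab-separated catalogues of RNAs altered
#' across a panel of human cancers, used in examples and tests:
#' `common_mrna_classI_II.tsv` (direction-consistent common mRNAs),
#' `common_mrna_classIII.tsv` (mixed-direction common mRNAs) and
#' `common_mirna.tsv` (common miRNAs over 15 cancers with cytoband locations
#' and risk-region flags). See [read_common_rna_table()] /
#' [read_mirna_table()] for the layout.
#'
#' @param name File name within the package's `extdata` directory; `NULL`
#'   lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
pcsr_example_file <- function(name = NULL) {
  if (is.null(name)) {
    return(list.files(system.file("extdata", package = "pcsrscan")))
  }
  path <- system.file("extdata", name, package = "pcsrscan")
  if (!nzchar(path)) stop("no such example file: ", name)
  path
}
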