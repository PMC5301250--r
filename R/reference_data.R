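#' Published reference table of high-emitting protected areas
#'
#' A transcription of a published table of 23 tropical PAs flagged as
#' emitting disproportionately more carbon than their year-2000 forest
#' area predicts (studentised residuals > 2). Columns: PA name, mean AGB
#' (Mg ha^-1), country, forest area in 2000 (km^2), IUCN category,
#' corrected 2000-2012 forest loss (%), total carbon stock (Mg C), annual
#' carbon loss (Mg C yr^-1) and the reported studentised residual. Used
#' as a worked-example input: recomputing each row's annual loss from its
#' printed stock and corrected loss percentage reproduces the printed
#' Mg C yr^-1 column to within the rounding of the printed rate.
#'
#' @return Data frame with 23 rows.
#' @examples
#' ref <- emitting_pa_reference()
#' head(ref$name)
#' @export
emitting_pa_reference <- function() {
  utils::read.csv(system.file("extdata", "emitting_pa_reference.csv",
                              package = "pacarbon", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
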