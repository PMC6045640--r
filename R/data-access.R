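#' Bundled example dosimetry and measurement tables
#'
#' Small plain-text tables from a seven-patient lung dose-escalation planning
#' study, bundled for examples and for exercising the statistical and
#' reporting operations: per-patient planning-target-volume (PTV) dose
#' metrics for a uniform-prescription plan A versus a sub-volume
#' dose-escalation plan B (`"ptv_dosimetry"`), the same comparison for
#' organs at risk (`"oar_dosimetry"`), and the measured metabolic sub-volume
#' sizes (`"subvolume_measurements"`).
#'
#' @param name one of `"ptv_dosimetry"`, `"oar_dosimetry"`,
#'   `"subvolume_measurements"`.
#' @return A data frame.
#' @export
example_table <- function(name = c("ptv_dosimetry", "oar_dosimetry",
                                   "subvolume_measurements")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "mtvseg",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
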