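#' Paths to the shipped example data files
#'
#' With no argument, lists the available files. The shipped set covers a
#' complete cutin workflow: replicate swelling data for seven solvents
#' (reactive solvents pre-flagged), the solvent HSP reference table, the
#' six-group food-component summary database, a small polymer table (cutin,
#' PLA, and a PHB placeholder), an illustrative component-level database
#' (plausible handbook-style values, not a published dataset), and a
#' documentation-only UV-VIS absorbance table from a 6-month sunflower-oil
#' contact experiment (no computation consumes it).
#'
#' @param file File name, e.g. `"cutin_swelling.csv"`.
#' @return A file path, or a character vector of file names.
#' @export
hspcompat_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "hspcompat")))
  }
  system.file("extdata", file, package = "hspcompat", mustWork = TRUE)
}

#' Built-in cutin swelling dataset
#'
#' Replicate volumetric swelling of cross-linked cutin films in seven
#' solvents (24 h immersion, two independent repetitions). Water is
#' pre-flagged as excluded: it hydrolyzes the polyester during immersion, so
#' its swelling does not refer to the same polymer structure. Isopropanol is
#' suspected of transesterification; exclude it via the `exclude` argument
#' for the more conservative five-solvent fit.
#'
#' @param exclude_isopropanol Also flag isopropanol as chemically altering
#'   (default FALSE).
#' @return A `"swelling_dataset"`.
#' @export
cutin_swelling <- function(exclude_isopropanol = FALSE) {
  ds <- read_swelling(hspcompat_example("cutin_swelling.csv"))
  if (exclude_isopropanol) {
    ds$excluded <- c(ds$excluded,
                     c(isopropanol = "chemical_alteration"))
  }
  ds
}
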