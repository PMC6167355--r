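#' The seven canonical X-STR linkage groups
#'
#' Physically clustered X-STRs inherit as units, so haplotype statistics
#' replace per-locus statistics for them. This is the standard grouping of
#' the 19-locus panel established by pedigree and population studies:
#' LG1 on the short arm, LG2 spanning the centromere, LG3-LG7 on the long arm.
#'
#' @return named list of ordered locus vectors (LG1..LG7).
#' @export
default_linkage_groups <- function() {
  list(
    LG1 = c("DXS10148", "DXS10135", "DXS8378"),
    LG2 = c("DXS10159", "DXS10162", "DXS10164"),
    LG3 = c("DXS7132", "DXS10079", "DXS10074", "DXS10075"),
    LG4 = c("DXS6809", "DXS6789"),
    LG5 = c("DXS7424", "DXS101"),
    LG6 = c("DXS10103", "HPRTB", "DXS10101"),
    LG7 = c("DXS10134", "DXS7423")
  )
}

#' The 19 loci of the extended X-STR panel, in report order
#'
#' @return character vector of locus names.
#' @export
panel_loci <- function() {
  c("DXS8378", "DXS7423", "DXS10148", "DXS10159", "DXS10134", "DXS7424",
    "DXS10164", "DXS10162", "DXS7132", "DXS10079", "DXS6789", "DXS101",
    "DXS10103", "DXS10101", "HPRTB", "DXS6809", "DXS10075", "DXS10074",
    "DXS10135")
}

#' The 11 loci shared with the 12-locus commercial X-STR kit
#'
#' Named preset for restricting inter-population comparisons to the loci that
#' overlap between the 19-locus panel and the widely genotyped 12-locus kit.
#'
#' @return character vector of 11 locus names.
#' @export
argus_overlap_loci <- function() {
  c("DXS7132", "DXS10079", "DXS10074", "DXS10103", "HPRTB", "DXS10101",
    "DXS10134", "DXS10148", "DXS10135", "DXS8378", "DXS7423")
}
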