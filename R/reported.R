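#' Published Gelao reference parameter tables
#'
#' The per-locus and per-linkage-group forensic parameter tables published
#' for the Guizhou Gelao population survey of the 19-locus X-STR panel
#' (513 individuals: 265 females, 248 males), shipped as plain-text data.
#' They serve as reference inputs for worked examples and for reproducing
#' the survey's combined powers from its printed per-unit values.
#'
#' @param which `"loci"` (19 rows, one per X-STR) or `"groups"` (7 rows, one
#'   per linkage group).
#' @return `data.frame` of published values (4-decimal precision as printed).
#' @export
reported_gelao_parameters <- function(which = c("loci", "groups")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0("reported_",
                          if (which == "loci") "locus" else "group",
                          "_parameters_gelao.csv"),
                   package = "xstrpop", mustWork = TRUE)
  read.table(f, header = TRUE, sep = ",", stringsAsFactors = FALSE)
}
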