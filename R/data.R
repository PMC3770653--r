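# Bundled reference datasets: a cohort of Spanish Lynch-syndrome families
# with characterized MSH2 large genomic rearrangements, the breakpoint
# features of the six fully sequenced junctions, and the published
# genotype-phenotype margin counts for MSH2 mutation carriers.  All three
# are small plain-text tables shipped under inst/extdata.

.extdata <- function(file) {
  system.file("extdata", file, package = "rearrangemap", mustWork = TRUE)
}

#' Carrier cohort of MSH2 rearrangement families
#'
#' One row per carrier individual across nine families with a pathogenic
#' MSH2 large genomic rearrangement (plus EPCAM-MSH2 in one family):
#' clinical criteria class, tumor history, mutation designation and
#' family-level pathogenicity flag.
#'
#' @return Individual-level cohort `data.frame`.
#' @export
msh2_lgr_cohort <- function() {
  df <- utils::read.delim(.extdata("msh2_lgr_cohort.tsv"),
                          stringsAsFactors = FALSE,
                          colClasses = c(family_id = "character"))
  df$tumors[is.na(df$tumors)] <- ""
  df$affected <- nzchar(df$tumors)
  df
}

#' Breakpoint features of the fully characterized MSH2 rearrangements
#'
#' The six sequenced junctions with their genomic coordinates, junction
#' microhomology, the repeat elements embedding each breakpoint (with
#' orientation) and the mechanism proposed from those features.
#'
#' @return A `data.frame`, one row per junction.
#' @export
msh2_breakpoint_features <- function() {
  utils::read.delim(.extdata("msh2_breakpoint_features.tsv"),
                    stringsAsFactors = FALSE)
}

#' Genotype-phenotype margin counts for MSH2 mutation carriers
#'
#' Per mutation class (point mutation vs large rearrangement): numbers of
#' affected and healthy carriers, carriers with one vs more than one tumor,
#' carriers developing colorectal or endometrial cancer, and the mean age
#' at first diagnosis.
#'
#' @return A `data.frame` with one row per mutation class.
#' @export
msh2_phenotype_counts <- function() {
  utils::read.delim(.extdata("msh2_phenotype_counts.tsv"),
                    stringsAsFactors = FALSE)
}
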