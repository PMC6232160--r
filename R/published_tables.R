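#' Published per-family summary tables for the giant reed miRNA survey
#'
#' Bundled copies of the published per-family counts for *Arundo donax*:
#' `published_locus_counts()` returns the rice-homolog locus table (one row
#' per miRNA family: rice locus count, inferred A. donax locus count, and
#' the per-rice-locus breakdown string with bracketed counts);
#' `published_target_counts()` returns the conserved-target table (per
#' family: targets conserved overall and against rice, maize, Arabidopsis
#' and grapevine, plus novel targets; NA where the species lacks the
#' family). These serve as inputs for recomputing the survey's summary
#' arithmetic with [locus_table_totals()] and
#' [conservation_table_totals()].
#'
#' @return a data.frame.
#' @export
published_locus_counts <- function() {
  utils::read.delim(system.file("extdata", "adonax_locus_counts.tsv",
                                package = "mirhunt"),
                    stringsAsFactors = FALSE)
}

#' @rdname published_locus_counts
#' @export
published_target_counts <- function() {
  utils::read.delim(system.file("extdata", "conserved_target_counts.tsv",
                                package = "mirhunt"),
                    na.strings = ".", stringsAsFactors = FALSE)
}
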