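#' Packaged transcriptions of published cohort-level tables
#'
#' The package ships plain-text transcriptions of the cohort-level summary
#' tables of the source exome study of adult-onset hearing loss (category
#' by sex participant counts, mean ages and noise-history counts for the
#' primary and follow-up cohorts; the list of variant-level
#' threshold-difference hits with their effect directions; deafness
#' gene-list composition; Sanger validation counts). They serve as inputs
#' for consistency checks: package functions recompute the derived figures
#' (weighted overall means, within-stratum percentages, direction tallies)
#' from these raw counts.
#'
#' @param name One of `"musc_summary"`, `"twinsuk_summary"`,
#'   `"scan_hits"`, `"deafness_counts"`, `"sanger"`.
#' @return The corresponding data frame.
#' @export
published_table <- function(name = c("musc_summary", "twinsuk_summary",
                                     "scan_hits", "deafness_counts",
                                     "sanger")) {
  name <- match.arg(name)
  file <- switch(name,
    musc_summary = "cohort_summary_musc.csv",
    twinsuk_summary = "cohort_summary_twinsuk.csv",
    scan_hits = "threshold_scan_hits_musc.tsv",
    deafness_counts = "deafness_gene_counts.csv",
    sanger = "sanger_validation.csv")
  path <- system.file("extdata", file, package = "presbyscan",
                      mustWork = TRUE)
  if (endsWith(file, ".tsv"))
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, quote = "",
                      comment.char = "")
  else
    utils::read.csv(path, stringsAsFactors = FALSE)
}
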