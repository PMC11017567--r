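#' Male/female case counts of the public reference cohorts
#'
#' Per-cancer-type counts of male and female cases in the public cohorts the
#' TI method was developed on: the 26 adult TCGA pan-cancer types
#' (7881 cases) and the four pediatric neural tumor types analyzed from the
#' Kids First and CBTN programs (489 cases). These counts are the inputs for
#' desk-scale cohort composition quantities: percent male and the
#' male:female count-ratio IRR.
#'
#' @param group `"all"` (default), `"adult"`, or `"pediatric"`.
#' @return Data.frame with columns `cancer_type`, `group`, `n_male`,
#'   `n_female`.
#' @export
#' @examples
#' counts <- cohort_counts("adult")
#' sum(counts$n_male) / sum(counts$n_female)  # pan-cancer M:F ratio
cohort_counts <- function(group = c("all", "adult", "pediatric")) {
  group <- match.arg(group)
  path <- system.file("extdata", "cohort_counts.tsv", package = "tindex",
                      mustWork = TRUE)
  counts <- utils::read.delim(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  if (group != "all") counts <- counts[counts$group == group, ]
  rownames(counts) <- NULL
  counts
}
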