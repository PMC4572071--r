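#' Published reference counts from a five-cohort HLOF exome survey
#'
#' Small plain-text tables of counts reported by a published survey of
#' homozygous loss-of-function variants across one cosmopolitan and four
#' isolate European cohorts, shipped with the package so its summary
#' statistics (gene-set enrichment ratios, per-population yields,
#' proportion summaries) can be recomputed from their published inputs.
#'
#' * `published_go_counts()` -- per GO term: background size `N`, term
#'   size `B`, target-set size `n`, overlap `b`, and the reported FDR `q`.
#' * `published_population_counts()` -- cohort sample sizes and HLOF
#'   variant counts.
#' * `published_summary_counts()` -- numerator/denominator pairs for
#'   proportion summaries (singleton HLOFs inside ROHs, testis expression,
#'   novel variants).
#'
#' @return A data.frame.
#' @name reference_counts
NULL

#' @rdname reference_counts
#' @export
published_go_counts <- function() {
  .read_refdata("published_go_counts.tsv")
}

#' @rdname reference_counts
#' @export
published_population_counts <- function() {
  .read_refdata("published_population_counts.tsv")
}

#' @rdname reference_counts
#' @export
published_summary_counts <- function() {
  .read_refdata("published_summary_counts.tsv")
}

.read_refdata <- function(name) {
  path <- system.file("extdata", name, package = "hlofscan", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
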