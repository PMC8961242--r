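#' Reference clinical scoring counts
#'
#' Lesion-count bookkeeping from a blinded prospective reading of cortical
#' lesions on artificial versus conventionally acquired DIR images of 15
#' MS patients (with a retrospective re-scoring iteration), shipped with
#' the package as reference inputs for the summary statistics: totals per
#' image type, the matched/unmatched contingency counts, and their
#' breakdown by lobe and lesion type.
#'
#' @return list with `counts` (named numeric vector of totals and
#'   increments) and `table` (data.frame of lobe/type contingency counts
#'   with columns `category`, `level`, `both`, `a_only`, `c_only`).
#' @examples
#' cs <- clinicalScoringCounts()
#' tp <- cs$counts["both_detected"]
#' tp / (tp + cs$counts["adir_only"])    # pooled precision
#' @export
clinicalScoringCounts <- function() {
  d <- system.file("extdata", package = "dirsynth")
  counts <- read.csv(file.path(d, "clinical_scoring_counts.csv"),
                     stringsAsFactors = FALSE)
  tab <- read.csv(file.path(d, "clinical_scoring_table.csv"),
                  stringsAsFactors = FALSE)
  list(counts = stats::setNames(counts$value, counts$metric), table = tab)
}
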