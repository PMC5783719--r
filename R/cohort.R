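# Cohort-level summaries and rank-based group comparisons.

#' Summarize one classified sample
#'
#' Breakpoints are counted one per junction (not per breakend).  Deletion
#' sizes are the spans of simple deletion-type junctions
#' (`posB - posA - 1` bp).  Class proportions are junction counts
#' normalized to 1 (empty for an empty report).
#'
#' @param report A [SampleReport-class] from [classifySample()].
#' @param sampleId Sample identifier.
#' @param genotype Genotype label (`"wild_type"`, `"rtel1_null"`, ...).
#' @return A list of class `SampleSummary` with fields `sampleId`,
#'   `genotype`, `breakpointCount`, `deletionSizes`, `classCounts`,
#'   `classProportions`.
#' @export
summarizeSample <- function(report, sampleId = "sample",
                            genotype = "other") {
  stopifnot(is(report, "SampleReport"))
  j <- report@junctions@junctions
  counts <- classCounts(report)
  del <- which(report@assignment == "deletion_type")
  sizes <- if (length(del)) j$posB[del] - j$posA[del] - 1 else numeric(0)
  props <- if (sum(counts) > 0) counts / sum(counts) else
    setNames(numeric(0), character(0))
  structure(list(sampleId = sampleId, genotype = genotype,
                 breakpointCount = nrow(j), deletionSizes = sizes,
                 classCounts = counts, classProportions = props),
            class = "SampleSummary")
}

#' @export
print.SampleSummary <- function(x, ...) {
  cat(sprintf("SampleSummary %s (%s): %d breakpoint(s)\n",
              x$sampleId, x$genotype, x$breakpointCount))
  invisible(x)
}

#' Compare two groups of sample summaries
#'
#' Two-sided Wilcoxon rank-sum test on per-sample breakpoint counts or on
#' pooled deletion sizes.  The exact null distribution is used for
#' combined sample sizes up to 20 (without ties); larger groups use the
#' normal approximation with tie correction.
#'
#' @param groupA,groupB Lists of `SampleSummary` objects (or plain numeric
#'   vectors of the metric).
#' @param metric `"breakpoint_count"` or `"deletion_size"`.
#' @return List with `statistic` (rank-sum `W`), `p.value`, `metric`,
#'   `nA`, `nB`.
#' @examples
#' compareGroups(list(1, 2, 3), list(10, 11, 12))
#' @export
compareGroups <- function(groupA, groupB,
                          metric = c("breakpoint_count", "deletion_size")) {
  metric <- match.arg(metric)
  pull <- function(g) {
    if (is.numeric(g)) return(g)
    if (!length(g)) return(numeric(0))
    if (is.numeric(g[[1L]]))
      return(vapply(g, function(x) x[[1L]], numeric(1)))
    if (metric == "breakpoint_count")
      vapply(g, function(s) s$breakpointCount, numeric(1))
    else
      unlist(lapply(g, function(s) s$deletionSizes))
  }
  a <- pull(groupA); b <- pull(groupB)
  if (!length(a) || !length(b))
    stop("both groups must be non-empty")
  exact <- (length(a) + length(b)) <= 20
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = !exact))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       metric = metric, nA = length(a), nB = length(b))
}
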