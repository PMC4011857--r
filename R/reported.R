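#' Published per-fissure integrity-level counts of a 573-exam COPD cohort
#'
#' Contingency-table counts (six integrity bins by five severity groups)
#' for the right oblique, right horizontal, left oblique and entire-lung
#' fissure integrity of a published 573-examination COPD screening cohort,
#' shipped as package data. Useful for checking the
#' \code{\link{distribution_percentages}} logic against an independent,
#' externally tabulated cohort and for comparing synthetic cohorts against
#' realistic marginal distributions.
#'
#' @return Named list of 6 x 5 count matrices (\code{rof}, \code{rhf},
#'   \code{lof}, \code{elf}); rows are the six integrity bins, columns the
#'   severity groups (non-COPD, GOLD I-IV).
#' @examples
#' cts <- reported_bin_counts()
#' distribution_percentages(cts$rof)$pct[, "all"]
#' @export
reported_bin_counts <- function() {
  path <- system.file("extdata", "reported_bin_counts.csv",
                      package = "fissint", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  out <- lapply(split(df, factor(df$fissure, unique(df$fissure))),
                function(x) {
    m <- as.matrix(x[, c("non_copd", "gold_i", "gold_ii", "gold_iii",
                         "gold_iv")])
    dimnames(m) <- list(x$bin, GOLD_LEVELS)
    m
  })
  out[c("rof", "rhf", "lof", "elf")]
}
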