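INTEGRITY_BINS <- c("[0%, 20%]", "(20%, 40%]", "(40%, 60%]", "(60%, 80%]",
                    "(80%, 90%]", "(90%, 100%]")

#' Fissure integrity from detected and complete areas
#'
#' Integrity is the proportion, in terms of area, of the complete
#' inter-lobar boundary on which the fissure is depicted:
#' \eqn{100 \cdot A_{detected} / A_{complete}}, clamped to [0, 100] (area
#' estimator noise can push the raw ratio slightly above 1).
#'
#' @param area_detected detected fissure area, mm^2 (>= 0).
#' @param area_complete complete boundary area, mm^2 (> 0).
#' @return Integrity percentage in [0, 100].
#' @examples
#' compute_integrity(2450, 4900)  # 50
#' @export
compute_integrity <- function(area_detected, area_complete) {
  if (any(area_complete <= 0)) stop("`area_complete` must be > 0")
  if (any(area_detected < 0)) stop("`area_detected` must be >= 0")
  pmin(pmax(100 * area_detected / area_complete, 0), 100)
}

#' Entire-lung fissure integrity
#'
#' Area-weighted aggregate over the three fissures:
#' \eqn{100 \cdot \sum A_{detected} / \sum A_{complete}}. With equal
#' complete areas this reduces to the plain mean of the per-fissure
#' integrities; in practice the right horizontal fissure carries roughly
#' half the weight of each oblique fissure.
#'
#' @param results data frame with columns \code{label},
#'   \code{area_detected_mm2}, \code{area_complete_mm2} (one row per
#'   fissure), as produced by \code{\link{fissure_integrity}}.
#' @param allow_missing permit fissures with unknown complete area
#'   (excluded from both sums); otherwise all of ROF, RHF, LOF must be
#'   present.
#' @return Entire-lung integrity percentage.
#' @export
entire_lung_integrity <- function(results, allow_missing = FALSE) {
  need <- c("ROF", "RHF", "LOF")
  ok <- !is.na(results$area_complete_mm2) & results$area_complete_mm2 > 0
  if (!allow_missing &&
      (!all(need %in% results$label[ok])))
    stop("missing fissure; set `allow_missing = TRUE` to aggregate anyway")
  if (!any(ok)) stop("no fissure with a valid complete boundary")
  compute_integrity(sum(results$area_detected_mm2[ok]),
                    sum(results$area_complete_mm2[ok]))
}

#' Bin an integrity percentage into the six reporting levels
#'
#' Levels are half-open to the left except the first:
#' [0\%, 20\%], (20\%, 40\%], (40\%, 60\%], (60\%, 80\%], (80\%, 90\%],
#' (90\%, 100\%]. A fissure in the last level is regarded as "complete".
#'
#' @param integrity_pct value(s) in [0, 100].
#' @return Ordered factor with the six bin labels.
#' @examples
#' bin_integrity(c(0, 20, 90, 90.01, 100))
#' @export
bin_integrity <- function(integrity_pct) {
  if (any(is.na(integrity_pct)) ||
      any(integrity_pct < 0 | integrity_pct > 100))
    stop("integrity values must lie in [0, 100]")
  cut(integrity_pct, breaks = c(0, 20, 40, 60, 80, 90, 100),
      labels = INTEGRITY_BINS, include.lowest = TRUE, right = TRUE,
      ordered_result = TRUE)
}

#' Is a fissure "complete"?
#'
#' Strictly greater than 90 percent, matching the (90\%, 100\%] bin.
#'
#' @param integrity_pct value(s) in [0, 100].
#' @return Logical vector.
#' @export
is_complete_fissure <- function(integrity_pct) integrity_pct > 90
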