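#' Simulate post-bronchodilator spirometry for an intended GOLD category
#'
#' FVC is drawn log-normally around 4 L; the FEV1/FVC ratio and FEV1
#' percent-predicted are drawn uniformly inside the spirometric band of
#' the intended category, so \code{\link{classify_gold}} recovers the
#' intended label by construction. FEV1 in litres follows from FVC and
#' the ratio.
#'
#' @param intended_gold character/factor vector of intended categories.
#' @param seed optional integer seed.
#' @return Data frame with \code{fev1_l}, \code{fvc_l},
#'   \code{fev1_fvc_pct}, \code{fev1_pct_pred}, \code{intended_gold}.
#' @export
simulate_spirometry <- function(intended_gold, seed = NULL) {
  g <- factor(intended_gold, levels = GOLD_LEVELS)
  if (any(is.na(g))) stop("unknown GOLD category")
  n <- length(g)
  draw <- function() {
    fvc <- stats::rlnorm(n, meanlog = log(4), sdlog = 0.15)
    ratio_lo <- c(71, 60, 50, 40, 30)[as.integer(g)]
    ratio_hi <- c(85, 69.5, 69.5, 60, 50)[as.integer(g)]
    ratio <- stats::runif(n, ratio_lo, ratio_hi)
    pp_lo <- c(82, 80, 50, 30, 15)[as.integer(g)]
    pp_hi <- c(115, 110, 79.9, 49.9, 29.9)[as.integer(g)]
    pct_pred <- stats::runif(n, pp_lo, pp_hi)
    data.frame(fev1_l = fvc * ratio / 100, fvc_l = fvc,
               fev1_fvc_pct = ratio, fev1_pct_pred = pct_pred,
               intended_gold = g)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Simulate a phantom cohort with paired spirometry
#'
#' Draws an intended GOLD category per subject from \code{gold_mix},
#' spirometry inside that category's band, and per-fissure integrity
#' targets from truncated normal distributions \emph{independently} of the
#' category — the null configuration in which fissure completeness carries
#' no information about disease severity. The default mix reflects a large
#' COPD screening cohort (38.7\% non-COPD, 14.5/24.6/11.0/11.2\% GOLD
#' I--IV); default integrity distributions centre the oblique fissures
#' near 82\% and the horizontal fissure near 62\% with wide subject-level
#' spread, truncated to [20, 100].
#'
#' @param n number of subjects.
#' @param gold_mix length-5 proportions over non-COPD..GOLD-IV; must sum
#'   to 1.
#' @param integrity_dist list with entries \code{ROF}, \code{RHF},
#'   \code{LOF}, each \code{c(mean, sd)} in percent.
#' @param seed integer seed.
#' @param spec_args extra arguments passed to \code{\link{phantom_spec}}
#'   for every subject (grid, noise, defects...).
#' @return List of length \code{n}; each element has \code{spec} (a
#'   \code{phantom_spec}) and \code{spirometry} (one-row data frame).
#' @export
simulate_cohort <- function(n,
                            gold_mix = c(0.387, 0.145, 0.246, 0.110, 0.112),
                            integrity_dist = list(ROF = c(82, 12),
                                                  RHF = c(62, 22),
                                                  LOF = c(82, 12)),
                            seed = 1L, spec_args = list()) {
  if (n < 1) stop("`n` must be >= 1")
  if (length(gold_mix) != 5L || any(gold_mix < 0) ||
      abs(sum(gold_mix) - 1) > 1e-8)
    stop("`gold_mix` must be 5 non-negative proportions summing to 1")
  with_seed(seed, {
    gold <- sample(GOLD_LEVELS, n, replace = TRUE, prob = gold_mix)
    spiro <- simulate_spirometry(gold)
    targets <- vapply(c("ROF", "RHF", "LOF"), function(lb) {
      p <- integrity_dist[[lb]]
      rnorm_trunc(n, p[1], p[2], lo = 20, hi = 100)
    }, numeric(n))
    if (n == 1L) targets <- matrix(targets, nrow = 1,
                                   dimnames = list(NULL, c("ROF", "RHF", "LOF")))
    seeds <- sample.int(.Machine$integer.max %/% 2L, n)
    lapply(seq_len(n), function(i) {
      sa <- c(list(target_integrity = targets[i, ], seed = seeds[i]),
              spec_args)
      list(spec = do.call(phantom_spec, sa),
           spirometry = spiro[i, , drop = FALSE])
    })
  })
}

# truncated normal by resampling (draws are cheap, bands are wide)
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  tries <- 0L
  while (length(bad) && tries < 100L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
    tries <- tries + 1L
  }
  pmin(pmax(x, lo), hi)
}
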