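GOLD_LEVELS <- c("non-COPD", "GOLD-I", "GOLD-II", "GOLD-III", "GOLD-IV")

#' GOLD severity staging from post-bronchodilator spirometry
#'
#' Subjects with FEV1/FVC >= 70\% are non-COPD; obstructed subjects are
#' graded by FEV1 percent predicted: GOLD-I >= 80, GOLD-II 50--79,
#' GOLD-III 30--49, GOLD-IV < 30. Staging is purely spirometric (the
#' chronic-respiratory-failure qualifier of stage IV needs fields a CT
#' cohort table does not carry).
#'
#' @param fev1_fvc_pct 100 x FEV1/FVC, percent; > 0.
#' @param fev1_pct_pred FEV1 percent of predicted; > 0.
#' @return Factor with levels non-COPD, GOLD-I..GOLD-IV.
#' @examples
#' classify_gold(75, 95)   # non-COPD
#' classify_gold(60, 55)   # GOLD-II
#' @export
classify_gold <- function(fev1_fvc_pct, fev1_pct_pred) {
  if (any(fev1_fvc_pct <= 0) || any(fev1_pct_pred <= 0))
    stop("spirometry values must be positive")
  out <- ifelse(fev1_fvc_pct >= 70, "non-COPD",
         ifelse(fev1_pct_pred >= 80, "GOLD-I",
         ifelse(fev1_pct_pred >= 50, "GOLD-II",
         ifelse(fev1_pct_pred >= 30, "GOLD-III", "GOLD-IV"))))
  factor(out, levels = GOLD_LEVELS)
}

#' Per-group mean and standard deviation of fissure integrity
#'
#' @param records data frame with a \code{gold} column and numeric
#'   integrity columns (by default \code{rof}, \code{rhf}, \code{lof},
#'   \code{elf}).
#' @param measures names of the integrity columns to summarise.
#' @return Data frame: one row per (measure, group) plus an all-groups row
#'   per measure, with n, mean and sample SD (NA for n < 2).
#' @export
group_summary <- function(records, measures = c("rof", "rhf", "lof", "elf")) {
  gold <- droplevels_keep(records$gold)
  out <- do.call(rbind, lapply(measures, function(m) {
    x <- records[[m]]
    per <- do.call(rbind, lapply(levels(gold), function(g) {
      xs <- x[gold == g]
      data.frame(measure = m, group = g, n = length(xs),
                 mean = if (length(xs)) mean(xs) else NA_real_,
                 sd = if (length(xs) > 1) stats::sd(xs) else NA_real_)
    }))
    rbind(per, data.frame(measure = m, group = "all", n = length(x),
                          mean = mean(x), sd = stats::sd(x)))
  }))
  rownames(out) <- NULL
  out
}

droplevels_keep <- function(g) {
  if (!is.factor(g)) g <- factor(g, levels = GOLD_LEVELS)
  g
}

#' Percentage logic of the integrity-level distribution tables
#'
#' Given a counts matrix (integrity bins x severity groups) computes the
#' per-group percentages (count over group n) and the all-groups column
#' (aggregate count over cohort n).
#'
#' @param counts integer matrix, rows = bins, columns = groups.
#' @return List with \code{counts} (input plus an \code{all} column),
#'   \code{pct} (same shape, percentages), \code{group_n} and \code{total}.
#' @export
distribution_percentages <- function(counts) {
  counts <- as.matrix(counts)
  group_n <- colSums(counts)
  all_counts <- rowSums(counts)
  total <- sum(counts)
  cts <- cbind(counts, all = all_counts)
  denom <- c(group_n, total)
  pct <- sweep(cts, 2, pmax(denom, 1), "/") * 100
  list(counts = cts, pct = pct, group_n = group_n, total = total)
}

#' Distribution of a fissure's integrity levels by severity group
#'
#' Tabulates subjects into the six integrity bins per GOLD group and
#' formats each cell as \code{"count/pct\%"}, with an all-groups column —
#' the layout of a per-fissure contingency table over a COPD cohort.
#'
#' @param records data frame with \code{gold} and the integrity column.
#' @param fissure_label integrity column name (e.g. \code{"rof"}).
#' @return List (class \code{distribution_table}) with \code{counts},
#'   \code{pct}, \code{formatted} (character matrix), \code{group_n},
#'   \code{total}.
#' @export
distribution_table <- function(records, fissure_label) {
  x <- records[[fissure_label]]
  if (is.null(x)) stop("unknown fissure column: ", fissure_label)
  gold <- droplevels_keep(records$gold)
  bins <- bin_integrity(x)
  counts <- table(bin = bins, group = gold)
  res <- distribution_percentages(unclass(counts))
  fmt <- matrix(sprintf("%d/%.1f%%", res$counts, res$pct),
                nrow = nrow(res$counts), dimnames = dimnames(res$counts))
  structure(c(res, list(formatted = fmt, fissure = fissure_label)),
            class = "distribution_table")
}

#' @export
print.distribution_table <- function(x, ...) {
  cat(sprintf("Integrity-level distribution (%s), count/percent per group:\n",
              toupper(x$fissure)))
  print(x$formatted, quote = FALSE)
  invisible(x)
}

#' Pearson correlation with t-test p-value
#'
#' Sample Pearson correlation; two-sided p-value from the t transform
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors, length >= 3, non-constant.
#' @return List with \code{r}, \code{p}, \code{n}.
#' @export
pearson_r <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("lengths differ")
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Spearman rank correlation with tied-rank handling
#'
#' Pearson correlation of mid-ranks (ties receive their average rank —
#' essential here, where severity takes five heavily tied levels), with
#' the p-value from the same t transform. Ordered factors are converted to
#' their level codes.
#'
#' @param x,y numeric vectors or ordered factors, length >= 3.
#' @return List with \code{rho}, \code{p}, \code{n}.
#' @export
spearman_rho <- function(x, y) {
  x <- as_rankable(x); y <- as_rankable(y)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  res <- pearson_r(rx, ry)
  list(rho = res$r, p = res$p, n = res$n)
}

as_rankable <- function(x) {
  if (is.factor(x)) as.integer(x) else as.numeric(x)
}

#' Correlation table of fissure integrity against lung function and
#' severity
#'
#' Pearson correlations of each integrity measure with FEV1 (litres) and
#' FEV1/FVC (percent); Spearman correlation with the five-level GOLD
#' severity.
#'
#' @param records data frame with \code{fev1_l}, \code{fev1_fvc_pct},
#'   \code{gold} and the integrity columns.
#' @param measures integrity column names.
#' @return Data frame with one row per (PFT measure, integrity measure).
#' @export
correlation_table <- function(records,
                              measures = c("rof", "rhf", "lof", "elf")) {
  rows <- list()
  for (m in measures) {
    x <- records[[m]]
    pr1 <- pearson_r(x, records$fev1_l)
    pr2 <- pearson_r(x, records$fev1_fvc_pct)
    sr <- spearman_rho(x, records$gold)
    rows[[length(rows) + 1L]] <-
      data.frame(measure = m,
                 pft = c("FEV1", "FEV1/FVC", "COPD severity"),
                 estimate = c(pr1$r, pr2$r, sr$rho),
                 p = c(pr1$p, pr2$p, sr$p))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort-level summary of fissure integrity
#'
#' Bundles the GOLD group sizes, per-group integrity means and SDs, the
#' per-fissure integrity-level distribution tables, and the correlation
#' table into one object.
#'
#' @param records data frame with columns \code{id}, \code{fev1_l},
#'   \code{fvc_l}, \code{fev1_fvc_pct}, \code{fev1_pct_pred}, \code{gold}
#'   (or the spirometry columns from which to stage), and integrity
#'   columns \code{rof}, \code{rhf}, \code{lof}, \code{elf}.
#' @return Object of class \code{fissure_cohort}.
#' @export
cohort_summary <- function(records) {
  if (is.null(records$gold))
    records$gold <- classify_gold(records$fev1_fvc_pct,
                                  records$fev1_pct_pred)
  records$gold <- droplevels_keep(records$gold)
  measures <- intersect(c("rof", "rhf", "lof", "elf"), names(records))
  structure(list(
    n = nrow(records),
    group_n = table(records$gold),
    summary = group_summary(records, measures),
    distributions = lapply(stats::setNames(measures, measures),
                           function(m) distribution_table(records, m)),
    correlations = correlation_table(records, measures),
    records = records), class = "fissure_cohort")
}

#' @export
print.fissure_cohort <- function(x, digits = 1, ...) {
  cat(sprintf("<fissure_cohort> n = %d\n", x$n))
  print(x$group_n)
  cat("\nMean integrity (%) by group:\n")
  s <- x$summary
  wide <- stats::reshape(
    s[, c("measure", "group", "mean")],
    idvar = "measure", timevar = "group", direction = "wide")
  names(wide) <- sub("^mean\\.", "", names(wide))
  print(cbind(measure = wide$measure,
              round(wide[, -1, drop = FALSE], digits)), row.names = FALSE)
  cat("\nCorrelations (estimate, p):\n")
  co <- x$correlations
  co$estimate <- signif(co$estimate, 3)
  co$p <- signif(co$p, 3)
  print(co, row.names = FALSE)
  invisible(x)
}

#' Stacked-bar plot of integrity-level distributions
#'
#' @param x a \code{fissure_cohort}.
#' @param measures fissures to include.
#' @param ... passed to \code{barplot}.
#' @return Invisibly, the percentage matrix plotted.
#' @export
plot.fissure_cohort <- function(x, measures = names(x$distributions), ...) {
  pct <- vapply(measures, function(m) {
    d <- x$distributions[[m]]
    d$pct[, "all"]
  }, numeric(6))
  colnames(pct) <- toupper(measures)
  cols <- grDevices::hcl.colors(6, "Blues3", rev = TRUE)
  graphics::barplot(pct, col = cols, ylab = "% of examinations",
                    xlab = "fissure", legend.text = rownames(pct),
                    args.legend = list(x = "topright", cex = 0.7,
                                       bg = "white"), ...)
  invisible(pct)
}
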