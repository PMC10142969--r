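#' Area under the ROC curve (rank statistic)
#'
#' Computes the AUROC as the Mann-Whitney concordance statistic: the
#' fraction of positive/negative pairs in which the positive scores higher,
#' with ties given half credit.
#'
#' @param scores numeric score vector (higher = more likely positive).
#' @param labels binary labels (1 = positive).
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop_config("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

boot_stratified <- function(scores, labels, n_boot, seed, stat) {
  set.seed(seed)
  pos <- which(labels == 1); neg <- which(labels == 0)
  vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    stat(scores[idx], labels[idx])
  }, numeric(1))
}

#' AUROC with a bootstrap 95% confidence interval
#'
#' Point estimate by [auroc()]; interval by class-stratified percentile
#' bootstrap (2.5th/97.5th percentiles over `n_boot` replicates).
#'
#' @inheritParams auroc
#' @param n_boot bootstrap replicates (>= 100; default 2000).
#' @param seed integer seed for resampling.
#' @return list with `auroc`, `ci` (length-2 vector), `n_boot`.
#' @export
auroc_with_ci <- function(scores, labels, n_boot = 2000L, seed = 1L) {
  check_count(n_boot, "n_boot", min = 100L)
  point <- auroc(scores, labels)
  reps <- boot_stratified(scores, as.numeric(labels), n_boot, seed, auroc)
  ci <- stats::quantile(reps, c(0.025, 0.975), names = FALSE, type = 7)
  list(auroc = point, ci = ci, n_boot = n_boot)
}

sens_spec_at <- function(scores, labels, threshold) {
  c(sensitivity = mean(scores[labels == 1] >= threshold),
    specificity = mean(scores[labels == 0] < threshold))
}

#' Sensitivity/specificity at a fixed operating point
#'
#' Chooses the least stringent cutoff achieving the requested target on the
#' given data -- for a sensitivity target, the largest threshold with
#' sensitivity at or above the target (maximising specificity); for a
#' specificity target, the smallest threshold with specificity at or above
#' it (maximising sensitivity). Alternatively a pre-chosen `threshold`
#' (e.g. fixed on validation data) can be supplied and is applied as-is.
#' Both metrics at the chosen threshold are reported with class-stratified
#' bootstrap 95% CIs.
#'
#' @inheritParams auroc
#' @param target_sensitivity,target_specificity exactly one may be set
#'   (e.g. 0.90) unless `threshold` is given.
#' @param threshold optional fixed cutoff overriding target search.
#' @param n_boot,seed bootstrap settings.
#' @return list with `threshold`, `sensitivity`, `specificity`,
#'   `sensitivity_ci`, `specificity_ci`.
#' @export
operating_point_metrics <- function(scores, labels,
                                    target_sensitivity = NULL,
                                    target_specificity = NULL,
                                    threshold = NULL,
                                    n_boot = 2000L, seed = 1L) {
  labels <- as.numeric(labels)
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0)
    stop_config("both classes must be present")
  if (is.null(threshold)) {
    if (is.null(target_sensitivity) == is.null(target_specificity))
      stop_config("set exactly one of target_sensitivity/target_specificity, or a threshold")
    cand <- sort(unique(scores))
    if (!is.null(target_sensitivity)) {
      ok <- vapply(cand, function(t) mean(scores[labels == 1] >= t),
                   numeric(1)) >= target_sensitivity
      if (!any(ok)) {
        warning("sensitivity target unattainable; using boundary threshold",
                call. = FALSE)
        threshold <- min(cand)
      } else threshold <- max(cand[ok])
    } else {
      cand <- c(cand, max(cand) + 1)
      ok <- vapply(cand, function(t) mean(scores[labels == 0] < t),
                   numeric(1)) >= target_specificity
      if (!any(ok)) {
        warning("specificity target unattainable; using boundary threshold",
                call. = FALSE)
        threshold <- max(cand)
      } else threshold <- min(cand[ok])
    }
  }
  point <- sens_spec_at(scores, labels, threshold)
  reps <- boot_stratified(scores, labels, n_boot, seed,
                          function(s, l) sens_spec_at(s, l, threshold)[1])
  reps2 <- boot_stratified(scores, labels, n_boot, seed + 1L,
                           function(s, l) sens_spec_at(s, l, threshold)[2])
  list(threshold = threshold,
       sensitivity = unname(point[1]), specificity = unname(point[2]),
       sensitivity_ci = stats::quantile(reps, c(0.025, 0.975), names = FALSE),
       specificity_ci = stats::quantile(reps2, c(0.025, 0.975), names = FALSE))
}

#' Univariate associations of baseline features with outcome
#'
#' Tests each feature against the binary outcome: Fisher's exact test
#' (two-sided) for binary features, Mann-Whitney U (two-sided
#' `wilcox.test`) for continuous ones, with Benjamini-Hochberg FDR
#' correction across the tested family. Group summaries are reported as
#' median [IQR] for continuous features and per-group proportions of the
#' reference level for binary ones. Constant features are skipped with a
#' note and excluded from the FDR family.
#'
#' @param data data frame holding the features and the outcome column.
#' @param features character vector of feature column names.
#' @param outcome name of the binary outcome column (default `"outcome"`).
#' @return data frame of class `association_table`: `feature`, `test`,
#'   `n`, `summary_dry`, `summary_fluid`, `p`, `p_adj`, `note`.
#' @export
univariate_associations <- function(data, features, outcome = "outcome") {
  y <- data[[outcome]]
  if (is.null(y)) stop_config("outcome column '", outcome, "' not found")
  rows <- lapply(features, function(f) {
    x <- data[[f]]
    ok <- !is.na(x) & !is.na(y)
    xv <- x[ok]; yv <- y[ok]
    lev <- sort(unique(xv))
    if (length(lev) < 2)
      return(data.frame(feature = f, test = NA_character_, n = sum(ok),
                        summary_dry = NA_character_,
                        summary_fluid = NA_character_,
                        p = NA_real_, note = "constant feature: skipped",
                        stringsAsFactors = FALSE))
    if (length(lev) == 2) {
      p <- stats::fisher.test(table(factor(xv), factor(yv)))$p.value
      ref <- lev[length(lev)]
      smry <- vapply(c(0, 1), function(g)
        sprintf("%.0f%% %s", 100 * mean(xv[yv == g] == ref), ref),
        character(1))
      test <- "fisher_exact"
    } else {
      p <- stats::wilcox.test(xv[yv == 0], xv[yv == 1], exact = FALSE)$p.value
      smry <- vapply(c(0, 1), function(g) {
        q <- stats::quantile(xv[yv == g], c(0.5, 0.25, 0.75), names = FALSE)
        sprintf("%.3g [%.3g, %.3g]", q[1], q[2], q[3])
      }, character(1))
      test <- "mann_whitney_u"
    }
    data.frame(feature = f, test = test, n = sum(ok),
               summary_dry = smry[1], summary_fluid = smry[2], p = p,
               note = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tested <- !is.na(out$p)
  out$p_adj <- NA_real_
  out$p_adj[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  out <- out[, c("feature", "test", "n", "summary_dry", "summary_fluid",
                 "p", "p_adj", "note")]
  class(out) <- c("association_table", "data.frame")
  out
}

#' Odds ratio and chi-square statistic for a 2x2 table
#'
#' For the table with cells `a`, `b` (first row) and `c`, `d` (second row):
#' OR = (a*d)/(b*c) and the Pearson chi-square statistic without continuity
#' correction. A zero cell triggers the Haldane-Anscombe correction (0.5
#' added to every cell for the OR) and is flagged.
#'
#' @param a,b,c,d non-negative cell counts.
#' @return list with `odds_ratio`, `chi_square`, `p_value`, `corrected`.
#' @examples
#' # complete dryness by protocol: dry/fluid counts for short vs standard
#' odds_ratio_2x2(344, 206, 476, 694)
#' @export
odds_ratio_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop_config("cell counts must be non-negative integers")
  tab <- matrix(cells, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_config("zero marginal total")
  corrected <- any(cells == 0)
  or_cells <- if (corrected) cells + 0.5 else cells
  or <- (or_cells[1] * or_cells[4]) / (or_cells[2] * or_cells[3])
  n <- sum(cells)
  chi2 <- n * (a * d - b * c)^2 /
    (prod(rowSums(tab)) * prod(colSums(tab)))
  list(odds_ratio = or, chi_square = chi2,
       p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       corrected = corrected)
}
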