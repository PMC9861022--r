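# ROC curves, AUC with DeLong confidence intervals, and Youden-optimal
# cut-points. Predicted-positive means score >= threshold; all scales are
# treated as risk-increasing.

.check_roc_input <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("`scores` and `labels` must have equal length")
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- as.logical(labels[keep])
  if (!any(labels) || all(labels))
    stop("degenerate outcome: labels must contain both classes")
  list(scores = scores, labels = labels)
}

#' ROC curve points
#'
#' Sweeps thresholds from +Inf downward over the distinct score values, with
#' predicted-positive defined as score >= threshold. Tied scores are grouped
#' at a single point, so the curve has one point per distinct score plus the
#' (0,0) origin, and ends at (1,1).
#'
#' @param scores Numeric risk scores (higher = more likely positive).
#' @param labels Logical (or 0/1) outcome labels.
#' @return A data.frame with columns `fpr`, `tpr`, `threshold`, ordered from
#'   (0,0) at threshold `Inf` to (1,1) at the minimum score.
#' @examples
#' roc_points(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' @export
roc_points <- function(scores, labels) {
  inp <- .check_roc_input(scores, labels)
  scores <- inp$scores; labels <- inp$labels
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  # group tied scores
  grp_last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[grp_last]
  fp <- cumsum(!y)[grp_last]
  data.frame(
    fpr = c(0, fp / sum(!labels)),
    tpr = c(0, tp / sum(labels)),
    threshold = c(Inf, s[grp_last])
  )
}

# Mann-Whitney concordance via midranks: (concordant + 0.5 * tied) pairs
# divided by (positives x negatives). O(n log n).
.auc_mann_whitney <- function(scores, labels) {
  m <- sum(labels)
  n <- sum(!labels)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - m * (m + 1) / 2) / (m * n)
}

# Trapezoidal area under the ROC polygon.
.auc_trapezoid <- function(pts) {
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}

# DeLong variance of the AUC via placement values computed from midranks.
.delong_var <- function(scores, labels, auc_hat) {
  x <- scores[labels]   # cases
  y <- scores[!labels]  # controls
  m <- length(x); n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rx) / n          # placement of each case
  v01 <- 1 - (r_all[m + seq_len(n)] - ry) / m  # placement of each control
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  s10 / m + s01 / n
}

#' AUC with 95% confidence interval
#'
#' Computes the area under the ROC curve as the Mann-Whitney concordance
#' probability (concordant pairs plus half the tied pairs over all
#' case-control pairs), which equals the trapezoidal area under
#' [roc_points()]. The 95% confidence interval uses the DeLong variance
#' estimator by default (Hanley-McNeil available), clipped to [0, 1].
#'
#' @inheritParams roc_points
#' @param ci_method `"delong"` (default) or `"hanley"`.
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `auc`, `ci` (length-2 vector), `se`, `n_pos`, `n_neg`.
#' @examples
#' auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc # 1
#' @export
auc <- function(scores, labels, ci_method = c("delong", "hanley"),
                conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  inp <- .check_roc_input(scores, labels)
  scores <- inp$scores; labels <- inp$labels
  a <- .auc_mann_whitney(scores, labels)
  m <- sum(labels); n <- sum(!labels)
  v <- if (ci_method == "delong") {
    .delong_var(scores, labels, a)
  } else {
    # Hanley & McNeil (1982) binormal-free approximation
    q1 <- a / (2 - a)
    q2 <- 2 * a^2 / (1 + a)
    (a * (1 - a) + (m - 1) * (q1 - a^2) + (n - 1) * (q2 - a^2)) / (m * n)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(max(v, 0))
  ci <- pmin(pmax(a + c(-1, 1) * z * se, 0), 1)
  list(auc = a, ci = ci, se = se, n_pos = m, n_neg = n)
}

#' Youden-optimal cut-point
#'
#' Maximises the Youden index J(t) = sensitivity(t) + specificity(t) - 1 over
#' all candidate thresholds: the midpoints between adjacent distinct sorted
#' scores plus the two extremes (-Inf, everything positive; +Inf, everything
#' negative). Predicted-positive means score >= threshold. Ties in J are
#' broken toward the lowest cut-off, which maximises sensitivity.
#'
#' @inheritParams roc_points
#' @return A list with `cutoff`, `sensitivity`, `specificity`, `youden`.
#' @examples
#' best_cutoff_youden(c(10, 11, 1, 2), c(1, 1, 0, 0)) # J = 1
#' @export
best_cutoff_youden <- function(scores, labels) {
  inp <- .check_roc_input(scores, labels)
  scores <- inp$scores; labels <- inp$labels
  m <- sum(labels); n <- sum(!labels)
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  # counts of cases/controls >= each candidate, via cumulative tail sums
  pos_at <- vapply(split(labels, factor(scores, levels = u)), sum, numeric(1))
  neg_at <- vapply(split(!labels, factor(scores, levels = u)), sum, numeric(1))
  # for candidate c(-Inf) all n+m positive; for midpoint after u[k], scores
  # >= candidate are those > u[k]
  tail_pos <- rev(cumsum(rev(pos_at)))
  tail_neg <- rev(cumsum(rev(neg_at)))
  sens <- c(1, if (length(u) > 1) tail_pos[-1] / m, 0)
  spec <- c(0, if (length(u) > 1) (n - tail_neg[-1]) / n, 1)
  j <- sens + spec - 1
  best <- which(j == max(j))[1]  # lowest cutoff among ties
  list(cutoff = unname(cand[best]), sensitivity = unname(sens[best]),
       specificity = unname(spec[best]), youden = unname(j[best]))
}

#' ROC battery over scales, criteria and sexes
#'
#' Runs the full discrimination analysis: for each of the six
#' insulin-resistance scales, each metabolic-syndrome criterion and each sex
#' stratum, computes the AUC with confidence interval and the Youden-optimal
#' cut-point with its sensitivity and specificity. Strata with a single-class
#' outcome are flagged not-computable; the remaining entries are still
#' produced.
#'
#' @param cohort Cohort with index panel ([derive_panel()]) and
#'   classification ([classify_mets()]) columns.
#' @param scales Scale column names (default the six indices).
#' @param criteria Criterion column suffixes (default `atpiii`, `idf`, `jis`).
#' @param ci_method Passed to [auc()].
#' @return A data.frame with one row per scale x criterion x sex: `scale,
#'   criterion, sex, n_pos, n_neg, auc, auc_lo, auc_hi, cutoff, sensitivity,
#'   specificity, youden, computable`.
#' @export
run_roc_battery <- function(cohort, scales = .scale_cols,
                            criteria = c("atpiii", "idf", "jis"),
                            ci_method = "delong") {
  rows <- list()
  for (sx in c("F", "M")) {
    sub <- cohort[cohort$sex == sx, , drop = FALSE]
    for (cr in criteria) {
      outcome <- sub[[paste0("ms_", cr)]]
      for (sc in scales) {
        scores <- sub[[sc]]
        keep <- !is.na(scores) & !is.na(outcome)
        row <- data.frame(scale = sc, criterion = cr, sex = sx,
                          n_pos = sum(outcome[keep]),
                          n_neg = sum(!outcome[keep]),
                          auc = NA_real_, auc_lo = NA_real_, auc_hi = NA_real_,
                          cutoff = NA_real_, sensitivity = NA_real_,
                          specificity = NA_real_, youden = NA_real_,
                          computable = FALSE, stringsAsFactors = FALSE)
        if (row$n_pos >= 1 && row$n_neg >= 1) {
          a <- auc(scores[keep], outcome[keep], ci_method = ci_method)
          y <- best_cutoff_youden(scores[keep], outcome[keep])
          row$auc <- a$auc; row$auc_lo <- a$ci[1]; row$auc_hi <- a$ci[2]
          row$cutoff <- y$cutoff; row$sensitivity <- y$sensitivity
          row$specificity <- y$specificity; row$youden <- y$youden
          row$computable <- TRUE
        }
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  do.call(rbind, rows)
}
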