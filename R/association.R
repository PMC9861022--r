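# Association statistics: binary logistic regression (IRLS) with Wald odds
# ratios, the 2x2 closed form, the scale/criterion OR tables, and the
# descriptive summary with t and chi-square tests.

#' Binary logistic regression via IRLS
#'
#' Fits a logistic model by iteratively reweighted least squares with
#' step-halving (the log-likelihood is non-decreasing across accepted
#' iterations). Convergence is declared when the maximum absolute coefficient
#' change drops below `tol`; estimation stops with an error on complete or
#' quasi-complete separation (diverging coefficients) or a rank-deficient
#' design.
#'
#' @param outcome Logical (or 0/1) response vector with both classes present.
#' @param design Numeric predictor matrix (without intercept unless
#'   `intercept = FALSE`); column names become term names.
#' @param intercept Prepend an intercept column (default `TRUE`).
#' @param tol Convergence tolerance on the max coefficient change
#'   (default 1e-8).
#' @param max_iter Iteration cap (default 100).
#' @param conf_level Confidence level for the Wald intervals (default 0.95).
#' @return An object of class `logistic_fit`: list with `terms`,
#'   `coefficients` (log-odds), `se`, `or`, `or_ci` (matrix), `p_value`
#'   (Wald), `converged`, `iterations`, `loglik` (per-iteration trace).
#' @examples
#' x <- rep(c(1, 1, 0, 0), c(30, 70, 10, 90))
#' y <- rep(c(1, 0, 1, 0), c(30, 70, 10, 90))
#' fit_logistic(y, cbind(exposed = x))$or # intercept, then OR = 3.857
#' @export
fit_logistic <- function(outcome, design, intercept = TRUE, tol = 1e-8,
                         max_iter = 100, conf_level = 0.95) {
  y <- as.numeric(outcome)
  if (any(is.na(y)) || !all(y %in% c(0, 1)))
    stop("`outcome` must be a binary vector without missing values")
  if (all(y == 0) || all(y == 1))
    stop("degenerate outcome: both classes required")
  X <- as.matrix(design)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (intercept)
    X <- cbind(`(Intercept)` = 1, X)
  if (nrow(X) != length(y))
    stop("`design` and `outcome` lengths differ")
  if (qr(X)$rank < ncol(X))
    stop("design error: predictor matrix is rank deficient")

  loglik <- function(eta) sum(y * eta - log1p(exp(eta)))
  beta <- rep(0, ncol(X))
  eta <- drop(X %*% beta)
  ll <- loglik(eta)
  ll_trace <- ll
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    w <- pmax(w, .Machine$double.eps)
    z <- eta + (y - mu) / w
    fit <- tryCatch(
      solve(crossprod(X, X * w), crossprod(X, w * z)),
      error = function(e) stop("separation error: information matrix singular",
                               call. = FALSE))
    beta_new <- drop(fit)
    # step-halve until the log-likelihood does not decrease
    step <- 1
    repeat {
      cand <- beta + step * (beta_new - beta)
      eta_cand <- drop(X %*% cand)
      ll_cand <- loglik(eta_cand)
      if (ll_cand >= ll - 1e-12 || step < 1e-4) break
      step <- step / 2
    }
    delta <- max(abs(cand - beta))
    beta <- cand; eta <- eta_cand; ll <- ll_cand
    ll_trace <- c(ll_trace, ll)
    if (max(abs(beta)) > 15)
      stop("separation error: coefficients diverging (complete or quasi-complete separation)",
           call. = FALSE)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  info <- crossprod(X, X * w)
  vcov <- solve(info)
  se <- sqrt(diag(vcov))
  z_crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  or_ci <- cbind(lo = exp(beta - z_crit * se), hi = exp(beta + z_crit * se))
  rownames(or_ci) <- colnames(X)
  fit <- list(
    terms = colnames(X),
    coefficients = stats::setNames(beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    or = stats::setNames(exp(beta), colnames(X)),
    or_ci = or_ci,
    p_value = stats::setNames(2 * stats::pnorm(-abs(beta / se)), colnames(X)),
    converged = converged,
    iterations = iter,
    loglik = ll_trace
  )
  class(fit) <- "logistic_fit"
  fit
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Binary logistic regression (IRLS,", x$iterations, "iterations)\n")
  tab <- data.frame(coef = x$coefficients, se = x$se, OR = x$or,
                    lo95 = x$or_ci[, "lo"], hi95 = x$or_ci[, "hi"],
                    p = x$p_value)
  print(round(tab, 4))
  invisible(x)
}

#' Odds ratio from a 2x2 table
#'
#' Closed-form odds ratio `ad/bc` with the Woolf log-scale Wald interval
#' `exp(ln OR +- z * sqrt(1/a + 1/b + 1/c + 1/d))`. No continuity correction:
#' a zero cell is an error.
#'
#' @param a,b,c,d Cell counts: exposed-case, exposed-noncase, unexposed-case,
#'   unexposed-noncase.
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `or`, `ci`, `se_log` (SE of the log odds ratio).
#' @examples
#' or_from_2x2(30, 70, 10, 90)$or # 3.857
#' @export
or_from_2x2 <- function(a, b, c, d, conf_level = 0.95) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers")
  if (any(counts == 0))
    stop("zero-cell error: all four cells must be positive")
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = or, ci = exp(log(or) + c(-1, 1) * z * se), se_log = se)
}

# Fit one crude (or adjusted) OR of `outcome ~ predictor (+ adjust)` on a
# cohort; returns a one-row data.frame or the error condition.
.one_or <- function(cohort, outcome_col, predictor_col, adjust = NULL) {
  keep <- stats::complete.cases(cohort[, c(outcome_col, predictor_col, adjust),
                                       drop = FALSE])
  dat <- cohort[keep, , drop = FALSE]
  X <- cbind(as.numeric(dat[[predictor_col]]))
  colnames(X) <- predictor_col
  if (!is.null(adjust)) {
    for (a in adjust) {
      v <- dat[[a]]
      if (a == "sex") v <- as.numeric(v == "M")
      X <- cbind(X, as.numeric(v))
      colnames(X)[ncol(X)] <- a
    }
  }
  res <- tryCatch(fit_logistic(dat[[outcome_col]], X), error = identity)
  if (inherits(res, "error")) {
    data.frame(outcome = outcome_col, predictor = predictor_col,
               or = NA_real_, or_lo = NA_real_, or_hi = NA_real_,
               p_value = NA_real_, n = nrow(dat),
               error = conditionMessage(res), stringsAsFactors = FALSE)
  } else {
    data.frame(outcome = outcome_col, predictor = predictor_col,
               or = unname(res$or[predictor_col]),
               or_lo = unname(res$or_ci[predictor_col, "lo"]),
               or_hi = unname(res$or_ci[predictor_col, "hi"]),
               p_value = unname(res$p_value[predictor_col]), n = nrow(dat),
               error = NA_character_, stringsAsFactors = FALSE)
  }
}

#' Odds ratios of metabolic syndrome by high-risk index status
#'
#' For each flagged insulin-resistance scale (TG/HDL, TyG, METS-IR) and each
#' metabolic-syndrome criterion, the odds ratio of syndrome-positive status
#' for high versus normal scale values, from a single-predictor logistic
#' model (crude by default; optionally adjusted).
#'
#' @param cohort Cohort with index flags and `ms_*` status columns.
#' @param adjust Optional character vector of adjustment covariates, e.g.
#'   `c("age", "sex")`.
#' @return A data.frame with one row per scale x criterion: `outcome,
#'   predictor, or, or_lo, or_hi, p_value, n, error` (error message for
#'   non-estimable cells, `NA` otherwise).
#' @export
scale_to_mets_or <- function(cohort, adjust = NULL) {
  rows <- list()
  for (flag in c("high_tg_hdl", "high_tyg", "high_mets_ir"))
    for (cr in c("ms_atpiii", "ms_idf", "ms_jis"))
      rows[[length(rows) + 1]] <- .one_or(cohort, cr, flag, adjust)
  do.call(rbind, rows)
}

#' Odds ratios of high index status by metabolic-syndrome component
#'
#' For each of the five metabolic-syndrome components (evaluated under the
#' ATPIII/JIS waist thresholds and, separately, the IDF waist thresholds),
#' the odds ratio of a high insulin-resistance flag (TyG, TG/HDL, METS-IR)
#' for component-positive versus component-negative subjects. Only the waist
#' cut-offs differ between the two threshold sets.
#'
#' @param cohort Cohort with index flags (see [derive_panel()]).
#' @param criteria Criteria configuration from [mets_criteria()].
#' @param adjust Optional adjustment covariates.
#' @return A data.frame with one row per threshold set x component x scale
#'   flag: `threshold_set, component, outcome, predictor, or, or_lo, or_hi,
#'   p_value, n, error`.
#' @export
component_to_scale_or <- function(cohort, criteria = mets_criteria(),
                                  adjust = NULL) {
  sets <- list(atpiii_jis = criteria$atpiii, idf = criteria$idf)
  comp_names <- c("waist_high", "hdl_low", "bp_high", "tg_high", "glucose_high")
  rows <- list()
  for (set_nm in names(sets)) {
    flags <- component_flags(cohort, sets[[set_nm]])
    tmp <- cohort
    for (f in comp_names) tmp[[f]] <- flags[[f]]
    for (f in comp_names)
      for (scale_flag in c("high_tyg", "high_tg_hdl", "high_mets_ir")) {
        r <- .one_or(tmp, scale_flag, f, adjust)
        r <- cbind(data.frame(threshold_set = set_nm, component = f,
                              stringsAsFactors = FALSE), r)
        names(r)[names(r) == "outcome"] <- "outcome"
        rows[[length(rows) + 1]] <- r
      }
  }
  do.call(rbind, rows)
}

#' Descriptive summary with sex comparison
#'
#' Per-sex and overall mean (SD) for the continuous variables with pooled
#' two-sample Student t-test p-values, and per-sex percentages for the
#' categorical variables (age bands, social class, smoking) with Pearson
#' chi-square p-values (no continuity correction).
#'
#' @param cohort Cohort data.frame.
#' @return A list with `continuous` (variable, female/male/total mean and sd,
#'   t statistic, p) and `categorical` (variable, level, female/male/total
#'   percentage, chi-square statistic, p) data.frames.
#' @export
descriptives <- function(cohort) {
  if (sum(cohort$sex == "F") < 2 || sum(cohort$sex == "M") < 2)
    stop("descriptives error: need at least 2 subjects per sex")
  cont_cols <- c("age", unname(.var_to_col), "ldl_mgdl")
  cont_cols <- intersect(cont_cols, names(cohort))
  f <- cohort$sex == "F"

  cont <- do.call(rbind, lapply(cont_cols, function(v) {
    x <- cohort[[v]][f]; y <- cohort[[v]][!f]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (stats::sd(c(x, y)) == 0) {
      # degenerate constant variable: no mean difference by construction
      tt <- list(statistic = c(t = 0), p.value = 1)
    } else {
      tt <- stats::t.test(x, y, var.equal = TRUE)
    }
    data.frame(variable = v,
               female_mean = mean(x), female_sd = stats::sd(x),
               male_mean = mean(y), male_sd = stats::sd(y),
               total_mean = mean(c(x, y)), total_sd = stats::sd(c(x, y)),
               t_stat = unname(tt$statistic), p_value = tt$p.value,
               stringsAsFactors = FALSE)
  }))

  cat_vars <- list(
    age_band = cut(cohort$age, c(17, 29, 39, 49, 59, Inf),
                   labels = c("18-29", "30-39", "40-49", "50-59", "60+")),
    social_class = factor(cohort$social_class, levels = c("I", "II", "III")),
    smoker = factor(cohort$smoker, levels = c(0, 1),
                    labels = c("nonsmoker", "smoker"))
  )
  cats <- do.call(rbind, lapply(names(cat_vars), function(v) {
    g <- cat_vars[[v]]
    tab <- table(g, cohort$sex)
    chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(variable = v, level = rownames(tab),
               female_pct = 100 * tab[, "F"] / sum(tab[, "F"]),
               male_pct = 100 * tab[, "M"] / sum(tab[, "M"]),
               total_pct = 100 * rowSums(tab) / sum(tab),
               chisq_stat = unname(chi$statistic), p_value = chi$p.value,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  list(continuous = cont, categorical = cats)
}
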