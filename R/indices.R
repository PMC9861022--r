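# Surrogate insulin-resistance indices: TG/HDL ratio, TyG and its
# anthropometric variants, METS-IR, plus BMI/WtHR and Friedewald LDL.

.check_positive <- function(..., .names) {
  args <- list(...)
  for (i in seq_along(args)) {
    x <- args[[i]]
    if (any(!is.na(x) & x <= 0))
      stop(sprintf("`%s` must be strictly positive", .names[i]))
  }
  invisible(NULL)
}

#' High-risk thresholds for the flagged indices
#'
#' Returns the operating thresholds above which an index value is flagged as
#' high insulin-resistance risk, together with whether the boundary itself
#' counts ("over 2.4" reads as strict for TG/HDL; "from 8.8" and "from 50"
#' read as inclusive for TyG and METS-IR).
#'
#' @param tg_hdl TG/HDL ratio threshold (default 2.4, strict `>`).
#' @param tyg TyG index threshold (default 8.8, inclusive `>=`).
#' @param mets_ir METS-IR threshold (default 50, inclusive `>=`).
#' @return A list with one element per flagged index holding `cut` and
#'   `inclusive`.
#' @export
index_thresholds <- function(tg_hdl = 2.4, tyg = 8.8, mets_ir = 50) {
  list(
    tg_hdl = list(cut = tg_hdl, inclusive = FALSE),
    tyg = list(cut = tyg, inclusive = TRUE),
    mets_ir = list(cut = mets_ir, inclusive = TRUE)
  )
}

.flag_high <- function(x, thr) {
  if (thr$inclusive) x >= thr$cut else x > thr$cut
}

#' Friedewald LDL cholesterol
#'
#' Estimates LDL-c as total cholesterol - HDL-c - triglycerides/5 (all in
#' mg/dL). The estimate is only valid below 400 mg/dL of triglycerides;
#' above that the result is missing.
#'
#' @param total_chol Total cholesterol, mg/dL.
#' @param hdl HDL cholesterol, mg/dL.
#' @param tg Fasting triglycerides, mg/dL.
#' @return LDL-c in mg/dL, `NA` where `tg >= 400`. Vectorised.
#' @examples
#' friedewald_ldl(200, 50, 100) # 130
#' @export
friedewald_ldl <- function(total_chol, hdl, tg) {
  .check_positive(total_chol, hdl, tg, .names = c("total_chol", "hdl", "tg"))
  ifelse(tg < 400, total_chol - hdl - tg / 5, NA_real_)
}

#' TyG index
#'
#' The triglyceride-glucose index, `ln(tg * glucose / 2)` with both inputs in
#' mg/dL; a fasting surrogate for insulin resistance.
#'
#' @param tg Fasting triglycerides, mg/dL.
#' @param glucose Fasting glucose, mg/dL.
#' @return The TyG index (natural-log scale). Vectorised.
#' @examples
#' tyg(150, 100) # ln(7500) = 8.92
#' @export
tyg <- function(tg, glucose) {
  .check_positive(tg, glucose, .names = c("tg", "glucose"))
  log(tg * glucose / 2)
}

#' Triglyceride/HDL ratio
#'
#' @param tg Fasting triglycerides, mg/dL.
#' @param hdl HDL cholesterol, mg/dL.
#' @return `tg / hdl`. Vectorised.
#' @export
tg_hdl_ratio <- function(tg, hdl) {
  .check_positive(tg, hdl, .names = c("tg", "hdl"))
  tg / hdl
}

#' METS-IR score
#'
#' The metabolic score for insulin resistance,
#' `ln(2 * glucose + tg) * bmi / ln(hdl)`. HDL must exceed 1 mg/dL so the
#' log denominator is positive.
#'
#' @param glucose Fasting glucose, mg/dL.
#' @param tg Fasting triglycerides, mg/dL.
#' @param bmi Body-mass index, kg/m^2.
#' @param hdl HDL cholesterol, mg/dL.
#' @return The METS-IR score (dimensionless). Vectorised.
#' @examples
#' mets_ir(90, 150, 30, 50) # 44.47
#' @export
mets_ir <- function(glucose, tg, bmi, hdl) {
  .check_positive(glucose, tg, bmi, hdl,
                  .names = c("glucose", "tg", "bmi", "hdl"))
  if (any(!is.na(hdl) & hdl <= 1))
    stop("`hdl` must exceed 1 mg/dL (log denominator must be positive)")
  log(2 * glucose + tg) * bmi / log(hdl)
}

#' Derive the insulin-resistance index panel for a cohort
#'
#' Appends BMI (weight/height^2, computed here and never read from input),
#' waist-to-height ratio (both lengths in cm), the six insulin-resistance
#' indices and the three high-risk flags to a cohort table. Rows with a
#' missing required field get missing index values (complete-case handling
#' downstream).
#'
#' @param cohort Cohort data.frame with the standard measurement columns.
#' @param thresholds Flag thresholds, see [index_thresholds()].
#' @return The cohort with columns `bmi, wthr, tg_hdl, tyg, tyg_bmi,
#'   tyg_waist, tyg_wthr, mets_ir, high_tg_hdl, high_tyg, high_mets_ir`
#'   appended.
#' @examples
#' cohort <- generate_cohort(default_spec(), n = 20, seed = 1)
#' panel <- derive_panel(cohort)
#' head(panel[, c("bmi", "tyg", "mets_ir")])
#' @export
derive_panel <- function(cohort, thresholds = index_thresholds()) {
  needed <- c("height_cm", "weight_kg", "waist_cm", "hdl_mgdl", "tg_mgdl",
              "glucose_mgdl")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks required columns: ", paste(missing_cols, collapse = ", "))

  out <- cohort
  out$bmi <- out$weight_kg / (out$height_cm / 100)^2
  out$wthr <- out$waist_cm / out$height_cm
  out$tg_hdl <- tg_hdl_ratio(out$tg_mgdl, out$hdl_mgdl)
  out$tyg <- tyg(out$tg_mgdl, out$glucose_mgdl)
  out$tyg_bmi <- out$tyg * out$bmi
  out$tyg_waist <- out$tyg * out$waist_cm
  out$tyg_wthr <- out$tyg * out$wthr
  out$mets_ir <- mets_ir(out$glucose_mgdl, out$tg_mgdl, out$bmi, out$hdl_mgdl)
  out$high_tg_hdl <- .flag_high(out$tg_hdl, thresholds$tg_hdl)
  out$high_tyg <- .flag_high(out$tyg, thresholds$tyg)
  out$high_mets_ir <- .flag_high(out$mets_ir, thresholds$mets_ir)
  out
}

# Names of the six scale columns, in reporting order.
.scale_cols <- c("tg_hdl", "tyg", "tyg_bmi", "tyg_waist", "tyg_wthr", "mets_ir")
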