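# Metabolic-syndrome classification under the NCEP/ATP-III, IDF and JIS
# criteria. Classification is measurement-only: the cohort carries no
# treatment or diagnosis fields, so drug-treated hypertension/diabetes cannot
# count as positive components (a documented divergence from the full
# published definitions).

#' Metabolic-syndrome criteria configuration
#'
#' Default Europid thresholds for the three criteria. All three share the
#' non-waist cut-offs — triglycerides >= 150 mg/dL, HDL < 40 (men) / < 50
#' (women) mg/dL, blood pressure >= 130 systolic or >= 85 diastolic mmHg,
#' fasting glucose >= 100 mg/dL — and differ only in the waist cut-offs and
#' the combination rule: ATP-III uses waist > 102/88 cm (men/women) and any 3
#' of 5 components; IDF uses waist >= 94/80 cm, mandatory, plus at least 2
#' others; JIS uses waist >= 94/80 cm and any 3 of 5.
#'
#' Every cut-off can be overridden, so alternative dialects (e.g. the
#' original ATP-III glucose >= 110) are a one-argument change.
#'
#' @param tg_cut Triglyceride cut-off, mg/dL (inclusive).
#' @param hdl_cut Named vector `c(male=, female=)` of HDL cut-offs, mg/dL
#'   (component positive when HDL is strictly below).
#' @param sbp_cut,dbp_cut Blood-pressure cut-offs, mmHg (inclusive; either
#'   suffices).
#' @param glucose_cut Fasting-glucose cut-off, mg/dL (inclusive).
#' @param waist_atpiii,waist_idf,waist_jis Named vectors `c(male=, female=)`
#'   of waist cut-offs in cm.
#' @return A named list of three criterion definitions, each with the
#'   component cut-offs, whether the waist comparison is strict, and the
#'   combination rule (`"any3"` or `"waist_plus_2"`).
#' @export
mets_criteria <- function(tg_cut = 150,
                          hdl_cut = c(male = 40, female = 50),
                          sbp_cut = 130, dbp_cut = 85,
                          glucose_cut = 100,
                          waist_atpiii = c(male = 102, female = 88),
                          waist_idf = c(male = 94, female = 80),
                          waist_jis = c(male = 94, female = 80)) {
  shared <- list(tg_cut = tg_cut, hdl_cut = hdl_cut, sbp_cut = sbp_cut,
                 dbp_cut = dbp_cut, glucose_cut = glucose_cut)
  crit <- list(
    atpiii = c(shared, list(waist_cut = waist_atpiii, waist_strict = TRUE,
                            rule = "any3")),
    idf = c(shared, list(waist_cut = waist_idf, waist_strict = FALSE,
                         rule = "waist_plus_2")),
    jis = c(shared, list(waist_cut = waist_jis, waist_strict = FALSE,
                         rule = "any3"))
  )
  for (nm in names(crit)) {
    cuts <- unlist(crit[[nm]][c("tg_cut", "hdl_cut", "sbp_cut", "dbp_cut",
                                "glucose_cut", "waist_cut")])
    if (any(cuts <= 0)) stop("all criterion cut-offs must be positive")
  }
  crit
}

#' Component flags for one criterion
#'
#' Evaluates the five metabolic-syndrome components against a criterion's
#' thresholds: elevated waist, elevated triglycerides, low HDL (sex-specific),
#' elevated blood pressure (systolic or diastolic) and elevated fasting
#' glucose. Triglyceride, blood-pressure and glucose flags are identical
#' across the three default criteria; only the waist cut-offs differ.
#'
#' @param cohort Cohort data.frame with `sex, waist_cm, tg_mgdl, hdl_mgdl,
#'   sbp_mmhg, dbp_mmhg, glucose_mgdl`.
#' @param criterion One element of [mets_criteria()].
#' @return A data.frame of logicals `waist_high, tg_high, hdl_low, bp_high,
#'   glucose_high`, one row per subject.
#' @export
component_flags <- function(cohort, criterion) {
  needed <- c("sex", "waist_cm", "tg_mgdl", "hdl_mgdl", "sbp_mmhg",
              "dbp_mmhg", "glucose_mgdl")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols))
    stop("cannot classify: missing columns ",
         paste(missing_cols, collapse = ", "))
  male <- cohort$sex == "M"
  wcut <- ifelse(male, criterion$waist_cut[["male"]],
                 criterion$waist_cut[["female"]])
  hcut <- ifelse(male, criterion$hdl_cut[["male"]],
                 criterion$hdl_cut[["female"]])
  data.frame(
    waist_high = if (criterion$waist_strict) cohort$waist_cm > wcut
                 else cohort$waist_cm >= wcut,
    tg_high = cohort$tg_mgdl >= criterion$tg_cut,
    hdl_low = cohort$hdl_mgdl < hcut,
    bp_high = cohort$sbp_mmhg >= criterion$sbp_cut |
              cohort$dbp_mmhg >= criterion$dbp_cut,
    glucose_high = cohort$glucose_mgdl >= criterion$glucose_cut
  )
}

# Combine the five component flags under a criterion's rule.
.combine_flags <- function(flags, rule) {
  n_pos <- rowSums(flags)
  switch(rule,
         any3 = n_pos >= 3,
         waist_plus_2 = flags$waist_high & (n_pos - flags$waist_high) >= 2,
         stop("unknown combination rule: ", rule))
}

#' Classify metabolic syndrome under all three criteria
#'
#' Appends the overall metabolic-syndrome status under ATP-III, IDF and JIS
#' to a cohort table. ATP-III and JIS are positive with any 3 of the 5
#' components; IDF requires elevated waist circumference (its mandatory
#' component) plus at least 2 of the remaining 4.
#'
#' @param cohort Cohort data.frame (see [component_flags()]).
#' @param criteria Criteria configuration from [mets_criteria()].
#' @param keep_flags If `TRUE`, also append the per-criterion component flags
#'   as columns `<criterion>_<flag>`.
#' @return The cohort with logical columns `ms_atpiii, ms_idf, ms_jis`
#'   appended.
#' @examples
#' cohort <- generate_cohort(default_spec(), n = 50, seed = 1)
#' table(classify_mets(cohort)$ms_idf)
#' @export
classify_mets <- function(cohort, criteria = mets_criteria(),
                          keep_flags = FALSE) {
  out <- cohort
  for (nm in names(criteria)) {
    flags <- component_flags(cohort, criteria[[nm]])
    out[[paste0("ms_", nm)]] <- .combine_flags(flags, criteria[[nm]]$rule)
    if (keep_flags)
      for (f in names(flags)) out[[paste(nm, f, sep = "_")]] <- flags[[f]]
  }
  out
}
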