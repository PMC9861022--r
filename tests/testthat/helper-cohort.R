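# Shared fixtures: small cohorts built in code.

small_cohort <- function(n = 200, seed = 11) {
  generate_cohort(default_spec(), n = n, seed = seed)
}

# Hand-built three-subject cohort exercising the classifier examples.
example_subjects <- function() {
  data.frame(
    subject_id = c("A", "B", "C"),
    sex = c("M", "M", "F"),
    age = c(45L, 45L, 40L),
    height_cm = c(175, 175, 162),
    weight_kg = c(85, 80, 60),
    waist_cm = c(105, 90, 85),
    sbp_mmhg = c(135, 118, 120),
    dbp_mmhg = c(88, 75, 75),
    total_chol_mgdl = c(200, 200, 190),
    hdl_mgdl = c(35, 35, 60),
    ldl_mgdl = c(133, 133, 110),
    tg_mgdl = c(160, 160, 100),
    glucose_mgdl = c(105, 105, 90),
    smoker = c(1L, 0L, 0L),
    social_class = c("III", "II", "I"),
    stringsAsFactors = FALSE
  )
}

# Brute-force Met-S status from five component flags and a rule.
brute_force_mets <- function(flags, rule) {
  n <- sum(unlist(flags))
  if (rule == "any3") n >= 3 else flags$waist_high && (n - flags$waist_high) >= 2
}

# Exhaustive Youden search: evaluate sens/spec directly at every candidate.
brute_force_youden <- function(scores, labels) {
  labels <- as.logical(labels)
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best <- NULL
  for (t in cand) {
    pred <- scores >= t
    sens <- sum(pred & labels) / sum(labels)
    spec <- sum(!pred & !labels) / sum(!labels)
    j <- sens + spec - 1
    if (is.null(best) || j > best$youden)
      best <- list(cutoff = t, sensitivity = sens, specificity = spec, youden = j)
  }
  best
}

# Brute-force AUC over all case-control pairs (concordant + half ties).
brute_force_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  x <- scores[labels]; y <- scores[!labels]
  tot <- 0
  for (xi in x) tot <- tot + sum(xi > y) + 0.5 * sum(xi == y)
  tot / (length(x) * length(y))
}
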