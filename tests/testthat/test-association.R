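test_that("2x2 closed form gives the textbook odds ratio and Woolf interval", {
  r <- or_from_2x2(30, 70, 10, 90)
  expect_equal(r$or, 2700 / 700, tolerance = 1e-12)
  expect_equal(r$se_log, sqrt(1 / 30 + 1 / 70 + 1 / 10 + 1 / 90), tolerance = 1e-12)
  expect_equal(r$ci, exp(log(r$or) + c(-1, 1) * qnorm(0.975) * r$se_log),
               tolerance = 1e-12)
  expect_equal(or_from_2x2(10, 10, 10, 10)$or, 1)
  expect_error(or_from_2x2(5, 0, 3, 7), "zero-cell")
})

test_that("single-predictor logistic fit reproduces the 2x2 closed form", {
  make_data <- function(a, b, c, d) {
    list(y = rep(c(1, 0, 1, 0), c(a, b, c, d)),
         x = rep(c(1, 1, 0, 0), c(a, b, c, d)))
  }
  d <- make_data(30, 70, 10, 90)
  fit <- fit_logistic(d$y, cbind(exposed = d$x))
  expect_equal(unname(fit$or["exposed"]), 3.857142857142857, tolerance = 1e-9)
  expect_true(fit$converged)

  set.seed(501)
  for (i in 1:50) {
    cells <- sample(3:60, 4, replace = TRUE)
    d <- make_data(cells[1], cells[2], cells[3], cells[4])
    fit <- fit_logistic(d$y, cbind(x = d$x))
    oracle <- or_from_2x2(cells[1], cells[2], cells[3], cells[4])
    expect_equal(unname(fit$or["x"]), oracle$or, tolerance = 1e-6)
    expect_equal(unname(fit$se["x"]), oracle$se_log, tolerance = 1e-6)
    expect_equal(unname(fit$or_ci["x", ]), unname(oracle$ci),
                 tolerance = 1e-6)
  }
})

test_that("logistic estimates agree with the stats::glm reference fit", {
  set.seed(502)
  n <- 400
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x1 - 0.6 * x2))
  fit <- fit_logistic(y, cbind(x1 = x1, x2 = x2))
  ref <- glm(y ~ x1 + x2, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  expect_equal(unname(fit$or), unname(exp(coef(ref))), tolerance = 1e-6)
  # OR/CI internal identities
  expect_equal(fit$or, exp(fit$coefficients), tolerance = 1e-12)
  expect_equal(unname(fit$or_ci[, "lo"]),
               unname(exp(fit$coefficients - qnorm(0.975) * fit$se)),
               tolerance = 1e-12)
})

test_that("IRLS log-likelihood is non-decreasing and degenerate designs error", {
  set.seed(503)
  n <- 200
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(x))
  fit <- fit_logistic(y, cbind(x = x))
  expect_true(all(diff(fit$loglik) >= -1e-10))
  expect_lte(fit$iterations, 100)
  # perfectly separating predictor
  xs <- c(rep(0, 20), rep(1, 20))
  ys <- xs
  expect_error(fit_logistic(ys, cbind(x = xs)), "separation")
  # rank-deficient design
  expect_error(fit_logistic(y, cbind(a = x, b = 2 * x)), "rank deficient")
  expect_error(fit_logistic(rep(1, 10), cbind(x = rnorm(10))), "degenerate")
})

test_that("null predictors give odds ratios near 1 with nominal CI coverage", {
  set.seed(504)
  cover <- 0
  reps <- 200
  for (i in seq_len(reps)) {
    x <- rbinom(120, 1, 0.5)
    y <- rbinom(120, 1, 0.4)  # independent of x
    fit <- tryCatch(fit_logistic(y, cbind(x = x)), error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$or_ci["x", "lo"] <= 1 && 1 <= fit$or_ci["x", "hi"])
      cover <- cover + 1
  }
  expect_gt(cover / reps, 0.90)  # ~95% nominal
})

test_that("scale-to-syndrome OR table mirrors the 3x3 layout with positive coupling", {
  co <- classify_mets(derive_panel(small_cohort(n = 8000, seed = 61)))
  tab <- scale_to_mets_or(co)
  expect_equal(nrow(tab), 9)
  expect_true(all(is.na(tab$error)))
  expect_true(all(tab$or > 1))
  # shuffled flags destroy the association
  set.seed(1)
  co$high_tyg <- sample(co$high_tyg)
  null_or <- scale_to_mets_or(co)
  null_or <- null_or[null_or$predictor == "high_tyg", ]
  expect_true(all(abs(log(null_or$or)) < 0.25))
  # adjusted variant returns the same layout
  adj <- scale_to_mets_or(co, adjust = c("age", "sex"))
  expect_equal(dim(adj), dim(tab))
})

test_that("component-to-scale OR table covers both threshold sets; small n does not crash", {
  co <- classify_mets(derive_panel(small_cohort(n = 8000, seed = 62)))
  tab <- component_to_scale_or(co)
  expect_equal(nrow(tab), 30)  # 2 sets x 5 components x 3 flags
  expect_setequal(unique(tab$threshold_set), c("atpiii_jis", "idf"))
  ok <- tab[is.na(tab$error), ]
  expect_true(all(ok$or > 1))
  # waist dominates blood pressure for the TyG outcome under both sets
  for (s in c("atpiii_jis", "idf")) {
    sub <- tab[tab$threshold_set == s & tab$outcome == "high_tyg", ]
    expect_gt(sub$or[sub$component == "waist_high"],
              sub$or[sub$component == "bp_high"])
  }
  tiny <- component_to_scale_or(
    classify_mets(derive_panel(small_cohort(n = 100, seed = 63))))
  expect_equal(nrow(tiny), 30)  # wide CIs or flagged errors, never a crash
})

test_that("descriptives reproduce closed-form t and chi-square statistics", {
  co <- small_cohort(n = 400, seed = 64)
  des <- descriptives(co)
  expect_true(all(c("waist_cm", "tg_mgdl", "age") %in% des$continuous$variable))
  # closed-form pooled t for one variable
  x <- co$waist_cm[co$sex == "F"]; y <- co$waist_cm[co$sex == "M"]
  sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
               (length(x) + length(y) - 2))
  t_manual <- (mean(x) - mean(y)) / (sp * sqrt(1 / length(x) + 1 / length(y)))
  got <- des$continuous[des$continuous$variable == "waist_cm", ]
  expect_equal(got$t_stat, t_manual, tolerance = 1e-12)
  expect_equal(got$female_mean, mean(x), tolerance = 1e-12)
  # identical groups: t = 0, p = 1
  same <- co[rep(1:10, 2), ]
  same$sex <- rep(c("F", "M"), each = 10)
  d0 <- descriptives(same)
  expect_equal(d0$continuous$t_stat, rep(0, nrow(d0$continuous)), tolerance = 1e-12)
  expect_equal(d0$continuous$p_value, rep(1, nrow(d0$continuous)), tolerance = 1e-12)
  # homogeneous 2x2 gives chi-square statistic 0
  hom <- data.frame(sex = rep(c("F", "M"), each = 20),
                    age = 30L, height_cm = 170, weight_kg = 70, waist_cm = 80,
                    sbp_mmhg = 120, dbp_mmhg = 70, total_chol_mgdl = 190,
                    hdl_mgdl = 55, ldl_mgdl = 110, tg_mgdl = 100,
                    glucose_mgdl = 90,
                    smoker = rep(c(0L, 1L), 20),
                    social_class = "III")
  dh <- descriptives(hom)
  smk <- dh$categorical[dh$categorical$variable == "smoker", ]
  expect_equal(unique(smk$chisq_stat), 0, tolerance = 1e-12)
  expect_error(descriptives(co[co$sex == "M", ]), "per sex")
})
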