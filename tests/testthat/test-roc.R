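test_that("ROC points match hand enumeration and handle ties", {
  pts <- roc_points(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(pts$fpr, c(0, 0, 0, 0.5, 1))
  expect_equal(pts$tpr, c(0, 0.5, 1, 1, 1))
  expect_equal(pts$threshold, c(Inf, 4, 3, 2, 1))
  # monotone, starts (0,0), ends (1,1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  # all scores tied: single jump to (1,1)
  tied <- roc_points(rep(2, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(tied$fpr, c(0, 1))
  expect_equal(tied$tpr, c(0, 1))
  expect_error(roc_points(1:3, c(1, 1, 1)), "degenerate")
})

test_that("AUC equals the pairwise concordance probability on small examples", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(auc(rep(3, 8), rep(c(0, 1), 4))$auc, 0.5)
  expect_equal(auc(c(1, 3, 2, 4), c(1, 1, 0, 0))$auc, 0.25)
  a <- auc(c(1, 2, 2, 3), c(0, 0, 1, 1))
  expect_equal(a$auc, brute_force_auc(c(1, 2, 2, 3), c(0, 0, 1, 1)))
  expect_true(a$ci[1] <= a$auc && a$auc <= a$ci[2])
})

test_that("trapezoidal area, Mann-Whitney concordance and brute force agree", {
  set.seed(401)
  for (i in 1:100) {
    n <- sample(4:25, 1)
    scores <- round(rnorm(n), sample(0:2, 1))  # induce ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    pts <- roc_points(scores, labels)
    trap <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
    a <- auc(scores, labels)$auc
    expect_equal(a, trap, tolerance = 1e-12)
    expect_equal(a, brute_force_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("label inversion flips the AUC when scores are tie-free", {
  set.seed(402)
  for (i in 1:20) {
    n <- sample(6:30, 1)
    scores <- rnorm(n)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    expect_equal(auc(scores, !labels)$auc, 1 - auc(scores, labels)$auc,
                 tolerance = 1e-12)
  }
})

test_that("Youden cut-point equals exhaustive search and reports consistent J", {
  # perfect separation: J = 1 with the cutoff strictly between the groups
  y <- best_cutoff_youden(c(10, 11, 1, 2), c(1, 1, 0, 0))
  expect_equal(y$youden, 1)
  expect_true(y$cutoff > 2 && y$cutoff < 10)
  # all scores equal: no discriminating threshold
  expect_equal(best_cutoff_youden(rep(5, 6), c(1, 0, 1, 0, 1, 0))$youden, 0)
  # interleaved case where no interior threshold beats the extremes
  y2 <- best_cutoff_youden(c(1, 3, 2, 4), c(1, 1, 0, 0))
  expect_equal(y2$youden, 0)
  expect_equal(y2, brute_force_youden(c(1, 3, 2, 4), c(1, 1, 0, 0)))

  set.seed(403)
  for (i in 1:100) {
    n <- sample(4:20, 1)
    scores <- round(runif(n, 0, 10), sample(0:1, 1))
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    got <- best_cutoff_youden(scores, labels)
    want <- brute_force_youden(scores, labels)
    expect_equal(got$youden, want$youden, tolerance = 1e-12)
    expect_equal(got$cutoff, want$cutoff)
    expect_equal(got$youden, got$sensitivity + got$specificity - 1,
                 tolerance = 1e-12)
  }
})

test_that("DeLong AUC and CI agree with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(404)
  for (i in 1:10) {
    n <- 80
    labels <- rep(c(TRUE, FALSE), each = n / 2)
    scores <- rnorm(n, mean = ifelse(labels, 0.8, 0))
    ours <- auc(scores, labels)
    ref <- suppressMessages(pROC::ci.auc(pROC::roc(labels, scores,
                                                   direction = "<", quiet = TRUE),
                                         method = "delong"))
    expect_equal(ours$auc, as.numeric(ref[2]), tolerance = 1e-10)
    expect_equal(ours$ci, as.numeric(ref[c(1, 3)]), tolerance = 1e-8)
  }
})

test_that("the ROC battery produces the full stratified layout", {
  co <- classify_mets(derive_panel(small_cohort(n = 4000, seed = 31)))
  bat <- run_roc_battery(co)
  expect_equal(nrow(bat), 36)  # 6 scales x 3 criteria x 2 sexes
  expect_true(all(bat$computable))
  expect_true(all(bat$auc > 0.5))  # positive metabolic coupling
  expect_true(all(bat$auc_lo <= bat$auc & bat$auc <= bat$auc_hi))
  expect_equal(bat$youden, bat$sensitivity + bat$specificity - 1,
               tolerance = 1e-12)
  # one-sex cohort: 18 computable entries plus 18 not-computable flags
  men <- co[co$sex == "M", ]
  bat_m <- run_roc_battery(men)
  expect_equal(nrow(bat_m), 36)
  expect_equal(sum(bat_m$computable), 18)
  expect_true(all(is.na(bat_m$auc[!bat_m$computable])))
  # noise scores discriminate nothing
  noisy <- co
  set.seed(1)
  noisy$tyg <- runif(nrow(noisy))
  b <- run_roc_battery(noisy, scales = "tyg", criteria = "idf")
  expect_true(all(abs(b$auc - 0.5) < 0.03))
})
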