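test_that("diagnostic metrics reproduce a 50-case confusion matrix", {
  # TP 17, FN 2, TN 29, FP 2 (19 positives in 50 cases)
  pos_pred <- c(rep(0.70, 17), rep(0.90, 2))   # 17 called, 2 missed
  neg_pred <- c(rep(0.95, 29), rep(0.75, 2))   # 29 called, 2 false alarms
  predicted <- c(pos_pred, neg_pred)
  reference <- c(rep(0.70, 19), rep(0.95, 31))
  rep_ <- classify_and_score(predicted, reference)
  expect_equal(unname(rep_$counts), c(17, 2, 29, 2))  # TP FP TN FN
  m <- rep_$metrics
  expect_equal(round(m["sensitivity", "pct"], 1), 89.5)
  expect_equal(round(m["specificity", "pct"], 1), 93.5)
  expect_equal(round(m["PPV", "pct"], 1), 89.5)
  expect_equal(round(m["NPV", "pct"], 1), 93.5)
  expect_equal(m["accuracy", "pct"], 92.0)
  # Clopper-Pearson CIs agree with binom.test
  ci <- as.numeric(binom.test(17, 19)$conf.int)
  expect_equal(unname(m["sensitivity", c("ci_lo", "ci_hi")]), 100 * ci,
               tolerance = 1e-12)
})

test_that("perfect and degenerate classifiers behave at the boundaries", {
  set.seed(1)
  ref <- runif(30, 0.5, 1.1)
  rep_ <- classify_and_score(ref, ref)
  expect_equal(unname(rep_$metrics[, "pct"]),
               rep(100, 5))
  expect_equal(rep_$bland_altman$mean_difference, 0)
  expect_equal(rep_$bland_altman$sd, 0)
  # all predictions non-ischemic
  mixed <- c(rep(0.6, 10), rep(1.0, 10))
  rep2 <- classify_and_score(rep(1.0, 20), mixed)
  expect_equal(unname(rep2$metrics["sensitivity", "pct"]), 0)
  expect_equal(unname(rep2$metrics["specificity", "pct"]), 100)
  # exact threshold value classifies ischemic
  rep3 <- classify_and_score(c(0.80, 0.81), c(0.70, 0.70))
  expect_equal(unname(rep3$counts["TP"]), 1L)
  expect_error(classify_and_score(1:3 / 3, 1:2 / 2), "lengths")
  expect_error(classify_and_score(c(0.5, 2), c(0.5, 0.6)), "input error")
})

test_that("metric identities hold over random confusion matrices", {
  set.seed(5)
  for (i in 1:30) {
    counts <- rmultinom(1, size = sample(20:200, 1), prob = runif(4, 0.05, 1))
    TP <- counts[1]; FP <- counts[2]; TN <- counts[3]; FN <- counts[4]
    predicted <- c(rep(0.7, TP), rep(0.7, FP), rep(0.9, TN), rep(0.9, FN))
    reference <- c(rep(0.7, TP), rep(0.9, FP), rep(0.9, TN), rep(0.7, FN))
    # jitter within class to keep values distinct but classifications fixed
    predicted <- predicted + runif(length(predicted), -0.02, 0.02)
    reference <- reference + runif(length(reference), -0.02, 0.02)
    r <- classify_and_score(predicted, reference)
    expect_equal(unname(r$counts), c(TP, FP, TN, FN))
    if (TP + FP > 0)
      expect_equal(unname(r$metrics["PPV", "pct"]), 100 * TP / (TP + FP))
    if (TN + FN > 0)
      expect_equal(unname(r$metrics["NPV", "pct"]), 100 * TN / (TN + FN))
    expect_equal(unname(r$metrics["accuracy", "pct"]),
                 100 * (TP + TN) / sum(counts))
  }
})

test_that("Bland-Altman summaries are symmetric about the mean difference", {
  set.seed(8)
  pred <- runif(40, 0.6, 1.0); ref <- pred + rnorm(40, 0.01, 0.05)
  ref <- pmin(pmax(ref, 0.3), 1.4)
  r <- classify_and_score(pred, ref)
  ba <- r$bland_altman
  expect_equal(ba$mean_difference, mean(pred - ref))
  expect_equal(mean(ba$limits), ba$mean_difference)
  expect_equal(diff(ba$limits), 2 * 1.96 * sd(pred - ref))
  expect_equal(r$pearson_r, cor(pred, ref))
})

test_that("ROC analysis recovers separation, symmetry, and the threshold", {
  # perfectly separated predictions
  pred <- c(rep(0.6, 8), rep(0.95, 12))
  ref <- c(rep(0.7, 8), rep(0.9, 12))
  roc <- roc_threshold_recovery(pred, ref)
  expect_equal(roc$AUC, 1.0)
  expect_true(roc$optimal_threshold["lo"] >= 0.6 &&
              roc$optimal_threshold["hi"] <= 0.95)
  # label-independent predictions give AUC ~ 0.5
  set.seed(200)
  predr <- runif(200, 0.4, 1.2)
  refr <- sample(c(0.7, 0.9), 200, replace = TRUE)
  rocr <- roc_threshold_recovery(predr, refr)
  expect_lt(abs(rocr$AUC - 0.5), 0.1)
  # reversing the score orientation maps AUC -> 1 - AUC
  roc_rev <- roc_threshold_recovery(-predr + 2, refr)
  expect_equal(roc_rev$AUC, 1 - rocr$AUC, tolerance = 1e-12)
  expect_error(roc_threshold_recovery(predr, rep(0.9, 200)), "single class")
})

test_that("AUC equals the Mann-Whitney U normalization", {
  set.seed(31)
  for (i in 1:10) {
    n1 <- sample(5:30, 1); n0 <- sample(5:30, 1)
    pred <- c(runif(n1, 0.4, 1.0), runif(n0, 0.6, 1.2))
    ref <- c(rep(0.7, n1), rep(0.9, n0))
    auc <- roc_threshold_recovery(pred, ref)$AUC
    # positives have LOW predicted FFR; U counts pred_pos < pred_neg
    u <- sum(outer(pred[1:n1], pred[-(1:n1)], "<")) +
      0.5 * sum(outer(pred[1:n1], pred[-(1:n1)], "=="))
    expect_equal(auc, u / (n1 * n0), tolerance = 1e-12)
  }
})

test_that("AUC cross-checks against an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  pred <- runif(80, 0.4, 1.2)
  ref <- ifelse(runif(80) < plogis((pred - 0.8) * 8), 0.9, 0.7)
  if (length(unique(ref)) < 2) ref[1:2] <- c(0.7, 0.9)
  ours <- roc_threshold_recovery(pred, ref)$AUC
  theirs <- suppressMessages(
    as.numeric(pROC::auc(response = as.integer(ref <= 0.8),
                         predictor = -pred)))
  expect_equal(ours, theirs, tolerance = 1e-9)
})

test_that("model configurations set the documented source flags", {
  b <- build_model_config("baseline")
  expect_true(all(b$flags == "patient_specific"))
  s <- build_model_config("semi-streamlined")
  expect_identical(unname(s$flags["MAP"]), "generalized")
  expect_identical(unname(s$flags["inlet_CO"]), "generalized")
  expect_identical(unname(s$flags["resistance_CO"]), "patient_specific")
  expect_identical(unname(s$flags["distal_location"]), "patient_specific")
  st <- build_model_config("streamlined")
  expect_identical(unname(st$flags["distal_location"]), "generalized")
  expect_equal(st$generalized$distal_location_mm, 30)
  expect_equal(st$generalized$MAP_mmHg, 87.3)
  expect_equal(st$generalized$CO_Lmin, 4.5)
  expect_error(build_model_config("turbo"), "arg")
  # applying the config swaps in the generalized values
  cases <- generate_cohort(cohort_recipe(n_patients = 1), seed = 4)
  eff <- apply_model_config(cases[[1]], st)
  expect_equal(eff$patient$MAP_mmHg, 87.3)
  expect_equal(eff$patient$HR_bpm, 70.8)
  expect_equal(eff$config$inlet_CO_Lmin, 4.5)
  expect_null(eff$config$resistance_CO_Lmin)
})

test_that("distal-location generalization moves FFR more than the rest", {
  # patients whose scalars sit at the cohort averages but whose distal
  # locations do not: semi-streamlining then changes nothing (its
  # generalized values equal the patient values), while full streamlining
  # moves the probe to 30 mm and must shift FFR
  cases <- generate_cohort(cohort_recipe(n_patients = 2), seed = 9)
  g <- generalized_inputs()
  for (i in seq_along(cases)) {
    cases[[i]]$patient$MAP_mmHg <- g$MAP_mmHg
    cases[[i]]$patient$HR_bpm <- g$HR_bpm
    cases[[i]]$patient$hematocrit_pct <- g$hematocrit_pct
    cases[[i]]$patient$CO_Lmin <- g$CO_Lmin
    cases[[i]]$patient$distal_location_mm <- c(8, 40)[i]
  }
  base <- cohort_ffr(cases, "baseline", controls = demo_controls())
  semi <- cohort_ffr(cases, "semi-streamlined", controls = demo_controls())
  full <- cohort_ffr(cases, "streamlined", controls = demo_controls())
  expect_equal(semi, base, tolerance = 1e-9)
  expect_gt(mean(abs(full - base)), mean(abs(semi - base)))
  expect_true(all(full != base))
})
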