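test_that("cross-validated Q2 matches the explicit-loop oracle", {
  inst <- make_instance(12, 20, seed = 41, effect = 1)
  for (a in 1:2) {
    cv <- cross_validate(inst$x, inst$labels, NULL, ncomp = a, n_folds = 4,
                         seed = 9)
    q2_oracle <- oracle_q2(inst$x, inst$labels, cv$fold_id, ncomp = a)
    expect_equal(cv$Q2, q2_oracle, tolerance = 1e-10)
  }
})

test_that("Q2 never exceeds R2 and is high only under real signal", {
  strong <- simulate_dataset(simulation_design(n_per_group = 12,
                                               n_features = 300,
                                               n_markers = 20,
                                               n_confounded = 0,
                                               marker_effect = 3, seed = 10))
  for (nf in c(6, 7, 8)) {
    fit <- pls2da(strong$features, strong$metadata$class, ncomp = 2)
    cv <- cross_validate(strong$features, strong$metadata$class, NULL,
                         ncomp = 2, n_folds = nf, seed = 3)
    expect_gt(cv$Q2, 0.5)
    expect_lte(cv$Q2, fit$R2)
  }
})

test_that("pure-noise data yields a null-centered, mostly nonpositive Q2", {
  q2 <- sapply(1:50, function(s) {
    sim <- simulate_dataset(simulation_design(n_per_group = 12,
                                              n_features = 200, n_markers = 0,
                                              n_confounded = 0,
                                              marker_effect = 0, seed = s))
    cross_validate(sim$features, sim$metadata$class, NULL, ncomp = 1,
                   n_folds = 7, seed = s)$Q2
  })
  # the null Q2 distribution sits at or below zero (its upper tail is what
  # the permutation test calibrates against)
  expect_lt(mean(q2), 0)
  expect_lte(median(q2), 0)
  expect_gt(mean(q2 <= 0), 0.55)
  expect_lt(max(q2), 0.5)
})

test_that("permutation p-value follows the add-one estimator and its floor", {
  strong <- simulate_dataset(simulation_design(n_per_group = 10,
                                               n_features = 100,
                                               n_markers = 20,
                                               n_confounded = 0,
                                               marker_effect = 3, seed = 12))
  pt <- permutation_test(strong$features, strong$metadata$class, NULL,
                         ncomp = 1, n_folds = 7, n_perm = 24, seed = 5)
  expect_equal(pt$p_value,
               (sum(pt$q2_perm >= pt$q2_obs) + 1) / (pt$n_perm + 1))
  # strong signal beats every permutation: the floor 1/(n_perm + 1) is hit
  expect_equal(pt$p_value, 1 / 25)
  expect_gt(pt$p_value, 0)
  expect_lte(pt$p_value, 1)
})

test_that("permutation p is invariant to relabeling the classes", {
  inst <- make_instance(12, 30, seed = 51, effect = 1.5)
  pt1 <- permutation_test(inst$x, inst$labels, NULL, ncomp = 1, n_folds = 4,
                          n_perm = 19, seed = 7)
  flipped <- factor(ifelse(inst$labels == "case", "B", "A"),
                    levels = c("B", "A"))
  pt2 <- permutation_test(inst$x, flipped, NULL, ncomp = 1, n_folds = 4,
                          n_perm = 19, seed = 7)
  expect_equal(pt1$p_value, pt2$p_value)
})

test_that("ROC handles the canonical hand-computed cases", {
  lab <- factor(c("ctl", "ctl", "case", "case"), levels = c("case", "ctl"))
  perfect <- roc_analysis(c(1, 2, 3, 4), lab, case = "case")
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  # interleaved scores: 3 concordant pairs of 4
  inter <- roc_analysis(c(1, 3, 2, 4), lab, case = "case")
  expect_equal(inter$auc, 0.75)
  expect_equal(inter$sensitivity, 1)     # tie broken toward sensitivity
  expect_equal(inter$specificity, 0.5)
  expect_gt(inter$threshold, 1); expect_lt(inter$threshold, 2)
  ties <- roc_analysis(rep(2, 4), lab, case = "case")
  expect_equal(ties$auc, 0.5)
  expect_error(roc_analysis(1:3, factor(rep("a", 3), levels = c("a", "b"))),
               "both classes")
})

test_that("AUC equals exhaustive pair counting on random instances", {
  set.seed(61)
  for (i in 1:100) {
    n1 <- sample(3:8, 1); n0 <- sample(3:8, 1)
    scores <- sample(seq_len(6), n1 + n0, replace = TRUE) +
      round(rnorm(n1 + n0), 1)
    pos <- c(rep(TRUE, n1), rep(FALSE, n0))
    lab <- factor(ifelse(pos, "case", "ctl"), levels = c("case", "ctl"))
    r <- roc_analysis(scores, lab, ci = FALSE)
    expect_identical(r$auc, oracle_auc(scores, pos))
  }
})

test_that("ROC curve is a valid monotone path from (0,0) to (1,1)", {
  set.seed(62)
  scores <- rnorm(20)
  lab <- factor(rep(c("case", "ctl"), 10), levels = c("case", "ctl"))
  r <- roc_analysis(scores, lab)
  expect_equal(r$curve$fpr[1], 0); expect_equal(r$curve$tpr[1], 0)
  expect_equal(r$curve$fpr[nrow(r$curve)], 1)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
})

test_that("DeLong interval contains the AUC and widens as n shrinks", {
  set.seed(63)
  scores <- c(rnorm(40, 1), rnorm(40))
  lab <- factor(rep(c("case", "ctl"), each = 40), levels = c("case", "ctl"))
  widths <- sapply(c(80, 40, 20), function(k) {
    idx <- c(seq_len(k / 2), 40 + seq_len(k / 2))
    r <- roc_analysis(scores[idx], lab[idx])
    expect_gte(r$auc, r$auc_ci95[1])
    expect_lte(r$auc, r$auc_ci95[2])
    diff(r$auc_ci95)
  })
  expect_true(all(diff(widths) > 0))
})

test_that("confounding screen flags leakage and clears independent metadata", {
  sim <- simulate_dataset(simulation_design(n_per_group = 12, n_features = 5,
                                            n_markers = 0, n_confounded = 0,
                                            seed = 14))
  leaky <- sim$metadata
  leaky$copy <- as.numeric(leaky$class == "case")
  scr <- confounding_screen(leaky, covariates = c("maternal_age", "bmi", "copy"),
                            seed = 2)
  expect_true(scr$confounded)
  expect_gt(scr$q2, 0.5)

  verdicts <- sapply(1:50, function(s) {
    simn <- simulate_dataset(simulation_design(n_per_group = 12,
                                               n_features = 5, n_markers = 0,
                                               n_confounded = 0, seed = s))
    covs <- c("maternal_age", "bmi", "previous_miscarriages", "nifedipine",
              "betamethasone", "atosiban", "progesterone",
              "gestational_age", "male")
    suppressWarnings(
      confounding_screen(simn$metadata, covariates = covs, seed = s)$confounded)
  })
  expect_gte(mean(!verdicts), 0.9)
})

test_that("external factor check is calibrated and detects true association", {
  sim <- simulate_dataset(simulation_design(n_per_group = 12,
                                            n_features = 200, n_markers = 25,
                                            n_confounded = 0,
                                            marker_effect = 3, seed = 15))
  fit <- pls2da(sim$features, sim$metadata$class, ncomp = 2)
  # positive control: the class itself
  chk <- external_factor_check(fit, as.numeric(sim$metadata$class == "case"))
  expect_gt(abs(chk$correlation), 0.7)
  expect_lt(chk$p_value, 0.001)
  # construction: median split of the predictive score correlates positively
  dich <- as.numeric(fit$T[, 1] > median(fit$T[, 1]))
  expect_gt(external_factor_check(fit, dich)$correlation, 0)
  # calibration under independent random factors
  set.seed(16)
  pvals <- replicate(200, {
    f <- rbinom(24, 1, 0.4)
    while (length(unique(f)) < 2) f <- rbinom(24, 1, 0.4)
    external_factor_check(fit, f)$p_value
  })
  expect_lt(abs(mean(pvals <= 0.05) - 0.05), 0.05)
  expect_error(external_factor_check(fit, rep(1, 24)), "constant")
})

test_that("validate_model assembles a coherent report", {
  sim <- simulate_dataset(simulation_design(n_per_group = 10,
                                            n_features = 120, n_markers = 15,
                                            n_confounded = 5,
                                            marker_effect = 2, seed = 17))
  zb <- encode_constraints(sim$metadata, c("maternal_age", "bmi"))
  rep <- validate_model(sim$features, sim$metadata$class, zb, ncomp = 2,
                        folds = c(6, 7), n_perm = 19, seed = 4)
  expect_named(rep$Q2_by_folds, c("Q2_6folds", "Q2_7folds"))
  expect_true(all(rep$Q2_by_folds <= 1))
  expect_gt(rep$roc$auc, 0.5)
  expect_true(rep$perm_pvalue > 0 && rep$perm_pvalue <= 1)
})
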