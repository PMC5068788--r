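no_scale <- pretreat_spec(log = FALSE, centering = "mean", scaling = "none")

test_that("single-feature PLS equals ordinary least squares", {
  inst <- make_instance(10, 1, seed = 3, effect = 1)
  fit <- pls2da(inst$x, inst$labels, ncomp = 1, pretreat = no_scale,
                post_transform = FALSE)
  xc <- scale(inst$x, scale = FALSE)
  Yraw <- cbind(as.numeric(inst$labels == "case"),
                as.numeric(inst$labels == "control"))
  ybar <- colMeans(Yraw)
  yc <- sweep(Yraw, 2, ybar)
  ols <- sweep(xc %*% solve(crossprod(xc), crossprod(xc, yc)), 2, ybar, "+")
  expect_lt(max(abs(fitted(fit) - ols)), 1e-10)
})

test_that("first weight matches the brute-force eigen-oracle", {
  for (s in 1:10) {
    inst <- make_instance(8, 5, seed = s)
    fit <- pls2da(inst$x, inst$labels, ncomp = 1, pretreat = no_scale,
                  post_transform = FALSE)
    xc <- scale(inst$x, scale = FALSE)
    rb <- response_block(inst$labels)
    w_oracle <- oracle_dominant_left(crossprod(xc, rb$Y))
    w_fit <- fit$W[, 1]
    sgn <- sign(sum(w_oracle * w_fit))
    expect_lt(max(abs(w_fit - sgn * w_oracle)), 1e-8)
  }
})

test_that("at full rank the PLS R2 equals the multivariate least-squares R2", {
  inst <- make_instance(8, 5, seed = 11)
  fit <- pls2da(inst$x, inst$labels, ncomp = 5, pretreat = no_scale,
                post_transform = FALSE)
  xc <- scale(inst$x, scale = FALSE)
  rb <- response_block(inst$labels)
  resid <- rb$Y - xc %*% solve(crossprod(xc), crossprod(xc, rb$Y))
  r2_ols <- 1 - sum(resid^2) / sum(rb$Y^2)
  expect_equal(fit$R2, r2_ols, tolerance = 1e-8)
})

test_that("R2 is nondecreasing in the number of components", {
  inst <- make_instance(12, 10, seed = 13, effect = 0.5)
  r2 <- sapply(1:4, function(a)
    pls2da(inst$x, inst$labels, ncomp = a)$R2)
  expect_true(all(diff(r2) >= -1e-12))
  expect_true(all(r2 >= 0 & r2 <= 1))
})

test_that("empty constraints reduce oCPLS2-DA exactly to PLS2-DA", {
  for (s in 1:10) {
    n <- sample(8:16, 1)
    p <- sample(5:40, 1)
    inst <- make_instance(n, p, seed = 100 + s, effect = 0.5)
    a <- min(3, n - 2, p)
    f_pls <- pls2da(inst$x, inst$labels, ncomp = a, post_transform = FALSE)
    f_con <- ocpls2da(inst$x, inst$labels,
                      constraints = matrix(numeric(0), n, 0), ncomp = a,
                      post_transform = FALSE)
    expect_lt(max(abs(f_pls$T - f_con$T)), 1e-8)
    expect_lt(max(abs(f_pls$P - f_con$P)), 1e-8)
    expect_lt(max(abs(f_pls$B - f_con$B)), 1e-8)
  }
})

test_that("scores are orthogonal to the constraints for every component", {
  for (s in 1:5) {
    inst <- make_instance(14, 25, seed = 200 + s, effect = 1)
    set.seed(300 + s)
    Z <- cbind(rnorm(14), rbinom(14, 1, 0.5), rnorm(14, 30, 4))
    fit <- ocpls2da(inst$x, inst$labels, constraints = Z, ncomp = 3)
    Zc <- fit$Z
    for (a in seq_len(ncol(fit$T)))
      expect_lt(max(abs(crossprod(Zc, fit$T[, a]))),
                1e-8 * norm(Zc, "F") * sqrt(sum(fit$T[, a]^2)))
    # NIPALS score columns are mutually orthogonal (before the in-model
    # rotation, which preserves Z-orthogonality but mixes score variances)
    raw <- ocpls2da(inst$x, inst$labels, constraints = Z, ncomp = 3,
                    post_transform = FALSE)
    G <- crossprod(raw$T)
    off <- G - diag(diag(G))
    expect_lt(max(abs(off)) / max(diag(G)), 1e-8)
    for (a in seq_len(ncol(raw$T)))
      expect_lt(max(abs(crossprod(Zc, raw$T[, a]))),
                1e-8 * norm(Zc, "F") * sqrt(sum(raw$T[, a]^2)))
  }
})

test_that("constraining on the class response destroys discrimination", {
  sim <- simulate_dataset(simulation_design(n_per_group = 12,
                                            n_features = 100, n_markers = 15,
                                            n_confounded = 0,
                                            marker_effect = 2, seed = 4))
  y01 <- as.numeric(sim$metadata$class == "case")
  Z <- matrix(y01 - mean(y01), ncol = 1)
  # every direction of Y-covariance lies in the constrained-out space, so no
  # discriminative component survives and predictions carry no class signal
  expect_warning(
    fit <- ocpls2da(sim$features, sim$metadata$class, constraints = Z,
                    ncomp = 2, post_transform = FALSE),
    "degenerate")
  if (fit$A >= 1) {
    tstat <- abs(t.test(fit$T[, 1] ~ sim$metadata$class)$statistic)
    expect_lt(tstat, 1e-6)
  } else {
    expect_equal(max(abs(fit$B)), 0)
  }
  q2 <- cross_validate(sim$features, sim$metadata$class, Z, ncomp = 2,
                       n_folds = 7, seed = 1)$Q2
  expect_lte(q2, 0)
})

test_that("rank-deficient constraints are rejected", {
  inst <- make_instance(10, 8, seed = 17)
  Z <- cbind(a = rnorm(10), b = rnorm(10))
  Z <- cbind(Z, c = Z[, "a"] + Z[, "b"])
  expect_error(ocpls2da(inst$x, inst$labels, constraints = Z, ncomp = 1),
               "dependent")
  expect_error(pls2da(inst$x, inst$labels, ncomp = 40), "rank")
})

test_that("post-transformation yields the 1+2 split without changing the model", {
  inst <- make_instance(16, 30, seed = 21, effect = 1)
  f0 <- pls2da(inst$x, inst$labels, ncomp = 3, post_transform = FALSE)
  f1 <- pls2da(inst$x, inst$labels, ncomp = 3, post_transform = TRUE)
  expect_identical(f1$A_pred, 1L)
  expect_identical(f1$A_orth, 2L)
  expect_lt(max(abs(fitted(f1) - fitted(f0))), 1e-10)
  expect_lt(max(abs(f1$T %*% t(f1$P) - f0$T %*% t(f0$P))), 1e-10)
  expect_lt(max(abs(f1$B - f0$B)), 1e-10)
  # rotated Y-orthogonal scores are uncorrelated with the centered response
  Yc <- f1$response$Y
  expect_lt(max(abs(cor(f1$T[, -seq_len(f1$A_pred)], Yc))), 1e-8)
  # rotation is orthonormal
  expect_lt(max(abs(crossprod(f1$G) - diag(3))), 1e-10)
})

test_that("prediction reproduces the training fit and respects duplicates", {
  inst <- make_instance(12, 20, seed = 23, effect = 1.5)
  fit <- ocpls2da(inst$x, inst$labels,
                  constraints = matrix(rnorm(12), ncol = 1), ncomp = 2)
  expect_lt(max(abs(predict(fit, inst$x) - fitted(fit))), 1e-10)
  dup <- inst$x[c(1, 1, 5, 5), ]
  pr <- predict(fit, dup)
  expect_identical(pr[1, ], pr[2, ])
  expect_identical(pr[3, ], pr[4, ])
  wrong <- inst$x[, 1:10]
  expect_error(predict(fit, wrong), "feature mismatch")
})

test_that("held-out class calls are accurate under strong synthetic signal", {
  sim <- simulate_dataset(simulation_design(n_per_group = 12,
                                            n_features = 500, n_markers = 25,
                                            n_confounded = 0,
                                            marker_effect = 2, seed = 6))
  cv <- cross_validate(sim$features, sim$metadata$class, NULL, ncomp = 2,
                       n_folds = 6, seed = 2)
  calls <- ifelse(cv$cv_scores > 0.5, "case", "control")
  expect_gt(mean(calls == as.character(sim$metadata$class)), 0.8)
})

test_that("PCA matches an independent eigendecomposition and its invariances", {
  inst <- make_instance(10, 6, seed = 31)
  pca <- fit_pca(inst$x, ncomp = 3)
  ev <- eigen(cov(inst$x), symmetric = TRUE)$values
  expect_equal(pca$explained, ev / sum(ev), tolerance = 1e-10)
  # rank-1 matrix: first component explains everything
  r1 <- outer(rnorm(8), rnorm(5)) + 5
  pca1 <- fit_pca(r1, ncomp = 1)
  expect_equal(pca1$explained[1], 1, tolerance = 1e-10)
  # column permutation leaves the spectrum unchanged
  perm <- fit_pca(inst$x[, c(4, 2, 6, 1, 3, 5)], ncomp = 2)
  expect_equal(pca$explained, perm$explained, tolerance = 1e-10)
  expect_error(fit_pca(inst$x, ncomp = 10), "rank")
})

test_that("models serialize to JSON and reload exactly", {
  inst <- make_instance(10, 12, seed = 37, effect = 1)
  fit <- ocpls2da(inst$x, inst$labels,
                  constraints = matrix(rnorm(10), ncol = 1), ncomp = 2)
  path <- tempfile(fileext = ".json")
  write_model_json(fit, path)
  back <- read_model_json(path)
  expect_equal(predict(back, inst$x), predict(fit, inst$x), tolerance = 1e-12)
  expect_equal(back$R2, fit$R2, tolerance = 1e-12)
  expect_identical(back$A_pred, fit$A_pred)
})
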