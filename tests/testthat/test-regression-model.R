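test_that("fit on a complete panel matches the closed form with R2 = 1", {
  panel <- complete_panel(n = 40, seed = 9)
  res <- evaluate_panel(panel$germination, panel$endpoints, model = "fit")
  m <- res$model
  ex <- res$extremes
  rng <- ex$max - ex$min
  # mean MFV is affine in the STIs, so OLS is exact:
  expect_equal(unname(m$coefficients), 1 / (7 * rng), tolerance = 1e-8)
  expect_equal(m$intercept, -sum(ex$min / (7 * rng)), tolerance = 1e-8)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)
  y <- predict_y(m, res$evaluation)
  expect_lte(max(abs(y - res$evaluation$mean_MFV)), 1e-10)
})

test_that("every trait minimum of 0 drives the intercept to numerical zero", {
  panel <- generate_panel(simulation_config(n_germplasms = 60), seed = 13)
  res <- evaluate_panel(panel$germination, panel$endpoints, model = "fit")
  # zero-filled non-germinating lines put the minimum of every STI at 0
  expect_true(all(res$extremes$min == 0))
  expect_lt(abs(res$model$intercept), 1e-12)
})

test_that("OLS residual optimum beats perturbed and random coefficient vectors", {
  panel <- complete_panel(n = 30, seed = 21)
  res <- evaluate_panel(panel$germination, panel$endpoints, model = "fit")
  X <- as.matrix(res$evaluation[paste0("STI_", trait_names())])
  y <- res$evaluation$mean_MFV
  rss <- function(beta, mu) sum((y - (X %*% beta + mu))^2)
  b0 <- res$model$coefficients
  mu0 <- res$model$intercept
  best <- rss(b0, mu0)
  set.seed(1)
  for (i in 1:50) {
    expect_gte(rss(b0 + rnorm(7, sd = 1e-3), mu0), best)
    expect_gte(rss(rnorm(7), rnorm(1)), best)  # brute-force random search
  }
})

test_that("rank deficiency and undersized panels are rejected by name", {
  X <- matrix(runif(12 * 7), 12, 7, dimnames = list(NULL, trait_names()))
  X[, "WC"] <- 0.5  # constant trait
  expect_error(fit_tolerance_model(X, rowMeans(X)), "WC")
  expect_error(fit_tolerance_model(X[1:8, ], rowMeans(X)[1:8]), "at least 9")
})

test_that("the published model reproduces the printed verification scores", {
  ex <- published_examples("sti")
  y <- predict_y(published_model(), ex)
  expect_true(all(abs(y - ex$Y) <= 5e-4))
  # all-zero profile scores the (numerically zero) intercept
  expect_equal(predict_y(published_model(), setNames(rep(0, 7), trait_names())),
               published_model()$intercept)
  expect_error(predict_y(published_model(),
                         setNames(c(NA, rep(0.5, 6)), trait_names())),
               "missing")
})

test_that("prediction is affine in the STI profile", {
  m <- published_model()
  set.seed(4)
  for (i in 1:20) {
    p1 <- setNames(runif(7, 0, 1.3), trait_names())
    p2 <- setNames(runif(7, 0, 1.3), trait_names())
    a <- runif(1)
    expect_equal(predict_y(m, a * p1 + (1 - a) * p2),
                 a * predict_y(m, p1) + (1 - a) * predict_y(m, p2))
  }
})

test_that("validation statistics summarise |Y - mean MFV| over a panel", {
  ex <- published_examples("sti")
  v <- validate_model(published_model(), ex, ex$mean_MFV)
  expect_equal(v$n, 15L)
  expect_lte(v$max, 0.003)  # printed rows carry 3-decimal input rounding
  expect_equal(v$mean, mean(abs(predict_y(published_model(), ex) - ex$mean_MFV)))
  expect_error(validate_model(published_model(), ex[0, ], numeric(0)), "empty")
})

test_that("correlation matrix matches a definitional oracle and is a valid PSD", {
  panel <- complete_panel(n = 25, seed = 17)
  res <- evaluate_panel(panel$germination, panel$endpoints)
  X <- as.matrix(res$evaluation[paste0("STI_", trait_names())])
  y <- res$evaluation$mean_MFV
  r <- correlation_matrix(res$sti, y)
  expect_equal(dim(r), c(8L, 8L))
  expect_equal(unname(diag(r)), rep(1, 8))
  expect_equal(r, t(r))
  expect_true(all(eigen(r, symmetric = TRUE, only.values = TRUE)$values > -1e-10))
  # brute-force covariance / (sd * sd) oracle
  Z <- cbind(X, y)
  for (i in 1:8) for (j in 1:8) {
    num <- mean((Z[, i] - mean(Z[, i])) * (Z[, j] - mean(Z[, j])))
    den <- sqrt(mean((Z[, i] - mean(Z[, i]))^2) * mean((Z[, j] - mean(Z[, j]))^2))
    expect_equal(unname(r[i, j]), num / den, tolerance = 1e-12)
  }
  Xconst <- X
  Xconst[, "STI_WC"] <- 1
  expect_error(correlation_matrix(Xconst, y), "zero-variance")
})

test_that("per-trait R2 equals squared correlation and flags strong traits", {
  panel <- complete_panel(n = 30, seed = 19)
  res <- evaluate_panel(panel$germination, panel$endpoints)
  y <- res$evaluation$mean_MFV
  r2 <- per_trait_r2(res$sti, y)
  r <- correlation_matrix(res$sti, y)
  expect_equal(unname(r2), unname(r[trait_names(), "mean_MFV"]^2))
  expect_true(all(r2 >= 0 & r2 <= 1))
  # a trait equal to the response has R2 exactly 1; an independent one ~ 0
  X <- as.matrix(res$evaluation[paste0("STI_", trait_names())])
  X[, "STI_GR"] <- y
  set.seed(33)
  X[, "STI_RL"] <- runif(nrow(X))
  r2b <- per_trait_r2(X, y)
  expect_equal(unname(r2b["GR"]), 1)
  expect_lt(r2b[["RL"]], 0.3)
})

test_that("standardized coefficients match a z-score refit and scaling invariance", {
  panel <- complete_panel(n = 35, seed = 23)
  res <- evaluate_panel(panel$germination, panel$endpoints, model = "fit")
  X <- as.matrix(res$evaluation[paste0("STI_", trait_names())])
  y <- res$evaluation$mean_MFV
  sb <- standardized_coefficients(res$model, res$sti, y)
  # oracle: refit on z-scored columns
  Z <- scale(X)
  refit <- lm(scale(y) ~ Z)
  expect_equal(unname(sb), unname(coef(refit)[-1]), tolerance = 1e-8)
  # scaling a trait changes its raw coefficient but not the standardized one
  X2 <- X; X2[, "STI_GI"] <- X[, "STI_GI"] * 10
  m2 <- fit_tolerance_model(X2, y)
  expect_equal(m2$coefficients[["GI"]], res$model$coefficients[["GI"]] / 10,
               tolerance = 1e-8)
  sb2 <- standardized_coefficients(m2, X2, y)
  expect_equal(sb2[["GI"]], sb[["GI"]], tolerance = 1e-8)
})
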