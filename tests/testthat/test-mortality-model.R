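test_that("the path head zeroes every coefficient", {
  set.seed(1)
  x <- matrix(rnorm(60 * 20), 60, 20)
  y <- rbinom(60, 1, 0.4)
  path <- fit_elastic_net_path(x, y, alpha_mix = 0.5)
  expect_true(all(path$beta[, 1] == 0))
  expect_true(any(path$beta[, length(path$lambdas)] != 0))
  xna <- x; xna[1, 1] <- NA
  expect_error(fit_elastic_net_path(xna, y), "non-finite")
})

test_that("lasso and ridge limits match closed forms on orthonormal
           designs", {
  n <- 40; p <- 10
  x <- orthonormal_design(n, p, seed = 4)
  set.seed(5)
  y <- rbinom(n, 1, 0.4)
  yc <- y - mean(y)
  b_ols <- as.vector(crossprod(x, yc) / n)
  for (lam in c(0.01, 0.05, 0.2)) {
    lasso <- fit_elastic_net_path(x, y, alpha_mix = 1, lambdas = lam)
    expect_equal(unname(lasso$beta[, 1]),
                 sign(b_ols) * pmax(abs(b_ols) - lam, 0),
                 tolerance = 1e-5)
    ridge <- fit_elastic_net_path(x, y, alpha_mix = 1e-8, lambdas = lam)
    expect_equal(unname(ridge$beta[, 1]), b_ols / (1 + lam),
                 tolerance = 1e-5)
  }
})

test_that("coordinate descent agrees with a generic convex optimizer", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 40; p <- 10
    x <- matrix(rnorm(n * p), n, p) %*%
      (diag(p) + 0.3 * matrix(runif(p * p), p, p)) # correlated design
    y <- rbinom(n, 1, 0.4)
    xs <- pop_standardize(x)
    yc <- y - mean(y)
    for (alpha in c(0.2, 0.5, 1.0)) {
      for (lam in c(0.02, 0.1)) {
        fit <- fit_elastic_net_path(x, y, alpha_mix = alpha,
                                    lambdas = lam)
        ref <- enet_optim_oracle(xs, yc, lam, alpha)
        expect_equal(unname(fit$beta[, 1]), ref, tolerance = 1e-5,
                     info = paste("seed", seed, "alpha", alpha,
                                  "lambda", lam))
      }
    }
  }
})

test_that("constant features are never selected", {
  set.seed(6)
  x <- cbind(matrix(rnorm(50 * 5), 50, 5), const = 7)
  y <- rbinom(50, 1, 0.5)
  path <- fit_elastic_net_path(x, y, 0.5)
  expect_true(all(path$beta[6, ] == 0))
})

test_that("cross-validation is deterministic and obeys the 1se rule", {
  set.seed(10)
  x <- matrix(rnorm(60 * 30), 60, 30)
  colnames(x) <- paste0("f", 1:30)
  y <- as.integer(x[, 1] + 0.5 * x[, 2] + rnorm(60, 0, 0.3) > 0)
  cm <- make_matrix(x, ifelse(y == 1, "NS", "S"))
  cv1 <- cross_validate(cm, 0.5, folds = 5, seed = 99)
  cv2 <- cross_validate(cm, 0.5, folds = 5, seed = 99)
  expect_identical(cv1, cv2)
  expect_gte(cv1$lambda_1se, cv1$lambda_min)
  i_min <- which(cv1$lambdas == cv1$lambda_min)
  expect_lte(cv1$error_1se, cv1$cv_error[i_min] + cv1$cv_se[i_min])
  expect_error(cross_validate(cm, 0.5, folds = 2), "folds")
})

test_that("separable outcomes reach zero cross-validated error and null
           labels track the majority-class rate", {
  set.seed(11)
  x <- matrix(rnorm(80 * 10), 80, 10)
  y <- rbinom(80, 1, 0.5)
  x[, 1] <- ifelse(y == 1, 1, -1) + rnorm(80, 0, 0.1) # wide margin
  cm <- make_matrix(x, ifelse(y == 1, "NS", "S"))
  cv <- cross_validate(cm, 0.5, folds = 5, seed = 1)
  expect_equal(cv$cv_error[which(cv$lambdas == cv$lambda_min)], 0)

  errs <- vapply(1:8, function(s) {
    set.seed(1000 + s)
    x <- matrix(rnorm(100 * 8), 100, 8)
    lab <- rep(c("NS", "S"), c(27, 73))[sample(100)]
    cm <- make_matrix(x, lab)
    cv <- cross_validate(cm, 0.5, folds = 5, seed = s)
    cv$cv_error[1] # at the grid head everything is intercept-only
  }, 0)
  expect_equal(mean(errs), 0.27, tolerance = 0.2)
})

test_that("VIF pruning removes collinear features until max VIF <= 5", {
  set.seed(12)
  n <- 200
  z <- rnorm(n)
  x <- cbind(a = z + rnorm(n, 0, 0.15), b = z + rnorm(n, 0, 0.15),
             c = z + rnorm(n, 0, 0.15), d = rnorm(n), e = rnorm(n))
  pr <- vif_prune(x, colnames(x))
  expect_lte(max(pr$vif), 5)
  expect_true(length(pr$removed) >= 1)
  expect_identical(sort(c(pr$kept, pr$removed)), sort(colnames(x)))

  # exact duplicates carry infinite VIF and one goes first
  x2 <- cbind(a = z, b = z, c = rnorm(n))
  pr2 <- vif_prune(x2, colnames(x2))
  expect_true("b" %in% pr2$removed) # later in order on the tie
  expect_false("b" %in% pr2$kept)
  expect_lte(max(pr2$vif), 5)

  # mutually orthogonal columns all keep VIF 1
  q <- orthonormal_design(50, 4, seed = 13)
  pr3 <- vif_prune(q, colnames(q))
  expect_equal(unname(pr3$vif), rep(1, 4), tolerance = 1e-8)
  expect_length(pr3$removed, 0)
})

test_that("rank AUC scores orderings correctly", {
  expect_equal(auc_rank(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auc_rank(c(0.2, 0.3, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_equal(auc_rank(c(0.5, 0.5, 0.5, 0.5), c(1, 1, 0, 0)), 0.5)
  expect_equal(auc_rank(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
})

test_that("the final refit reports coefficients, MSE and fold AUCs", {
  set.seed(14)
  x <- matrix(rnorm(60 * 4), 60, 4)
  colnames(x) <- c("f1", "f2", "f3", "f4")
  y <- as.integer(x[, 1] - x[, 2] + rnorm(60, 0, 0.1) > 0)
  cm <- make_matrix(x, ifelse(y == 1, "NS", "S"))
  rep <- finalize_model(cm, c("f1", "f2"), seed = 2)
  expect_length(rep$auc_folds, 5)
  expect_gte(rep$auc_mean, 0.9) # nearly separable
  expect_equal(rep$mse,
               mean(lm(y ~ x[, 1] + x[, 2])$residuals^2))
  expect_error(finalize_model(cm, character()), "kept_features")
  tiny <- make_matrix(x[1:4, , drop = FALSE], c("S", "NS", "S", "NS"))
  expect_error(finalize_model(tiny, colnames(x)), "more patients")
})

test_that("the full model build recovers strong planted effects", {
  gen <- generate_cohort(cohort_spec(n_patients = 73, seed = 20))
  fvs <- lapply(seq_along(gen$records), function(i) {
    extract_features(gen$records[[i]], gen$truth$truth$true_onset_h[i])
  })
  cm <- assemble_matrix(fvs)
  model <- build_mortality_model(cm, seed = 20)
  expect_lte(max(model$vif), 5)
  expect_true(all(model$selected_features %in% model$enet_features))
  expect_gte(model$auc_mean, 0.8)
  expect_true(is.finite(model$mse))
  # deterministic end to end
  model2 <- build_mortality_model(cm, seed = 20)
  expect_identical(model$coefficients, model2$coefficients)
  expect_identical(model$auc_folds, model2$auc_folds)
})
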