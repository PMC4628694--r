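# Elastic-net mortality model: penalized linear regression on the 0/1
# seven-day mortality label, k-fold cross-validation with the
# one-standard-error rule, iterative VIF pruning, unpenalized refit and
# cross-validated AUC.

standardize_columns <- function(x) {
  center <- colMeans(x)
  xc <- sweep(x, 2L, center)
  scale <- sqrt(colMeans(xc^2)) # population sd, as in coordinate descent
  ok <- scale > 0
  xs <- xc
  xs[, ok] <- sweep(xc[, ok, drop = FALSE], 2L, scale[ok], `/`)
  xs[, !ok] <- 0
  list(x = xs, center = center, scale = ifelse(ok, scale, 1),
       constant = !ok)
}

run_rng <- function(seed, expr) {
  # evaluate expr with a private RNG stream; caller's stream untouched
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Fit an elastic-net regularization path
#'
#' Penalized linear regression of the 0/1 outcome on standardized
#' features by cyclic coordinate descent with soft-thresholding and
#' warm starts. The objective at penalty `lambda` with mixing weight
#' `alpha_mix` is `(1/2n) RSS + lambda (alpha_mix |b|_1 +
#' (1 - alpha_mix)/2 |b|_2^2)`. The default grid has `nlambda`
#' log-spaced values from `lambda_max` (the smallest penalty zeroing
#' every coefficient) down to `lambda_min_ratio * lambda_max`.
#' Constant features are never selected.
#'
#' @param x Numeric matrix (patients x features), no missing values.
#' @param y Numeric 0/1 outcome (1 = nonsurvivor).
#' @param alpha_mix L1 mixing weight in (0, 1]; default 0.5.
#' @param lambdas Optional decreasing penalty grid; computed if `NULL`.
#' @param nlambda,lambda_min_ratio Grid shape when `lambdas` is `NULL`.
#' @param tol Convergence threshold on the largest coefficient change.
#' @param maxit Maximum coordinate-descent sweeps per lambda.
#' @return A list of class `enet_path`: `lambdas`, `beta`
#'   (standardized-scale coefficients, p x L), `beta_raw`
#'   (original-scale), `intercepts` (original-scale), `alpha_mix`,
#'   `feature_names`, and the standardization used.
#' @export
fit_elastic_net_path <- function(x, y, alpha_mix = 0.5, lambdas = NULL,
                                 nlambda = 100L, lambda_min_ratio = 1e-4,
                                 tol = 1e-7, maxit = 100000L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), nrow(x) >= 2L,
            alpha_mix > 0, alpha_mix <= 1)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite entries in the design or outcome", call. = FALSE)
  }
  n <- nrow(x)
  std <- standardize_columns(x)
  yc <- y - mean(y)
  if (is.null(lambdas)) {
    lambda_max <- max(abs(crossprod(std$x, yc)) / n) / alpha_mix
    if (lambda_max <= 0) lambda_max <- 1e-3
    lambdas <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                       length.out = nlambda))
  } else {
    stopifnot(all(diff(lambdas) < 0))
  }
  xss <- ifelse(std$constant, 0, 1)
  beta <- enet_path_cpp(std$x, yc, xss, lambdas, alpha_mix, tol,
                        as.integer(maxit))
  beta_raw <- beta / std$scale
  intercepts <- mean(y) - as.vector(crossprod(beta_raw, std$center))
  fn <- colnames(x)
  if (is.null(fn)) fn <- paste0("x", seq_len(ncol(x)))
  rownames(beta) <- rownames(beta_raw) <- fn
  structure(list(lambdas = lambdas, beta = beta, beta_raw = beta_raw,
                 intercepts = intercepts, alpha_mix = alpha_mix,
                 feature_names = fn, x_center = std$center,
                 x_scale = std$scale, constant = std$constant),
            class = "enet_path")
}

#' Predict from an elastic-net path
#'
#' @param object An `enet_path`.
#' @param newx Matrix with the same columns as the training design.
#' @param ... Unused.
#' @return Matrix of linear predictions, rows = patients, columns =
#'   lambdas.
#' @export
predict.enet_path <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  sweep(newx %*% object$beta_raw, 2L, object$intercepts, `+`)
}

stratified_folds <- function(labels, k) {
  # returns integer fold id per observation; each class dealt
  # round-robin after a seeded shuffle (caller controls the RNG)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      stop("class ", cl, " has fewer members (", length(idx),
           ") than folds (", k, ")", call. = FALSE)
    }
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validate the elastic net over its penalty grid
#'
#' Stratified k-fold cross-validation of the misclassification error
#' obtained by thresholding the linear prediction at 0.5. Fold-wise
#' models are trained with standardization computed on the training
#' portion only. `lambda_min` is the penalty with the lowest mean
#' error (largest such penalty on ties) and `lambda_1se` the largest
#' penalty whose error is within one standard error of that minimum.
#'
#' @param matrix A [assemble_matrix()] result.
#' @param alpha_mix L1 mixing weight.
#' @param folds Number of folds (3, 4 or 5).
#' @param seed Integer seed controlling the fold split.
#' @param nlambda,lambda_min_ratio Grid shape (shared across folds,
#'   computed from the full data).
#' @return A list of class `cv_curve`: `lambdas`, `cv_error`, `cv_se`,
#'   `lambda_min`, `lambda_1se`, `error_min`, `error_1se`, `folds`,
#'   `alpha_mix`, `seed`.
#' @export
cross_validate <- function(matrix, alpha_mix = 0.5, folds = 5L, seed = 1L,
                           nlambda = 100L, lambda_min_ratio = 1e-4) {
  stopifnot(inherits(matrix, "cohort_matrix"), folds %in% 3:5)
  x <- matrix$x
  y <- as.numeric(matrix$labels == "NS")
  full <- fit_elastic_net_path(x, y, alpha_mix, nlambda = nlambda,
                               lambda_min_ratio = lambda_min_ratio)
  lambdas <- full$lambdas
  fold_id <- run_rng(seed, stratified_folds(matrix$labels, folds))
  errs <- t(vapply(seq_len(folds), function(k) {
    tr <- fold_id != k
    fit <- fit_elastic_net_path(x[tr, , drop = FALSE], y[tr], alpha_mix,
                                lambdas = lambdas)
    pred <- predict(fit, x[!tr, , drop = FALSE])
    colMeans((pred >= 0.5) != y[!tr])
  }, numeric(length(lambdas))))
  cv_error <- colMeans(errs)
  cv_se <- apply(errs, 2L, sd) / sqrt(folds)
  i_min <- which(cv_error == min(cv_error))[1L] # grid decreasing: first
  thr <- cv_error[i_min] + cv_se[i_min]
  i_1se <- which(cv_error <= thr)[1L]
  structure(list(lambdas = lambdas, cv_error = cv_error, cv_se = cv_se,
                 lambda_min = lambdas[i_min],
                 lambda_1se = lambdas[i_1se],
                 error_min = cv_error[i_min],
                 error_1se = cv_error[i_1se],
                 folds = folds, alpha_mix = alpha_mix, seed = seed,
                 path = full),
            class = "cv_curve")
}

#' Features selected at a penalty value
#'
#' @param path An `enet_path`.
#' @param lambda Penalty at which to read off the active set (matched
#'   to the nearest grid point).
#' @return Character vector of features with nonzero coefficients.
#' @export
selected_features <- function(path, lambda) {
  stopifnot(inherits(path, "enet_path"))
  l <- which.min(abs(path$lambdas - lambda))
  path$feature_names[path$beta[, l] != 0]
}

vif_values <- function(x) {
  # VIF_j = 1/(1 - R^2_j) of feature j regressed on the others
  p <- ncol(x)
  if (p == 1L) return(setNames(1, colnames(x)))
  std <- standardize_columns(x)
  xs <- std$x
  vif <- numeric(p)
  for (j in seq_len(p)) {
    yj <- xs[, j]
    if (std$constant[j]) { vif[j] <- 1; next }
    xo <- cbind(1, xs[, -j, drop = FALSE])
    fit <- stats::lm.fit(xo, yj)
    rss <- sum(fit$residuals^2)
    tss <- sum(yj^2) # standardized: mean 0
    r2 <- 1 - rss / tss
    vif[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  setNames(vif, colnames(x))
}

#' Iterative variance-inflation-factor pruning
#'
#' Repeatedly computes VIF for every feature in the working set and
#' removes the single feature with the largest VIF while the maximum
#' exceeds `threshold`; exactly collinear features have infinite VIF
#' and go first. Ties are broken by removing the feature appearing
#' later in the supplied order.
#'
#' @param x Imputed numeric matrix with named columns.
#' @param features Character vector of features to consider.
#' @param threshold VIF threshold (default 5).
#' @return List: `kept` (features, original order), `removed` (in
#'   removal order), `vif` (final VIF map over kept features).
#' @export
vif_prune <- function(x, features, threshold = 5) {
  stopifnot(length(features) >= 1L, all(features %in% colnames(x)))
  keep <- features
  removed <- character()
  repeat {
    vif <- vif_values(x[, keep, drop = FALSE])
    if (length(keep) == 1L || max(vif) <= threshold) break
    worst <- which(vif == max(vif))
    drop_j <- worst[length(worst)] # later in canonical order on ties
    removed <- c(removed, keep[drop_j])
    keep <- keep[-drop_j]
  }
  list(kept = keep, removed = removed,
       vif = vif_values(x[, keep, drop = FALSE]))
}

#' Rank-based (trapezoidal) AUC
#'
#' Area under the ROC curve computed from ranks (Mann-Whitney
#' statistic), with midranks for tied scores; equivalent to the
#' trapezoidal area.
#'
#' @param scores Numeric risk scores (higher = more likely positive).
#' @param labels 0/1 (or logical) outcome.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Refit the selected features and evaluate by cross-validated AUC
#'
#' Fits an unpenalized least-squares model of the 0/1 label on the
#' kept features, reports original-scale coefficients and in-sample
#' mean squared error, and evaluates discrimination by stratified
#' k-fold cross-validation: each fold's held-out linear predictions
#' are scored by rank-based AUC, reported as mean and standard
#' deviation over folds.
#'
#' @param matrix A [assemble_matrix()] result.
#' @param kept_features Non-empty character vector of feature names.
#' @param seed Integer seed for the fold split.
#' @param cv_folds Number of evaluation folds (default 5).
#' @return A list of class `model_report`: `selected_features`,
#'   `coefficients` (named, incl. `(Intercept)`), `mse`, `auc_mean`,
#'   `auc_sd`, `auc_folds` (per-fold values), `cv_folds`, `seed`.
#' @export
finalize_model <- function(matrix, kept_features, seed = 1L,
                           cv_folds = 5L) {
  stopifnot(inherits(matrix, "cohort_matrix"),
            length(kept_features) >= 1L)
  x <- matrix$x[, kept_features, drop = FALSE]
  y <- as.numeric(matrix$labels == "NS")
  if (nrow(x) <= ncol(x)) {
    stop("need more patients (", nrow(x), ") than kept features (",
         ncol(x), ") for the unpenalized refit", call. = FALSE)
  }
  df <- data.frame(y = y, x, check.names = FALSE)
  fit <- lm(y ~ ., data = df)
  mse <- mean(fit$residuals^2)
  fold_id <- run_rng(seed, stratified_folds(matrix$labels, cv_folds))
  aucs <- vapply(seq_len(cv_folds), function(k) {
    tr <- fold_id != k
    f <- lm(y ~ ., data = df[tr, , drop = FALSE])
    pr <- predict(f, newdata = df[!tr, , drop = FALSE])
    auc_rank(pr, y[!tr])
  }, 0)
  structure(list(selected_features = kept_features,
                 coefficients = coef(fit), mse = mse,
                 auc_mean = mean(aucs), auc_sd = sd(aucs),
                 auc_folds = aucs, cv_folds = cv_folds, seed = seed),
            class = "model_report")
}

#' Build the full 7-day mortality model
#'
#' End-to-end model construction: elastic-net paths are
#' cross-validated at each requested fold count, the fold count whose
#' one-standard-error model has the lowest cross-validated error is
#' chosen (ties to more folds), the features active at its
#' `lambda_1se` are pruned by iterative VIF, and the pruned set is
#' refit and evaluated with [finalize_model()]. If the
#' one-standard-error penalty selects no feature, the selection falls
#' back to `lambda_min`.
#'
#' @param matrix A [assemble_matrix()] result.
#' @param alpha_mix L1 mixing weight (default 0.5).
#' @param fold_counts Fold counts to try (default 3, 4, 5).
#' @param seed Integer seed.
#' @param vif_threshold VIF threshold (default 5).
#' @param eval_folds Folds for the AUC evaluation (default 5).
#' @return A `model_report` with additional fields: `vif`,
#'   `removed_by_vif`, `cv_curves` (one `cv_curve` per fold count),
#'   `chosen_folds`, `enet_features` (pre-pruning selection),
#'   `alpha_mix`.
#' @export
build_mortality_model <- function(matrix, alpha_mix = 0.5,
                                  fold_counts = c(3L, 4L, 5L), seed = 1L,
                                  vif_threshold = 5, eval_folds = 5L) {
  stopifnot(inherits(matrix, "cohort_matrix"))
  curves <- lapply(fold_counts, function(k) {
    cross_validate(matrix, alpha_mix, folds = k, seed = seed + k)
  })
  names(curves) <- paste0("folds_", fold_counts)
  err <- vapply(curves, `[[`, 0, "error_1se")
  best <- max(which(err == min(err))) # ties to larger fold count
  curve <- curves[[best]]
  sel <- selected_features(curve$path, curve$lambda_1se)
  if (!length(sel)) sel <- selected_features(curve$path, curve$lambda_min)
  if (!length(sel)) {
    stop("elastic net selected no features at lambda_1se or lambda_min",
         call. = FALSE)
  }
  pr <- vif_prune(matrix$x, sel, threshold = vif_threshold)
  rep <- finalize_model(matrix, pr$kept, seed = seed,
                        cv_folds = eval_folds)
  rep$vif <- pr$vif
  rep$removed_by_vif <- pr$removed
  rep$cv_curves <- curves
  rep$chosen_folds <- fold_counts[best]
  rep$enet_features <- sel
  rep$alpha_mix <- alpha_mix
  rep
}

#' @export
print.model_report <- function(x, ...) {
  cat("<model_report> ", length(x$selected_features),
      " features; MSE ", format(round(x$mse, 4)),
      "; AUC ", format(round(x$auc_mean, 3)), " +/- ",
      format(round(x$auc_sd, 3)), "\n", sep = "")
  invisible(x)
}
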