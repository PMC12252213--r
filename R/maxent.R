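#' Maximum-entropy model parameters
#'
#' @param feature_classes Feature classes; default linear + quadratic + hinge.
#' @param beta_multiplier Global multiplier on the L1 penalty; each feature's
#'   penalty is `beta_multiplier * s_j / sqrt(m)` where `s_j` is the feature's
#'   standard deviation over the presences (floored at 1e-3) and `m` the
#'   presence count. Default 1.
#' @param background_n Background sample size, default 10000.
#' @param max_iter Maximum coordinate-descent sweeps, default 20000.
#' @param tol Convergence tolerance on the objective change per cycle,
#'   default 1e-7.
#' @param transform Output transform: `"cloglog"` (default), `"logistic"` or
#'   `"raw"`.
#' @param clamp Clamp projections to the training range (default `TRUE`).
#' @param folds Cross-validation replicates `k`, default 10.
#' @param n_knots Hinge/threshold knots per variable, default 15.
#' @param seed Seed for background sampling, fold assignment and permutation.
#' @return List of class `maxent_params`.
#' @export
maxent_params <- function(feature_classes = c("linear", "quadratic", "hinge"),
                          beta_multiplier = 1, background_n = 10000,
                          max_iter = 20000, tol = 1e-7,
                          transform = c("cloglog", "logistic", "raw"),
                          clamp = TRUE, folds = 10, n_knots = 15,
                          seed = NULL) {
  transform <- match.arg(transform)
  if (beta_multiplier < 0)
    abort("beta_multiplier must be >= 0", class = "nichetrack_config_error")
  if (background_n < 2)
    abort("background_n must be >= 2", class = "nichetrack_config_error")
  if (folds < 1)
    abort("folds must be >= 1", class = "nichetrack_config_error")
  structure(list(feature_classes = feature_classes,
                 beta_multiplier = beta_multiplier,
                 background_n = background_n, max_iter = max_iter, tol = tol,
                 transform = transform, clamp = clamp, folds = folds,
                 n_knots = n_knots, seed = seed),
            class = "maxent_params")
}

#' Sample background cells from a stack
#'
#' Uniform sample (without replacement) of distinct non-nodata cells inside
#' the mask, reproducible under `seed`. If fewer cells are available than
#' requested, all cells are returned with a warning.
#'
#' @param stack `sdm_stack`.
#' @param n Requested background size.
#' @param seed Seed; `NULL` uses the current RNG state.
#' @return Tibble of background cells with coordinates and layer values.
#' @export
sample_background <- function(stack, n = 10000, seed = NULL) {
  cl <- cells(stack)
  keep <- rowSums(is.na(as.matrix(cl[stack_names(stack)]))) == 0
  cl <- cl[keep, , drop = FALSE]
  if (nrow(cl) == 0L)
    abort("no usable background cells (empty mask?)",
          class = "nichetrack_data_error")
  if (nrow(cl) <= n) {
    if (nrow(cl) < n)
      warn(sprintf("only %d background cells available (requested %d); using all",
                   nrow(cl), n))
    return(cl)
  }
  idx <- with_seed_(seed, sample.int(nrow(cl), n))
  cl[sort(idx), , drop = FALSE]
}

# Mann-Whitney objective pieces shared by fit/predict
logsumexp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

#' Fit an L1-regularized maximum-entropy model
#'
#' Minimizes the convex objective
#' `-(1/m) sum_presence lambda.f(x) + log((1/B) sum_background exp(lambda.f(x)))
#'  + sum_j beta_j |lambda_j|`
#' by cyclic coordinate descent with soft-thresholded Newton steps (compiled
#' core). The fitted Gibbs density over the background,
#' `raw(x) = exp(lambda.f(x)) / Z`, sums to 1 over the background sample.
#' Per-feature gain increments are recorded during training for
#' percent-contribution accounting.
#'
#' @param presence_values Tibble of environmental values at presence points.
#' @param background_values Tibble of environmental values at background
#'   cells (same variables).
#' @param params [maxent_params()].
#' @param expansion Optional pre-built [feature_expansion()]; by default one
#'   is built from `background_values`.
#' @param vars Optional character vector restricting the variables used.
#' @return Object of class `maxent_model`: feature weights `lambda`,
#'   normalizer `log_z`, entropy `entropy` of the fitted background
#'   distribution, regularized training gain `gain`, the expansion, and
#'   training metadata.
#' @export
maxent_fit <- function(presence_values, background_values,
                       params = maxent_params(), expansion = NULL,
                       vars = NULL) {
  if (is.null(expansion))
    expansion <- feature_expansion(background_values,
                                   classes = params$feature_classes,
                                   n_knots = params$n_knots, vars = vars)
  Xp <- build_features(presence_values, expansion, clamp = TRUE)
  Xb <- build_features(background_values, expansion, clamp = TRUE)
  m <- nrow(Xp); B <- nrow(Xb)
  if (m < 2) abort("need at least 2 presences", class = "nichetrack_data_error")
  if (B < 2) abort("need at least 2 background points",
                   class = "nichetrack_data_error")
  pbar <- colMeans(Xp)
  s <- pmax(apply(Xp, 2, sd), 1e-3)
  beta <- params$beta_multiplier * s / sqrt(m)
  sol <- maxent_cd_solver(Xb, pbar, beta, params$tol, params$max_iter)
  if (!sol$converged)
    abort(sprintf("maxent fit did not converge in %d cycles (objective delta %.3g)",
                  params$max_iter, sol$final_delta),
          class = "nichetrack_convergence_error")
  lambda <- setNames(sol$lambda, colnames(Xb))
  eta_b <- drop(Xb %*% lambda)
  log_z <- logsumexp(eta_b)
  p <- exp(eta_b - log_z)
  entropy <- log_z - sum(p * eta_b)
  model <- structure(list(
    lambda = lambda, expansion = expansion, beta = beta,
    log_z = log_z, entropy = entropy, gain = sol$gain,
    reg_gain = -sol$objective,
    gain_increments = setNames(sol$gain_increments, colnames(Xb)),
    objective = sol$objective, cycles = sol$cycles,
    params = params, n_presence = m, n_background = B,
    bg_means = setNames(expansion$vars$mean, expansion$vars$variable)),
    class = "maxent_model")
  model$train_auc <- auc_score(predict(model, presence_values, "raw"),
                               exp(eta_b - log_z))
  model
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(paste0("<maxent_model> %d features over %d variables, ",
                     "%d presences vs %d background\n",
                     "  gain %.4f, entropy %.4f, training AUC %.3f\n"),
              length(x$lambda), nrow(x$expansion$vars), x$n_presence,
              x$n_background, x$gain, x$entropy, x$train_auc))
  invisible(x)
}

#' Variables entering a fitted model
#' @param model A `maxent_model`.
#' @return Character vector of variable names.
#' @export
model_variables <- function(model) model$expansion$vars$variable

#' Predict suitability from a fitted model
#'
#' `raw` is the Gibbs density `exp(lambda.f(x)) / Z` (sums to 1 over the
#' training background); `logistic` is `e^H r / (1 + e^H r)` and `cloglog` is
#' `1 - exp(-e^H r)`, where `H` is the entropy of the fitted background
#' distribution. All three transforms are strictly increasing in `raw`, so
#' cell rankings agree.
#'
#' @param object A `maxent_model`.
#' @param newdata Tibble of environmental values, or an `sdm_stack` (nodata
#'   propagates as `NA` and masked cells stay nodata).
#' @param transform `"cloglog"`, `"logistic"` or `"raw"`; defaults to the
#'   fitting parameters.
#' @param clamp Override the clamping flag for this projection.
#' @param ... Unused.
#' @return Numeric vector (tibble input) or `sdm_raster` (stack input).
#' @export
predict.maxent_model <- function(object, newdata, transform = NULL,
                                 clamp = NULL, ...) {
  transform <- transform %||% object$params$transform
  clamp <- clamp %||% object$params$clamp
  if (inherits(newdata, "sdm_stack")) {
    missing <- setdiff(model_variables(object), stack_names(newdata))
    if (length(missing))
      abort(paste0("projection stack lacks variable(s): ",
                   paste(missing, collapse = ", ")),
            class = "nichetrack_data_error")
    cl <- cells(newdata)
    ok <- rowSums(is.na(as.matrix(cl[model_variables(object)]))) == 0
    pred <- rep(NA_real_, nrow(cl))
    if (any(ok))
      pred[ok] <- predict(object, cl[ok, , drop = FALSE], transform, clamp)
    cl$suitability <- pred
    return(raster_from_cells(cl, newdata$spec, "suitability", "suitability"))
  }
  X <- build_features(newdata, object$expansion, clamp = clamp)
  eta <- drop(X %*% object$lambda)
  raw <- exp(eta - object$log_z)
  switch(transform,
         raw = raw,
         logistic = { eh <- exp(object$entropy) * raw; eh / (1 + eh) },
         cloglog = -expm1(-exp(object$entropy) * raw))
}

#' Rank-based AUC (Mann-Whitney estimator, ties count one half)
#'
#' @param presence_scores,background_scores Numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(presence_scores, background_scores) {
  m <- length(presence_scores); B <- length(background_scores)
  if (m == 0L || B == 0L)
    abort("both score vectors must be nonempty", class = "nichetrack_data_error")
  r <- rank(c(presence_scores, background_scores), ties.method = "average")
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * B)
}

#' Accuracy band of an AUC value
#'
#' Bands: `(0.9, 1]` very high, `(0.8, 0.9]` good, `(0.7, 0.8]` average,
#' `(0.6, 0.7]` poor, `[0.5, 0.6]` failure, below 0.5 worse than random.
#'
#' @param value AUC in `[0, 1]`.
#' @return Character scalar naming the band.
#' @export
classify_auc <- function(value) {
  if (value < 0 || value > 1)
    abort("AUC must lie in [0, 1]", class = "nichetrack_data_error")
  if (value < 0.5) return("worse_than_random")
  if (value <= 0.6) return("failure")
  if (value <= 0.7) return("poor")
  if (value <= 0.8) return("average")
  if (value <= 0.9) return("good")
  "very_high"
}

#' k-fold cross-validated maximum-entropy fit
#'
#' Presences are partitioned into `k` seeded folds; each replicate fits on
#' the other `k - 1` folds and scores test AUC on the held-out fold against
#' the shared background sample. `k = 1` degenerates to a single fit on all
#' presences (its test AUC is then the training AUC). The combined
#' suitability raster, when a `stack` is supplied, is the arithmetic mean of
#' the per-fold rasters.
#'
#' @param presence_values Tibble of environmental values at presences.
#' @param background_values Tibble of background values (shared by folds).
#' @param params [maxent_params()]; `folds` and `seed` control the partition.
#' @param stack Optional `sdm_stack` to project each fold onto.
#' @return Object of class `maxent_cv`: `models` (list), `eval` (per-fold
#'   tibble with train/test AUC), `mean_raster` (or `NULL`).
#' @export
maxent_cv <- function(presence_values, background_values,
                      params = maxent_params(), stack = NULL) {
  m <- nrow(presence_values)
  k <- params$folds
  if (m < k)
    abort(sprintf("%d presences cannot fill %d folds; use smaller k", m, k),
          class = "nichetrack_data_error")
  fold_id <- if (k == 1L) rep(1L, m) else
    with_seed_(params$seed, sample(rep_len(seq_len(k), m)))
  if (any(tabulate(fold_id, k) == 0L))
    abort("a fold received 0 presences; use smaller k",
          class = "nichetrack_data_error")
  expansion <- feature_expansion(background_values,
                                 classes = params$feature_classes,
                                 n_knots = params$n_knots)
  models <- vector("list", k)
  evals <- vector("list", k)
  rasters <- vector("list", k)
  for (f in seq_len(k)) {
    train <- if (k == 1L) presence_values else
      presence_values[fold_id != f, , drop = FALSE]
    test <- presence_values[fold_id == f, , drop = FALSE]
    fit <- maxent_fit(train, background_values, params, expansion = expansion)
    fit$fold <- f
    bg_raw <- predict(fit, background_values, "raw")
    test_auc <- auc_score(predict(fit, test, "raw"), bg_raw)
    evals[[f]] <- tibble(fold = f, train_auc = fit$train_auc,
                         test_auc = test_auc, gain = fit$gain)
    models[[f]] <- fit
    if (!is.null(stack)) rasters[[f]] <- predict(fit, stack)
  }
  eval_tbl <- bind_rows(evals)
  mean_raster <- NULL
  if (!is.null(stack)) {
    acc <- rasters[[1]]$values
    if (k > 1) for (f in 2:k) acc <- acc + rasters[[f]]$values
    mean_raster <- new_raster(acc / k, stack$spec, "suitability_mean")
  }
  structure(list(models = models, eval = eval_tbl, mean_raster = mean_raster,
                 fold_id = fold_id, params = params),
            class = "maxent_cv")
}

#' @export
print.maxent_cv <- function(x, ...) {
  cat(sprintf("<maxent_cv> %d folds: mean test AUC %.3f (sd %.3f), mean train AUC %.3f\n",
              nrow(x$eval), mean(x$eval$test_auc), sd(x$eval$test_auc),
              mean(x$eval$train_auc)))
  invisible(x)
}

#' Project a cross-validated model onto a stack
#'
#' Arithmetic mean of the per-fold suitability rasters.
#'
#' @param object A `maxent_cv`.
#' @param newdata An `sdm_stack`.
#' @param transform,clamp Passed to each fold's [predict.maxent_model()].
#' @param ... Unused.
#' @return `sdm_raster` of mean suitability.
#' @export
predict.maxent_cv <- function(object, newdata, transform = NULL, clamp = NULL,
                              ...) {
  preds <- map(object$models, predict, newdata = newdata,
               transform = transform, clamp = clamp)
  acc <- preds[[1]]$values
  if (length(preds) > 1)
    for (f in 2:length(preds)) acc <- acc + preds[[f]]$values
  new_raster(acc / length(preds), newdata$spec, "suitability_mean")
}
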