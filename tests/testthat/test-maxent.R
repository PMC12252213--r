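test_that("background sampling is seeded, saturating and near-uniform", {
  st <- toy_stack(4, 5)
  s1 <- sample_background(st, 10, seed = 1)
  s2 <- sample_background(st, 10, seed = 1)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 10L)
  expect_warning(all_cells <- sample_background(st, 50, seed = 1),
                 "available")
  expect_equal(nrow(all_cells), 20L)

  # frequency of each of 4 cells over 200 seeded draws of B = 1
  st4 <- assemble_stack(list(toy_raster(2, 2, name = "a")))
  draws <- vapply(1:200, function(s) {
    b <- sample_background(st4, 1, seed = s)
    paste(b$row, b$col)
  }, character(1))
  freqs <- table(draws) / 200
  expect_equal(length(freqs), 4L)
  expect_true(all(abs(freqs - 0.25) < 0.1))
})

test_that("feature construction scales, kinks and clamps as documented", {
  bg <- tibble::tibble(x = c(0, 2, 4, 6, 8, 10))
  ex <- feature_expansion(bg, classes = c("linear", "quadratic", "hinge"),
                          n_knots = 3)
  X <- build_features(bg, ex)
  expect_true(all(X >= 0 & X <= 1))
  expect_equal(X[1, "linear:x"], 0, ignore_attr = TRUE)
  expect_equal(X[6, "linear:x"], 1, ignore_attr = TRUE)
  expect_equal(X[, "quadratic:x"], (bg$x / 10)^2, ignore_attr = TRUE)
  # forward hinge: 0 at its knot, 1 at the max
  hid <- grep("^hinge:", colnames(X), value = TRUE)[1]
  k <- ex$features$knot[match(hid, ex$features$id)]
  at_knot <- build_features(tibble::tibble(x = k * 10), ex)
  expect_equal(at_knot[, hid], 0, ignore_attr = TRUE)
  expect_equal(X[6, hid], 1, ignore_attr = TRUE)
  # clamped projection: beyond-range value = same features as the extreme
  over <- build_features(tibble::tibble(x = 15), ex, clamp = TRUE)
  expect_equal(over, build_features(tibble::tibble(x = 10), ex),
               ignore_attr = TRUE)
  expect_error(feature_expansion(bg, classes = "splines"),
               "unknown feature class", class = "nichetrack_config_error")
})

test_that("uniform presences give a null model; raw output normalizes", {
  withr::with_seed(11, {
    bg <- tibble::tibble(x = runif(400, 0, 1), z = runif(400, 0, 1))
    pres <- bg # the exact background measure: no signal at all
    fit <- maxent_fit(pres, bg, maxent_params(folds = 1))
    expect_lt(max(abs(fit$lambda)), 1e-3)
    expect_lt(fit$gain, 1e-3)
    expect_equal(sum(predict(fit, bg, "raw")), 1, tolerance = 1e-9)
  })
})

test_that("beta=0 linear fit moment-matches and agrees with a BFGS oracle", {
  # 50-cell toy problem
  withr::with_seed(21, {
    bg <- tibble::tibble(x = runif(50, 0, 2), z = runif(50, -1, 1))
    pres <- tibble::tibble(x = runif(25, 1.2, 2), z = runif(25, -1, 1))
  })
  params <- maxent_params(feature_classes = "linear", beta_multiplier = 0,
                          tol = 1e-12)
  fit <- maxent_fit(pres, bg, params)
  Xb <- build_features(bg, fit$expansion)
  Xp <- build_features(pres, fit$expansion)
  w <- predict(fit, bg, "raw")
  # KKT moment matching: fitted feature expectations = presence means
  expect_equal(drop(w %*% Xb), colMeans(Xp), tolerance = 1e-6)

  # independent convex-solver oracle on the same objective
  obj <- function(l) {
    eta <- drop(Xb %*% l)
    -mean(Xp %*% l) + log(mean(exp(eta)))
  }
  o <- optim(rep(0, ncol(Xb)), obj, method = "BFGS",
             control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(obj(fit$lambda), o$value, tolerance = 1e-6)
  expect_equal(fit$objective, o$value, tolerance = 1e-6)
})

test_that("fit is invariant to duplicating the background sample", {
  withr::with_seed(13, {
    bg <- tibble::tibble(x = runif(120, 0, 1))
    pres <- tibble::tibble(x = runif(30, 0.5, 1))
  })
  params <- maxent_params(feature_classes = c("linear", "quadratic"),
                          tol = 1e-10)
  f1 <- maxent_fit(pres, bg, params)
  ex <- f1$expansion
  f2 <- maxent_fit(pres, dplyr::bind_rows(bg, bg), params, expansion = ex)
  expect_equal(f1$lambda, f2$lambda, tolerance = 1e-4)
})

test_that("transforms are monotone in raw and the null model is closed-form", {
  fx <- default_fixture()
  fit <- maxent_fit(fx$pres, fx$bg, maxent_params())
  raw <- predict(fit, fx$bg, "raw")
  logi <- predict(fit, fx$bg, "logistic")
  clog <- predict(fit, fx$bg, "cloglog")
  expect_equal(sum(raw), 1, tolerance = 1e-9)
  expect_true(all(logi >= 0 & logi <= 1))
  expect_true(all(clog >= 0 & clog <= 1))
  # monotone transforms: identical cell rankings up to saturation ties
  ord <- order(raw)
  expect_true(all(diff(logi[ord]) >= 0))
  expect_true(all(diff(clog[ord]) >= 0))
  mid <- ord[raw[ord] > quantile(raw, 0.5) & clog[ord] < 1 - 1e-9]
  expect_identical(order(raw[mid]), order(clog[mid]))

  # lambda = 0 model: raw = 1/B everywhere
  null_fit <- fit
  null_fit$lambda[] <- 0
  null_fit$log_z <- log(fit$n_background)
  expect_equal(predict(null_fit, fx$bg[1:5, ], "raw"),
               rep(1 / fit$n_background, 5))
})

test_that("objective from two different solver paths agrees (convexity)", {
  withr::with_seed(41, {
    bg <- tibble::tibble(x = runif(200), z = runif(200))
    pres <- tibble::tibble(x = runif(50, 0.4, 1), z = runif(50))
  })
  p1 <- maxent_params(tol = 1e-10, n_knots = 5)
  f1 <- maxent_fit(pres, bg, p1)
  # different path: restrict sweeps per call is not exposed, so permute the
  # feature order instead - same convex problem, same optimum
  ex <- f1$expansion
  ex2 <- ex
  perm <- rev(seq_len(nrow(ex$features)))
  ex2$features <- ex$features[perm, ]
  f2 <- maxent_fit(pres, bg, p1, expansion = ex2)
  expect_equal(f1$objective, f2$objective, tolerance = 1e-6)
})

test_that("AUC follows the Mann-Whitney hand oracle with half ties", {
  expect_equal(auc_score(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  expect_equal(auc_score(c(1, 1, 1), c(1, 1)), 0.5)
  expect_equal(auc_score(c(0.8, 0.9), c(0.1, 0.2)), 1.0)
  # invariance under strictly monotone transforms of the scores
  withr::with_seed(8, {
    p <- runif(20); b <- runif(50)
    a0 <- auc_score(p, b)
    expect_equal(auc_score(exp(3 * p), exp(3 * b)), a0)
    expect_equal(auc_score(qlogis(p / 2 + 0.25), qlogis(b / 2 + 0.25)), a0)
  })
})

test_that("AUC bands split at the documented break points", {
  expect_equal(classify_auc(0.942), "very_high")
  expect_equal(classify_auc(0.85), "good")
  expect_equal(classify_auc(0.75), "average")
  expect_equal(classify_auc(0.65), "poor")
  expect_equal(classify_auc(0.5), "failure")
  expect_equal(classify_auc(0.6), "failure")
  expect_equal(classify_auc(0.3), "worse_than_random")
})

test_that("cross-validation partitions reproducibly and k=1 degenerates", {
  fx <- default_fixture()
  p <- maxent_params(folds = 4, seed = 9)
  cv1 <- maxent_cv(fx$pres, fx$bg, p)
  cv2 <- maxent_cv(fx$pres, fx$bg, p)
  expect_identical(cv1$fold_id, cv2$fold_id)
  expect_equal(tidy(cv1), tidy(cv2))
  expect_true(all(cv1$eval$test_auc >= 0 & cv1$eval$test_auc <= 1))

  single <- maxent_cv(fx$pres[1:30, ], fx$bg, maxent_params(folds = 1))
  expect_equal(nrow(single$eval), 1L)
  expect_equal(single$eval$test_auc, single$eval$train_auc)
  expect_error(maxent_cv(fx$pres[1:5, ], fx$bg, maxent_params(folds = 10)),
               "smaller k", class = "nichetrack_data_error")
})

test_that("projection onto a stack propagates nodata and names variables", {
  fx <- default_fixture()
  fit <- maxent_fit(fx$pres, fx$bg, maxent_params(n_knots = 5))
  r <- predict(fit, fx$stack)
  expect_s3_class(r, "sdm_raster")
  expect_true(all(r$values >= 0 & r$values <= 1, na.rm = TRUE))
  # a stack missing one model variable errors by name
  st_missing <- assemble_stack(fx$stack$layers[
    setdiff(stack_names(fx$stack), "bio7")])
  expect_error(predict(fit, st_missing), "bio7",
               class = "nichetrack_data_error")
})
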