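#' Percent contribution per variable
#'
#' Each coordinate-descent gain increment recorded during training is
#' credited to the updated feature's source variable (product features split
#' evenly between their two sources). Negative credits are floored at zero
#' and the result is normalized to sum to 100.
#'
#' @param model A fitted `maxent_model`.
#' @return Tibble `variable`, `contribution` (percent), sorted descending.
#' @export
percent_contribution <- function(model) {
  if (is.null(model$gain_increments))
    abort("model lacks a training gain trace", class = "nichetrack_data_error")
  M <- feature_credit_matrix(model$expansion)
  credit <- pmax(drop(model$gain_increments %*% M), 0)
  total <- sum(credit)
  pct <- if (total > 0) 100 * credit / total else
    rep(0, length(credit))
  tibble(variable = colnames(M), contribution = unname(pct)) |>
    arrange(desc(.data$contribution))
}

#' Permutation importance per variable
#'
#' For each variable, its values are permuted jointly across the presences
#' and background, the training AUC is recomputed under the fitted model, and
#' the importance is `max(0, AUC_original - AUC_permuted)`, normalized to sum
#' to 100. The permutation is seeded.
#'
#' @param model A fitted `maxent_model`.
#' @param presence_values,background_values The training tables.
#' @param seed Permutation seed.
#' @return Tibble `variable`, `importance` (percent), sorted descending.
#' @export
permutation_importance <- function(model, presence_values, background_values,
                                   seed = NULL) {
  vars <- model_variables(model)
  m <- nrow(presence_values)
  base_auc <- auc_score(predict(model, presence_values, "raw"),
                        predict(model, background_values, "raw"))
  combined <- bind_rows(as_tibble(presence_values)[vars],
                        as_tibble(background_values)[vars])
  drops <- with_seed_(seed, vapply(vars, function(v) {
    perm <- combined
    perm[[v]] <- sample(perm[[v]])
    auc_p <- auc_score(predict(model, perm[seq_len(m), , drop = FALSE], "raw"),
                       predict(model, perm[-seq_len(m), , drop = FALSE], "raw"))
    max(0, base_auc - auc_p)
  }, numeric(1)))
  total <- sum(drops)
  pct <- if (total > 0) 100 * drops / total else rep(0, length(drops))
  tibble(variable = vars, importance = unname(pct)) |>
    arrange(desc(.data$importance))
}

#' Jackknife variable-importance test
#'
#' For each variable `v`, fits a model using only `v` (`gain_with_only`) and
#' one using every variable except `v` (`gain_without`), on the same presence
#' and background tables as the full model, and reports the regularized
#' training gains (presence log-likelihood improvement over uniform, net of
#' the L1 penalty) alongside the full-model gain. Using the penalty-netted
#' gain makes the nesting guarantee exact: a model over a feature subset can
#' never out-score the full model.
#'
#' @param presence_values,background_values Training tables.
#' @param params [maxent_params()].
#' @return Tibble `variable`, `gain_with_only`, `gain_without`, with the
#'   full-model gain in attribute `full_gain`.
#' @export
jackknife_gain <- function(presence_values, background_values,
                           params = maxent_params()) {
  expansion <- feature_expansion(background_values,
                                 classes = params$feature_classes,
                                 n_knots = params$n_knots)
  vars <- expansion$vars$variable
  if (length(vars) < 2)
    abort("jackknife needs at least 2 variables",
          class = "nichetrack_data_error")
  full <- maxent_fit(presence_values, background_values, params,
                     expansion = expansion)
  rows <- map(vars, function(v) {
    with_only <- maxent_fit(presence_values, background_values, params,
                            vars = v)
    without <- maxent_fit(presence_values, background_values, params,
                          vars = setdiff(vars, v))
    tibble(variable = v, gain_with_only = with_only$reg_gain,
           gain_without = without$reg_gain)
  })
  structure(bind_rows(rows), full_gain = full$reg_gain)
}

#' Marginal response curve of one variable
#'
#' Sweeps the target variable across its background range while every other
#' variable is held at its background mean, and evaluates the model.
#'
#' @param model A fitted `maxent_model`.
#' @param variable Variable name.
#' @param n Evaluation grid size, default 100.
#' @param transform Output transform (defaults to the fitting parameters).
#' @return Tibble of class `response_curve`: `variable`, `value`,
#'   `suitability`.
#' @export
response_curve <- function(model, variable, n = 100, transform = NULL) {
  vt <- model$expansion$vars
  if (!variable %in% vt$variable)
    abort(paste0("variable not in model: ", variable),
          class = "nichetrack_data_error")
  i <- match(variable, vt$variable)
  grid <- seq(vt$min[i], vt$max[i], length.out = n)
  newdata <- as_tibble(as.list(model$bg_means))[rep(1, n), ]
  newdata[[variable]] <- grid
  pred <- predict(model, newdata, transform = transform)
  structure(tibble(variable = variable, value = grid, suitability = pred),
            class = c("response_curve", class(tibble())))
}

#' Optimal value range(s) from a response curve
#'
#' Maximal contiguous intervals of the variable where predicted suitability
#' is at or above `level`, with linear interpolation at the crossings.
#'
#' @param curve A [response_curve()].
#' @param level Suitability threshold, default 0.5.
#' @return Tibble `xmin`, `xmax`; zero rows when the curve never reaches
#'   `level`.
#' @export
optimal_range <- function(curve, level = 0.5) {
  x <- curve$value; y <- curve$suitability
  above <- y >= level
  if (!any(above)) return(tibble(xmin = numeric(), xmax = numeric()))
  cross_x <- function(i) { # crossing between grid points i and i+1
    x[i] + (level - y[i]) * (x[i + 1] - x[i]) / (y[i + 1] - y[i])
  }
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (r in seq_along(runs$values)) {
    if (!runs$values[r]) next
    i0 <- starts[r]; i1 <- ends[r]
    xmin <- if (i0 == 1L) x[1] else cross_x(i0 - 1L)
    xmax <- if (i1 == length(x)) x[length(x)] else cross_x(i1)
    out[[length(out) + 1L]] <- tibble(xmin = xmin, xmax = xmax)
  }
  bind_rows(out)
}

#' @export
#' @method tidy maxent_model
tidy.maxent_model <- function(x, ...) {
  fe <- x$expansion$features
  tibble(feature = fe$id, kind = fe$kind, variable = fe$var1,
         variable2 = fe$var2, knot = fe$knot,
         lambda = unname(x$lambda[fe$id]),
         gain_increment = unname(x$gain_increments[fe$id]))
}

#' @export
#' @method glance maxent_model
glance.maxent_model <- function(x, ...) {
  tibble(gain = x$gain, reg_gain = x$reg_gain, entropy = x$entropy,
         log_z = x$log_z,
         train_auc = x$train_auc, n_features = length(x$lambda),
         n_nonzero = sum(x$lambda != 0), n_presence = x$n_presence,
         n_background = x$n_background, cycles = x$cycles)
}

#' @export
#' @method tidy maxent_cv
tidy.maxent_cv <- function(x, ...) x$eval

#' @export
#' @method glance maxent_cv
glance.maxent_cv <- function(x, ...) {
  tibble(folds = nrow(x$eval),
         mean_test_auc = mean(x$eval$test_auc),
         sd_test_auc = sd(x$eval$test_auc),
         mean_train_auc = mean(x$eval$train_auc),
         mean_gain = mean(x$eval$gain))
}
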