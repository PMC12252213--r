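#' Build a feature expansion from background values
#'
#' Records, per variable, the min/max/mean over the background sample (used
#' to scale every variable into `[0, 1]`) and the feature descriptors for the
#' requested classes:
#' * `linear`: the scaled value `t`,
#' * `quadratic`: `t^2`,
#' * `product`: pairwise products of scaled values,
#' * `hinge`: forward `max(0, (t - k)/(1 - k))` and reverse
#'   `max(0, (k - t)/k)` hinges with knots `k` at background quantiles
#'   (`n_knots` per variable, interior probabilities),
#' * `threshold`: indicator `t > k` at the same knots.
#'
#' Every feature maps background values into `[0, 1]`.
#'
#' @param bg_values Tibble of background environmental values.
#' @param classes Feature classes, subset of
#'   `c("linear", "quadratic", "product", "hinge", "threshold")`.
#' @param n_knots Number of hinge/threshold knots per variable (default 15).
#' @param vars Optional character vector restricting variables.
#' @return Object of class `feature_expansion`.
#' @export
feature_expansion <- function(bg_values,
                              classes = c("linear", "quadratic", "hinge"),
                              n_knots = 15, vars = NULL) {
  ok <- c("linear", "quadratic", "product", "hinge", "threshold")
  if (length(bad <- setdiff(classes, ok)))
    abort(paste0("unknown feature class: ", paste(bad, collapse = ", ")),
          class = "nichetrack_config_error")
  df <- as_tibble(bg_values)
  drop_cols <- c("point_id", "lon", "lat", "nodata", "species", "row", "col",
                 "area_km2")
  num <- df[vapply(df, is.numeric, logical(1))]
  num <- num[setdiff(names(num), drop_cols)]
  if (!is.null(vars)) num <- num[vars]
  if (anyNA(num))
    abort("background values must be finite", class = "nichetrack_data_error")
  vtab <- tibble(variable = names(num),
                 min = vapply(num, min, numeric(1)),
                 max = vapply(num, max, numeric(1)),
                 mean = vapply(num, mean, numeric(1)))
  feats <- list()
  add <- function(kind, var1, var2 = NA_character_, knot = NA_real_) {
    feats[[length(feats) + 1L]] <<- tibble(kind = kind, var1 = var1,
                                           var2 = var2, knot = knot)
  }
  scaled <- function(v) {
    rng <- vtab$max[vtab$variable == v] - vtab$min[vtab$variable == v]
    if (rng == 0) return(rep(0, nrow(num)))
    (num[[v]] - vtab$min[vtab$variable == v]) / rng
  }
  for (v in vtab$variable) {
    if ("linear" %in% classes) add("linear", v)
    if ("quadratic" %in% classes) add("quadratic", v)
    if (any(c("hinge", "threshold") %in% classes)) {
      t <- scaled(v)
      ks <- unique(unname(quantile(t, probs = seq_len(n_knots) / (n_knots + 1))))
      ks <- ks[ks > 0 & ks < 1]
      for (k in ks) {
        if ("hinge" %in% classes) { add("hinge", v, knot = k); add("rev_hinge", v, knot = k) }
        if ("threshold" %in% classes) add("threshold", v, knot = k)
      }
    }
  }
  if ("product" %in% classes && nrow(vtab) >= 2) {
    cmb <- utils::combn(vtab$variable, 2)
    for (i in seq_len(ncol(cmb))) add("product", cmb[1, i], cmb[2, i])
  }
  features <- bind_rows(feats)
  features$id <- ifelse(is.na(features$knot),
                        ifelse(is.na(features$var2),
                               paste(features$kind, features$var1, sep = ":"),
                               paste(features$kind, features$var1,
                                     features$var2, sep = ":")),
                        paste(features$kind, features$var1,
                              sprintf("%.6g", features$knot), sep = ":"))
  structure(list(vars = vtab, features = features, classes = classes,
                 n_knots = n_knots),
            class = "feature_expansion")
}

#' @export
print.feature_expansion <- function(x, ...) {
  cat(sprintf("<feature_expansion> %d features over %d variables (%s)\n",
              nrow(x$features), nrow(x$vars), paste(x$classes, collapse = "+")))
  invisible(x)
}

#' Evaluate a feature expansion on new values
#'
#' When projecting onto new data, scaled values are clamped to the training
#' range `[0, 1]` iff `clamp` is `TRUE`, so any value beyond the background
#' min/max yields the same feature vector as the corresponding extreme.
#'
#' @param values Tibble containing every variable of the expansion.
#' @param expansion A [feature_expansion()].
#' @param clamp Clamp scaled values into the training range (default `TRUE`).
#' @return Numeric matrix, one column per feature (column names = feature ids).
#' @export
build_features <- function(values, expansion, clamp = TRUE) {
  df <- as_tibble(values)
  missing <- setdiff(expansion$vars$variable, names(df))
  if (length(missing))
    abort(paste0("variable missing from data: ", paste(missing, collapse = ", ")),
          class = "nichetrack_data_error")
  n <- nrow(df)
  tmat <- matrix(0, n, nrow(expansion$vars),
                 dimnames = list(NULL, expansion$vars$variable))
  for (i in seq_len(nrow(expansion$vars))) {
    v <- expansion$vars$variable[i]
    rng <- expansion$vars$max[i] - expansion$vars$min[i]
    t <- if (rng == 0) rep(0, n) else (df[[v]] - expansion$vars$min[i]) / rng
    if (clamp) t <- pmin(pmax(t, 0), 1)
    tmat[, i] <- t
  }
  fe <- expansion$features
  X <- matrix(0, n, nrow(fe), dimnames = list(NULL, fe$id))
  for (j in seq_len(nrow(fe))) {
    t <- tmat[, fe$var1[j]]
    X[, j] <- switch(fe$kind[j],
      linear = t,
      quadratic = t^2,
      product = t * tmat[, fe$var2[j]],
      hinge = pmax(0, (t - fe$knot[j]) / (1 - fe$knot[j])),
      rev_hinge = pmax(0, (fe$knot[j] - t) / fe$knot[j]),
      threshold = as.numeric(t > fe$knot[j]))
  }
  X
}

# map each feature column to the variable(s) it derives from; product features
# split credit evenly between their two sources
feature_credit_matrix <- function(expansion) {
  fe <- expansion$features
  vars <- expansion$vars$variable
  M <- matrix(0, nrow(fe), length(vars), dimnames = list(fe$id, vars))
  for (j in seq_len(nrow(fe))) {
    if (fe$kind[j] == "product") {
      M[j, fe$var1[j]] <- 0.5
      M[j, fe$var2[j]] <- 0.5
    } else M[j, fe$var1[j]] <- 1
  }
  M
}
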