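#' Pairwise Pearson correlation matrix
#'
#' Standard Pearson correlations between all numeric variable columns.
#' Constant columns (zero variance) get a correlation of 0 against every other variable
#' and are flagged in the `constant` attribute.
#'
#' @param values Data frame of extracted environmental values, one row per
#'   point; non-numeric columns and the bookkeeping columns `point_id`, `lon`,
#'   `lat`, `nodata` are ignored. Rows flagged as nodata must be removed
#'   before correlating.
#' @param vars Optional character vector restricting the variables used.
#' @return A symmetric correlation matrix of class `cor_matrix` (diagonal
#'   exactly 1), with attribute `constant` naming zero-variance variables.
#' @export
pearson_matrix <- function(values, vars = NULL) {
  df <- as_tibble(values)
  drop_cols <- c("point_id", "lon", "lat", "nodata", "species", "row", "col",
                 "area_km2")
  num <- df[vapply(df, is.numeric, logical(1))]
  num <- num[setdiff(names(num), drop_cols)]
  if (!is.null(vars)) num <- num[vars]
  if (anyNA(num))
    abort("values contain missing entries; drop nodata rows before correlating",
          class = "nichetrack_data_error")
  if (nrow(num) < 3L)
    abort("need at least 3 rows to estimate correlations",
          class = "nichetrack_data_error")
  sds <- vapply(num, sd, numeric(1))
  const <- names(num)[sds == 0]
  r <- suppressWarnings(cor(as.matrix(num)))
  r[is.na(r)] <- 0
  diag(r) <- 1
  structure(r, constant = const, class = c("cor_matrix", class(r)))
}

#' @export
#' @method tidy cor_matrix
tidy.cor_matrix <- function(x, ...) {
  nms <- colnames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble(var1 = nms[idx[, 1]], var2 = nms[idx[, 2]],
         r = x[idx])
}

as_contrib <- function(contrib) {
  if (is.data.frame(contrib)) {
    setNames(contrib$contribution, contrib$variable)
  } else contrib
}

#' Prune collinear variables, keeping the higher-contribution member
#'
#' Offending pairs (`|r| >= threshold`) are processed greedily in descending
#' `|r|` (ties broken by variable-name order). For each pair in which both
#' variables are still alive, the member with the lower percent contribution
#' is dropped (contribution ties drop the later name alphabetically). After
#' pruning, no surviving pair is at or above the threshold.
#'
#' @param corr A `cor_matrix` from [pearson_matrix()].
#' @param contrib Percent contributions: a tibble with columns `variable`,
#'   `contribution` (as returned by [percent_contribution()]) or a named
#'   numeric vector. Must cover every variable in `corr`.
#' @param threshold Absolute-correlation threshold, default 0.8.
#' @return List with `kept` (character vector, original variable order) and
#'   `drop_log` (tibble: `kept`, `dropped`, `r`, `contribution_kept`,
#'   `contribution_dropped`).
#' @export
prune_collinear <- function(corr, contrib, threshold = 0.8) {
  nms <- colnames(corr)
  cv <- as_contrib(contrib)
  missing <- setdiff(nms, names(cv))
  if (length(missing))
    abort(paste0("no contribution entry for: ", paste(missing, collapse = ", ")),
          class = "nichetrack_config_error")
  pairs <- tidy(corr)
  pairs <- pairs[abs(pairs$r) >= threshold, , drop = FALSE]
  # deterministic greedy order: descending |r|, then name order
  a <- pmin(pairs$var1, pairs$var2); b <- pmax(pairs$var1, pairs$var2)
  ord <- order(-abs(pairs$r), a, b)
  pairs <- pairs[ord, , drop = FALSE]
  alive <- setNames(rep(TRUE, length(nms)), nms)
  log_rows <- list()
  for (i in seq_len(nrow(pairs))) {
    v1 <- pairs$var1[i]; v2 <- pairs$var2[i]
    if (!alive[v1] || !alive[v2]) next
    c1 <- cv[[v1]]; c2 <- cv[[v2]]
    if (c1 > c2) { keep <- v1; drop <- v2 }
    else if (c2 > c1) { keep <- v2; drop <- v1 }
    else { keep <- min(v1, v2); drop <- max(v1, v2) }
    alive[drop] <- FALSE
    log_rows[[length(log_rows) + 1L]] <-
      tibble(kept = keep, dropped = drop, r = pairs$r[i],
             contribution_kept = cv[[keep]], contribution_dropped = cv[[drop]])
  }
  list(kept = nms[alive[nms]],
       drop_log = if (length(log_rows)) bind_rows(log_rows)
                  else tibble(kept = character(), dropped = character(),
                              r = numeric(), contribution_kept = numeric(),
                              contribution_dropped = numeric()))
}

#' Two-pass variable selection
#'
#' Pass 1 fits a preliminary maximum-entropy model on all candidate variables
#' to obtain percent contributions; pass 2 computes Pearson correlations
#' (over the presence points by default, matching the practice of extracting
#' species climate data just before correlating) and prunes collinear pairs
#' with [prune_collinear()].
#'
#' @param presence_values Tibble of environmental values at presence points
#'   (variable columns only are used).
#' @param stack `sdm_stack` of all candidate layers.
#' @param params [maxent_params()] for the preliminary fit.
#' @param threshold Pruning threshold on `|r|`, default 0.8.
#' @param cor_basis `"presence"` (default) correlates values at presence
#'   points; `"raster"` correlates over all background cells.
#' @return List: `kept`, `drop_log`, `contributions`, `correlation`
#'   (`cor_matrix`), `preliminary_model`.
#' @export
select_variables <- function(presence_values, stack, params = maxent_params(),
                             threshold = 0.8,
                             cor_basis = c("presence", "raster")) {
  cor_basis <- match.arg(cor_basis)
  bg <- sample_background(stack, params$background_n, seed = params$seed)
  fit0 <- maxent_fit(presence_values, bg, params)
  contrib <- percent_contribution(fit0)
  basis <- if (cor_basis == "presence") presence_values else bg
  corr <- pearson_matrix(basis, vars = model_variables(fit0))
  pr <- prune_collinear(corr, contrib, threshold)
  list(kept = pr$kept, drop_log = pr$drop_log, contributions = contrib,
       correlation = corr, preliminary_model = fit0)
}
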