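#' Configuration for the synthetic study-system generator
#'
#' Defines a complete synthetic counterpart of a real SDM study: a regular
#' grid, `V` spatially autocorrelated standardized environmental layers with
#' a planted correlation structure, a known log-linear (cloglog-link) true
#' suitability surface, presence samples drawn from it, and shifted scenario
#' stacks. Defaults describe the reference conditions used throughout the
#' test-suite: a 100 x 100 grid, six variables with one r = 0.9 collinear
#' pair, one dominant positive coefficient, 200 presences, and two future
#' scenarios that shift the dominant driver downward.
#'
#' @param nrows,ncols Grid size, default 100 x 100.
#' @param cellsize Cell size in degrees, default 0.05.
#' @param origin Lower-left corner `c(lon, lat)`, default `c(105, 22)`.
#' @param vars Variable names (`V >= 2`).
#' @param smoothness Moving-average kernel half-width in cells, default 5.
#' @param cor_plan Tibble `var1`, `var2`, `r`: after generation, `var2` is
#'   rebuilt as the mix `r*var1 + sqrt(1 - r^2)*noise`. A variable may be rebuilt
#'   at most once and cycles are rejected.
#' @param coefs Named linear coefficients of the true log-linear predictor
#'   (on the standardized layers).
#' @param quad_coefs Optional named quadratic coefficients.
#' @param intercept Intercept of the linear predictor, default -1.
#' @param n_presences Number of presence records, default 200 (>= 10).
#' @param scenario_shifts Named list of per-variable additive deltas (on the
#'   standardized scale) defining non-baseline scenarios.
#' @param seed Generator seed.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(nrows = 100, ncols = 100, cellsize = 0.05,
                             origin = c(105, 22),
                             vars = c("bio14", "bio12", "bio7", "bio4",
                                      "alum_sat", "dem"),
                             smoothness = 5,
                             cor_plan = tibble(var1 = "alum_sat", var2 = "dem",
                                               r = 0.9),
                             coefs = c(bio14 = 4, bio12 = 1, bio7 = -0.7,
                                       bio4 = 0.5, alum_sat = 0.4, dem = 0),
                             quad_coefs = NULL,
                             intercept = -8, n_presences = 200,
                             scenario_shifts = list(
                               future_low = c(bio14 = -0.4),
                               future_high = c(bio14 = -1)),
                             seed = 1) {
  if (length(vars) < 2)
    abort("need V >= 2 variables", class = "nichetrack_config_error")
  if (n_presences < 10)
    abort("n_presences must be >= 10", class = "nichetrack_config_error")
  if (nrow(cor_plan) > 0) {
    if (any(abs(cor_plan$r) >= 1))
      abort("|target r| must be < 1", class = "nichetrack_config_error")
    if (anyDuplicated(cor_plan$var2))
      abort("infeasible correlation plan: a variable is rebuilt twice",
            class = "nichetrack_config_error")
    # reject cycles: var1 must not be rebuilt from (a descendant of) var2
    for (i in seq_len(nrow(cor_plan))) {
      anc <- cor_plan$var1[i]
      seen <- character()
      while (anc %in% cor_plan$var2) {
        if (anc %in% seen || anc == cor_plan$var2[i])
          abort("infeasible correlation plan: cyclic dependency",
                class = "nichetrack_config_error")
        seen <- c(seen, anc)
        anc <- cor_plan$var1[match(anc, cor_plan$var2)]
      }
      if (anc == cor_plan$var2[i])
        abort("infeasible correlation plan: cyclic dependency",
              class = "nichetrack_config_error")
    }
    stopifnot(all(c(cor_plan$var1, cor_plan$var2) %in% vars))
  }
  stopifnot(all(names(coefs) %in% vars))
  structure(list(nrows = nrows, ncols = ncols, cellsize = cellsize,
                 origin = origin, vars = vars, smoothness = smoothness,
                 cor_plan = cor_plan, coefs = coefs, quad_coefs = quad_coefs,
                 intercept = intercept, n_presences = n_presences,
                 scenario_shifts = scenario_shifts, seed = seed),
            class = "generator_config")
}

# separable moving-average smoother with edge renormalization (kernel of
# half-width w applied along rows then columns)
ma_smooth <- function(m, w) {
  if (w <= 0) return(m)
  k <- rep(1, 2 * w + 1)
  sm1 <- function(x) { # smooth the columns of x
    padded <- rbind(matrix(0, w, ncol(x)), x, matrix(0, w, ncol(x)))
    ones <- rbind(matrix(0, w, ncol(x)), matrix(1, nrow(x), ncol(x)),
                  matrix(0, w, ncol(x)))
    num <- apply(padded, 2, function(col) stats::filter(col, k, sides = 2))
    den <- apply(ones, 2, function(col) stats::filter(col, k, sides = 2))
    (num / den)[(w + 1):(w + nrow(x)), , drop = FALSE]
  }
  t(sm1(t(sm1(m))))
}

#' Generate a synthetic environmental stack
#'
#' Each layer is seeded white noise smoothed by a separable moving-average
#' kernel of half-width `smoothness` and standardized to mean 0, sd 1 over
#' the grid; then the correlation plan is imposed by linear mixing
#' (`var2 <- r * var1 + sqrt(1 - r^2) * var2`), followed by
#' re-standardization. Deterministic under the config seed.
#'
#' @param cfg A [generator_config()].
#' @return `sdm_stack` with one layer per variable.
#' @export
gen_env_stack <- function(cfg) {
  spec <- grid_spec(cfg$ncols, cfg$nrows, cfg$origin[1], cfg$origin[2],
                    cfg$cellsize)
  layers <- with_seed_(cfg$seed, {
    out <- list()
    for (v in cfg$vars) {
      z <- matrix(rnorm(cfg$nrows * cfg$ncols), cfg$nrows, cfg$ncols)
      z <- ma_smooth(z, cfg$smoothness)
      z <- (z - mean(z)) / sd(z)
      out[[v]] <- z
    }
    out
  })
  if (nrow(cfg$cor_plan) > 0) {
    for (i in seq_len(nrow(cfg$cor_plan))) {
      v1 <- cfg$cor_plan$var1[i]; v2 <- cfg$cor_plan$var2[i]
      r <- cfg$cor_plan$r[i]
      mixed <- r * layers[[v1]] + sqrt(1 - r^2) * layers[[v2]]
      layers[[v2]] <- (mixed - mean(mixed)) / sd(mixed)
    }
  }
  assemble_stack(map2(layers, names(layers),
                      function(m, nm) new_raster(m, spec, nm)))
}

#' True suitability surface of a synthetic stack
#'
#' Linear predictor `eta = intercept + sum(coefs * layer)
#' (+ sum(quad_coefs * layer^2))`, mapped through the cloglog link
#' `1 - exp(-exp(eta))` — the same output family as the model's default
#' transform, so parameter recovery is well-posed.
#'
#' @param stack `sdm_stack` from [gen_env_stack()] or [gen_scenario()].
#' @param cfg The [generator_config()].
#' @return `sdm_raster` named `"true_suitability"` with values in `[0, 1]`.
#' @export
true_suitability <- function(stack, cfg) {
  spec <- stack$spec
  eta <- matrix(cfg$intercept, spec$nrows, spec$ncols)
  for (v in names(cfg$coefs))
    eta <- eta + cfg$coefs[[v]] * stack$layers[[v]]$values
  for (v in names(cfg$quad_coefs %||% numeric()))
    eta <- eta + cfg$quad_coefs[[v]] * stack$layers[[v]]$values^2
  new_raster(1 - exp(-exp(eta)), spec, "true_suitability")
}

#' Sample presence records from a true suitability surface
#'
#' Cells are drawn without replacement with probability proportional to
#' suitability x geodesic cell area; each record sits at its cell center, so
#' downstream thinning on the same grid is exactly predictable.
#'
#' @param suitability `sdm_raster` in `[0, 1]`.
#' @param n Number of presences.
#' @param seed Sampling seed.
#' @param species Species label, default `"synthetic"`.
#' @return Occurrence tibble (`species`, `lon`, `lat`, `source`).
#' @export
sample_presences <- function(suitability, n, seed = NULL,
                             species = "synthetic") {
  spec <- suitability$spec
  v <- as.vector(suitability$values)
  row <- rep(seq_len(spec$nrows), times = spec$ncols)
  col <- rep(seq_len(spec$ncols), each = spec$nrows)
  wt <- v * cell_area_km2(spec, row)
  ok <- !is.na(wt) & wt > 0
  if (sum(ok) < n)
    abort(sprintf("only %d cells with positive suitability; cannot draw %d",
                  sum(ok), n),
          class = "nichetrack_data_error")
  pick <- with_seed_(seed, sample(which(ok), n, prob = wt[ok]))
  cc <- cell_center(row[pick], col[pick], spec)
  tibble(species = species, lon = cc$lon, lat = cc$lat, source = "generator")
}

#' Shift a stack into a scenario
#'
#' Adds per-variable deltas (standardized scale) to the layers; the truth for
#' the shifted stack is recomputed from the same coefficients via
#' [true_suitability()] / [truth_bundle()].
#'
#' @param stack Baseline `sdm_stack`.
#' @param shifts Named numeric vector of additive deltas.
#' @return Shifted `sdm_stack`.
#' @export
gen_scenario <- function(stack, shifts) {
  unknown <- setdiff(names(shifts), stack_names(stack))
  if (length(unknown))
    abort(paste0("shift for unknown variable: ", paste(unknown, collapse = ", ")),
          class = "nichetrack_config_error")
  layers <- map(stack$layers, function(r) {
    d <- if (r$name %in% names(shifts)) shifts[[r$name]] else 0
    new_raster(r$values + d, r$spec, r$name)
  })
  assemble_stack(unname(layers), mask = stack$mask)
}

#' Ground-truth bundle for every scenario of a config
#'
#' Recomputes, deterministically from the config alone: the baseline stack,
#' per-scenario shifted stacks, true suitability rasters, true class areas
#' and true centroids. No hidden state — calling it twice gives identical
#' results.
#'
#' @param cfg A [generator_config()].
#' @param breaks Classification breaks, default `c(0.25, 0.5, 0.75)`.
#' @return List: `stacks` (named, incl. `current`), `suitability` (named
#'   rasters), `class_maps`, `areas` (tibble), `centroids`
#'   ([centroid_track()] tibble), `cfg`.
#' @export
truth_bundle <- function(cfg, breaks = c(0.25, 0.5, 0.75)) {
  base <- gen_env_stack(cfg)
  stacks <- c(list(current = base),
              map(cfg$scenario_shifts, function(sh) gen_scenario(base, sh)))
  suits <- map(stacks, true_suitability, cfg = cfg)
  cmaps <- map(suits, classify_suitability, breaks = breaks)
  areas <- bind_rows(imap(cmaps, function(cm, nm) class_areas(cm, scenario = nm)))
  cents <- if (length(cmaps) >= 2) centroid_track(cmaps) else NULL
  list(stacks = stacks, suitability = suits, class_maps = cmaps,
       areas = areas, centroids = cents, cfg = cfg)
}

#' Write a complete synthetic fixture to disk
#'
#' Emits everything the pipeline consumes — occurrence CSV, per-scenario
#' ASCII grid directories, a YAML pipeline config — plus the truth tables
#' for assertions.
#'
#' @param cfg A [generator_config()].
#' @param dir Output directory (created if needed).
#' @return List: `config_path`, `occurrences_path`, `scenario_dirs`, `truth`
#'   (the [truth_bundle()]), `pipeline_config` (parsed list).
#' @export
end_to_end_fixture <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- truth_bundle(cfg)
  occ <- sample_presences(truth$suitability$current, cfg$n_presences,
                          seed = cfg$seed + 1)
  occ_path <- file.path(dir, "occurrences.csv")
  readr::write_csv(occ, occ_path, progress = FALSE)
  sc_dirs <- imap(truth$stacks, function(st, nm) {
    d <- file.path(dir, "layers", nm)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (r in st$layers) write_ascii_grid(r, file.path(d, paste0(r$name, ".asc")))
    d
  })
  readr::write_csv(truth$areas, file.path(dir, "truth_areas.csv"),
                   progress = FALSE)
  if (!is.null(truth$centroids))
    readr::write_csv(as_tibble(truth$centroids),
                     file.path(dir, "truth_centroids.csv"), progress = FALSE)
  pc <- list(
    occurrences = occ_path,
    scenarios = setNames(as.list(unlist(sc_dirs)), names(sc_dirs)),
    baseline = "current",
    output_dir = file.path(dir, "run"),
    thin_cellsize = 2.5 / 60,
    cor_threshold = 0.8,
    breaks = c(0.25, 0.5, 0.75),
    seed = cfg$seed,
    maxent = list(background_n = 10000, folds = 10, beta_multiplier = 1,
                  transform = "cloglog"))
  cfg_path <- file.path(dir, "config.yml")
  yaml::write_yaml(pc, cfg_path)
  list(config_path = cfg_path, occurrences_path = occ_path,
       scenario_dirs = sc_dirs, truth = truth, pipeline_config = pc)
}
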