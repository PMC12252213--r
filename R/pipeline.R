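#' Read and validate a pipeline configuration
#'
#' The config is a YAML file (or an equivalent named list) with keys:
#' `occurrences` (CSV path), `scenarios` (named map scenario -> directory of
#' `.asc` layers), `baseline` (name present in `scenarios`), `output_dir`,
#' `thin_cellsize` (degrees, default 2.5/60), `cor_threshold` (default 0.8),
#' `breaks` (default 0.25/0.5/0.75), `seed`, and `maxent` (a map of
#' [maxent_params()] arguments).
#'
#' @param config Path to a YAML file, or a named list.
#' @return Validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  defaults <- list(thin_cellsize = 2.5 / 60, cor_threshold = 0.8,
                   breaks = c(0.25, 0.5, 0.75), seed = 1, maxent = list())
  cfg <- modifyList(defaults, cfg)
  for (key in c("occurrences", "scenarios", "baseline", "output_dir")) {
    if (is.null(cfg[[key]]))
      abort(paste0("pipeline config missing key: ", key),
            class = "nichetrack_config_error")
  }
  cfg$breaks <- unlist(cfg$breaks)
  if (!cfg$baseline %in% names(cfg$scenarios))
    abort("baseline scenario must appear in the scenario list",
          class = "nichetrack_config_error")
  if (!file.exists(cfg$occurrences))
    abort(paste0("occurrence file not found: ", cfg$occurrences),
          class = "nichetrack_config_error")
  for (d in unlist(cfg$scenarios)) {
    if (!dir.exists(d))
      abort(paste0("scenario directory not found: ", d),
            class = "nichetrack_config_error")
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

read_stack_dir <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
  if (!length(paths))
    abort(paste0("no .asc layers in ", dir), class = "nichetrack_data_error")
  assemble_stack(map(paths, read_ascii_grid))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
          class = "nichetrack_pipeline_error", stage = name, parent = e)
  })
}

#' Run the full analysis pipeline
#'
#' Executes: clean -> thin -> extract -> preliminary fit -> collinearity
#' pruning -> cross-validated fit -> evaluation -> per-scenario projection
#' (clamped) -> classification -> areas/changes/centroids. Writes to the run
#' directory: thinned occurrences, correlation matrix and drop log,
#' importance tables, evaluation summary, mean suitability / class / change
#' grids per scenario, the area-change table, the centroid track, and a
#' manifest listing every output with an MD5 content hash plus all seeds and
#' parameters. Reruns under the same config and seed are byte-identical.
#'
#' The single config seed fans out to fixed stage offsets (background = seed
#' + 1, folds = seed + 2, permutation = seed + 3) so each stage is
#' independently reproducible.
#'
#' @param config Path to a YAML config or a named list
#'   (see [read_pipeline_config()]).
#' @return Invisibly, a list of the principal results (`selection`, `cv`,
#'   `report`, `eval`, paths), with the run directory in `$run_dir`.
#' @export
run_full <- function(config) {
  cfg <- read_pipeline_config(config)
  run_dir <- cfg$output_dir
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  seed_bg <- cfg$seed + 1L; seed_folds <- cfg$seed + 2L
  seed_perm <- cfg$seed + 3L

  stacks <- stage("load_layers",
                  map(cfg$scenarios, read_stack_dir))
  base_stack <- stacks[[cfg$baseline]]

  occ_raw <- stage("read_occurrences", read_occurrences(cfg$occurrences))
  occ <- stage("clean", clean_occurrences(occ_raw, bounds = base_stack$spec))
  occ <- stage("thin", thin_occurrences(
    occ, cellsize = cfg$thin_cellsize,
    origin = c(base_stack$spec$xllcorner, base_stack$spec$yllcorner)))
  write_occurrences(occ, file.path(run_dir, "occurrences_thinned.csv"),
                    audit_path = file.path(run_dir, "occurrences_removed.csv"))

  pres <- stage("extract", {
    ex <- extract_at_points(occ, base_stack)
    ex[!ex$nodata, , drop = FALSE]
  })

  mx_args <- cfg$maxent
  mx_args$seed <- seed_folds
  params <- do.call(maxent_params, mx_args)

  sel <- stage("select_variables", {
    p1 <- params; p1$seed <- seed_bg
    select_variables(pres, base_stack, p1, threshold = cfg$cor_threshold)
  })
  readr::write_csv(as_tibble(as.data.frame(unclass(sel$correlation)),
                             rownames = "variable"),
                   file.path(run_dir, "correlation_matrix.csv"),
                   progress = FALSE)
  readr::write_csv(sel$drop_log, file.path(run_dir, "variable_drop_log.csv"),
                   progress = FALSE)

  bg <- stage("background",
              sample_background(base_stack, params$background_n,
                                seed = seed_bg))
  cv <- stage("crossvalidate",
              maxent_cv(pres[, sel$kept, drop = FALSE],
                        bg[, sel$kept, drop = FALSE], params,
                        stack = base_stack))

  final_fit <- stage("final_fit",
                     maxent_fit(pres[, sel$kept, drop = FALSE],
                                bg[, sel$kept, drop = FALSE], params))
  imp <- stage("importance", {
    contrib <- percent_contribution(final_fit)
    perm <- permutation_importance(final_fit, pres[, sel$kept, drop = FALSE],
                                   bg[, sel$kept, drop = FALSE],
                                   seed = seed_perm)
    left_join(contrib, perm, by = "variable")
  })
  readr::write_csv(imp, file.path(run_dir, "importance_table.csv"),
                   progress = FALSE)

  eval_tbl <- glance(cv)
  eval_tbl$auc_band <- classify_auc(eval_tbl$mean_test_auc)
  readr::write_csv(eval_tbl, file.path(run_dir, "evaluation.csv"),
                   progress = FALSE)
  readr::write_csv(tidy(cv), file.path(run_dir, "evaluation_folds.csv"),
                   progress = FALSE)

  cmaps <- stage("project_classify", {
    out <- list()
    for (nm in names(stacks)) {
      suit <- if (nm == cfg$baseline) cv$mean_raster else
        predict(cv, stacks[[nm]])
      suit$name <- paste0(nm, "_suitability")
      write_ascii_grid(suit, file.path(run_dir, paste0(nm, "_suitability.asc")))
      cm <- classify_suitability(suit, breaks = cfg$breaks)
      write_ascii_grid(cm, file.path(run_dir, paste0(nm, "_class.asc")))
      out[[nm]] <- cm
    }
    out
  })

  report <- stage("report", scenario_report(cmaps, baseline = cfg$baseline))
  readr::write_csv(report$areas, file.path(run_dir, "area_change_table.csv"),
                   progress = FALSE)
  for (nm in names(report$change_maps))
    write_ascii_grid(report$change_maps[[nm]],
                     file.path(run_dir, paste0(nm, "_change.asc")))
  if (!is.null(report$centroids))
    readr::write_csv(as_tibble(report$centroids),
                     file.path(run_dir, "centroid_track.csv"),
                     progress = FALSE)

  stage("manifest", {
    files <- sort(setdiff(list.files(run_dir), "manifest.yml"))
    manifest <- list(
      tool = "nichetrack", version = as.character(packageVersion("nichetrack")),
      seed = cfg$seed,
      derived_seeds = list(background = seed_bg, folds = seed_folds,
                           permutation = seed_perm),
      parameters = list(thin_cellsize = cfg$thin_cellsize,
                        cor_threshold = cfg$cor_threshold,
                        breaks = cfg$breaks, maxent = cfg$maxent),
      kept_variables = sel$kept,
      outputs = setNames(as.list(unname(
        tools::md5sum(file.path(run_dir, files)))), files))
    yaml::write_yaml(manifest, file.path(run_dir, "manifest.yml"))
  })

  invisible(list(run_dir = run_dir, selection = sel, cv = cv, eval = eval_tbl,
                 importance = imp, report = report, class_maps = cmaps,
                 occurrences = occ))
}
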