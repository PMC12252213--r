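# integer codes used in class maps and change maps
CLASS_CODES <- c(non = 0L, low = 1L, medium = 2L, high = 3L)
CHANGE_CODES <- c(never_suitable = 0L, stable = 1L, expansion = 2L,
                  contraction = 3L)

#' Classify a suitability raster into four bands
#'
#' Intervals are left-closed/right-open with the top band closed at 1:
#' `[0, 0.25)` non-suitable (0), `[0.25, 0.5)` low (1), `[0.5, 0.75)` medium
#' (2), `[0.75, 1]` high (3). Nodata propagates.
#'
#' @param suitability `sdm_raster` with values in `[0, 1]` or `NA`.
#' @param breaks Ascending break points, default `c(0.25, 0.5, 0.75)`.
#' @return `sdm_raster` of integer class codes (class `class_map`), with the
#'   breaks recorded in attribute `breaks`.
#' @export
classify_suitability <- function(suitability, breaks = c(0.25, 0.5, 0.75)) {
  v <- suitability$values
  fin <- v[!is.na(v)]
  if (length(fin) && (min(fin) < 0 || max(fin) > 1))
    abort(sprintf("suitability values outside [0, 1]: range [%g, %g]",
                  min(fin), max(fin)),
          class = "nichetrack_validation_error")
  cls <- matrix(NA_real_, nrow(v), ncol(v))
  cls[!is.na(v)] <- findInterval(v[!is.na(v)], breaks)
  out <- new_raster(cls, suitability$spec, paste0(suitability$name, "_class"))
  attr(out, "breaks") <- breaks
  class(out) <- c("class_map", class(out))
  out
}

#' Class areas of a suitability class map
#'
#' Sums geodesic cell areas (see [cell_area_km2()]) per class and reports
#' them in units of 10^4 km^2; total suitable = low + medium + high. The
#' `planar` method instead gives every cell the equatorial cell area, for
#' grids whose provenance used equal-area-naive accounting.
#'
#' @param cmap A `class_map`.
#' @param scenario Scenario label attached to the row.
#' @param method `"geodesic"` (default) or `"planar"`.
#' @return One-row tibble: `scenario`, `area_non`, `area_low`, `area_medium`,
#'   `area_high`, `area_total_suitable`, all in 10^4 km^2.
#' @export
class_areas <- function(cmap, scenario = cmap$name,
                        method = c("geodesic", "planar")) {
  method <- match.arg(method)
  spec <- cmap$spec
  row <- rep(seq_len(spec$nrows), times = spec$ncols)
  area <- if (method == "geodesic") cell_area_km2(spec, row) else
    rep(6371.0088^2 * (spec$cellsize * pi / 180)^2, length(row))
  cls <- as.vector(cmap$values)
  tot <- function(code) sum(area[!is.na(cls) & cls == code]) / 1e4
  a <- vapply(CLASS_CODES, tot, numeric(1))
  tibble(scenario = scenario,
         area_non = a[["non"]], area_low = a[["low"]],
         area_medium = a[["medium"]], area_high = a[["high"]],
         area_total_suitable = a[["low"]] + a[["medium"]] + a[["high"]])
}

#' Percent change versus a baseline area
#'
#' `100 * (area - baseline) / baseline`, rounded half-away-from-zero to two
#' decimals (the convention of printed area tables). A zero baseline with a
#' positive area is undefined and yields `NA` with a warning.
#'
#' @param area,baseline Numeric vectors (any consistent unit).
#' @return Numeric vector of percent changes, 2 decimals.
#' @export
percent_change <- function(area, baseline) {
  out <- rep(NA_real_, length(area))
  bad <- baseline <= 0
  if (any(bad & area > 0))
    warn("percent change undefined for zero baseline; returning NA")
  ok <- !bad
  out[ok] <- round_half_away(100 * (area[ok] - baseline[ok]) / baseline[ok], 2)
  out
}

#' Expansion/stability/contraction map between two class maps
#'
#' Cells suitable in neither map are `never_suitable` (0); suitable in both,
#' `stable` (1); newly suitable, `expansion` (2); newly unsuitable,
#' `contraction` (3). "Suitable" means class at or above `suitable_min`
#' (default: low).
#'
#' @param baseline,scenario Aligned `class_map`s.
#' @param suitable_min Minimum class code counted as suitable, default 1.
#' @return `sdm_raster` of change codes (class `change_map`).
#' @export
change_map <- function(baseline, scenario, suitable_min = 1L) {
  if (!grids_aligned(baseline$spec, scenario$spec))
    abort("class maps are misaligned", class = "nichetrack_alignment_error")
  b <- baseline$values >= suitable_min
  s <- scenario$values >= suitable_min
  st <- matrix(NA_real_, nrow(b), ncol(b))
  ok <- !is.na(b) & !is.na(s)
  st[ok & !b & !s] <- CHANGE_CODES[["never_suitable"]]
  st[ok & b & s] <- CHANGE_CODES[["stable"]]
  st[ok & !b & s] <- CHANGE_CODES[["expansion"]]
  st[ok & b & !s] <- CHANGE_CODES[["contraction"]]
  out <- new_raster(st, baseline$spec, paste0(scenario$name, "_change"))
  class(out) <- c("change_map", class(out))
  out
}

#' Cell counts per change state
#'
#' @param chmap A [change_map()].
#' @return Tibble `state`, `cells`.
#' @export
change_summary <- function(chmap) {
  v <- as.vector(chmap$values)
  tibble(state = names(CHANGE_CODES),
         cells = unname(vapply(CHANGE_CODES,
                               function(code) sum(v == code, na.rm = TRUE),
                               numeric(1))))
}

#' Centroid of the suitable habitat
#'
#' Area-weighted mean of suitable-cell center coordinates. Mode
#' `"suitability"` weights by suitability x area instead (requires the
#' continuous `suitability` raster). Longitudes are assumed non-wrapping
#' within the study window.
#'
#' @param cmap A `class_map`.
#' @param mode `"binary"` (default) or `"suitability"`.
#' @param suitability `sdm_raster` of continuous suitability, needed for mode
#'   `"suitability"`.
#' @param suitable_min Minimum class code counted as suitable, default 1.
#' @return Tibble `lon`, `lat`.
#' @export
habitat_centroid <- function(cmap, mode = c("binary", "suitability"),
                             suitability = NULL, suitable_min = 1L) {
  mode <- match.arg(mode)
  suit <- !is.na(cmap$values) & cmap$values >= suitable_min
  if (!any(suit))
    abort("no suitable cells; centroid undefined",
          class = "nichetrack_data_error")
  idx <- which(suit, arr.ind = TRUE)
  cc <- cell_center(idx[, 1], idx[, 2], cmap$spec)
  w <- cell_area_km2(cmap$spec, idx[, 1])
  if (mode == "suitability") {
    if (is.null(suitability))
      abort("mode 'suitability' needs the continuous suitability raster",
            class = "nichetrack_config_error")
    w <- w * suitability$values[idx]
  }
  tibble(lon = sum(w * cc$lon) / sum(w), lat = sum(w * cc$lat) / sum(w))
}

#' Centroid-migration track across scenarios
#'
#' Computes the suitable-habitat centroid per scenario and, for each
#' consecutive pair, the great-circle (haversine, R = 6371.0088 km)
#' displacement and initial bearing.
#'
#' @param cmaps Named ordered list of `class_map`s (>= 2 scenarios).
#' @param ... Passed to [habitat_centroid()].
#' @return Tibble of class `centroid_track`: `scenario`, `lon`, `lat`,
#'   `displacement_km`, `bearing_deg` (both `NA` on the first row).
#' @export
centroid_track <- function(cmaps, ...) {
  if (length(cmaps) < 2)
    abort("need at least 2 scenarios", class = "nichetrack_data_error")
  cents <- bind_rows(imap(cmaps, function(cm, nm) {
    bind_cols(tibble(scenario = nm), habitat_centroid(cm, ...))
  }))
  n <- nrow(cents)
  p <- as.matrix(cents[, c("lon", "lat")])
  disp <- c(NA_real_,
            geosphere::distHaversine(p[-n, , drop = FALSE],
                                     p[-1, , drop = FALSE], r = 6371.0088))
  bear <- c(NA_real_,
            geosphere::bearing(p[-n, , drop = FALSE], p[-1, , drop = FALSE]))
  cents$displacement_km <- disp
  cents$bearing_deg <- bear
  structure(cents, class = c("centroid_track", class(cents)))
}

#' Scenario report: class areas, percent changes, change maps, centroids
#'
#' Builds the area table (one row per scenario, each suitability class and
#' the total with its percent change versus the baseline scenario), the
#' per-scenario change maps, and the centroid track.
#'
#' @param cmaps Named list of `class_map`s including the baseline.
#' @param baseline Name of the baseline scenario.
#' @param method Area method, see [class_areas()].
#' @return List: `areas` (tibble with `ratio_*` columns; baseline ratios
#'   `NA`), `change_maps` (named list, non-baseline scenarios),
#'   `centroids` (a [centroid_track()], or `NULL` with a single scenario).
#' @export
scenario_report <- function(cmaps, baseline, method = "geodesic") {
  if (!baseline %in% names(cmaps))
    abort(paste0("baseline scenario not found: ", baseline),
          class = "nichetrack_config_error")
  areas <- bind_rows(imap(cmaps, function(cm, nm)
    class_areas(cm, scenario = nm, method = method)))
  base <- areas[areas$scenario == baseline, ]
  ratio <- function(col) {
    out <- percent_change(areas[[col]], rep(base[[col]], nrow(areas)))
    out[areas$scenario == baseline] <- NA_real_
    out
  }
  areas$ratio_non <- ratio("area_non")
  areas$ratio_low <- ratio("area_low")
  areas$ratio_medium <- ratio("area_medium")
  areas$ratio_high <- ratio("area_high")
  areas$ratio_total_suitable <- ratio("area_total_suitable")
  areas <- areas[, c("scenario",
                     "area_non", "ratio_non", "area_low", "ratio_low",
                     "area_medium", "ratio_medium", "area_high", "ratio_high",
                     "area_total_suitable", "ratio_total_suitable")]
  others <- setdiff(names(cmaps), baseline)
  chmaps <- setNames(map(others, function(nm)
    change_map(cmaps[[baseline]], cmaps[[nm]])), others)
  cents <- if (length(cmaps) >= 2) centroid_track(cmaps) else NULL
  list(areas = areas, change_maps = chmaps, centroids = cents)
}
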