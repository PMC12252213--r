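#' Clean raw occurrence records
#'
#' Applies the mechanical cleaning rules, in order: records with missing or
#' unparseable coordinates are removed as `incomplete`; coordinates outside
#' the valid lon/lat ranges or at exactly (0, 0) are removed as `invalid`;
#' coordinates outside the study bounds (or falling on a nodata/masked cell
#' when `mask` is given) are removed as `out_of_bounds`; exact coordinate
#' duplicates are removed as `duplicate`, keeping the first in input order.
#' A provenance log counts removals per rule; the counts always reconcile with
#' input size minus output size.
#'
#' @param records Data frame with columns `lon`, `lat` and optionally
#'   `species`, `source`, `id`.
#' @param bounds Optional [grid_spec()] or numeric `c(xmin, xmax, ymin, ymax)`
#'   bounding box defining the study extent.
#' @param mask Optional `sdm_raster`; records on `NA`/zero cells are removed
#'   as out of bounds.
#' @param species Species name attached to the set; defaults to the first
#'   non-missing `species` value in `records`.
#' @return A tibble of retained records (class `occurrence_set`) with
#'   attributes `species`, `provenance` (named integer vector) and `removed`
#'   (tibble of discarded records with a `reason` column). Issues a warning if
#'   no records survive.
#' @export
clean_occurrences <- function(records, bounds = NULL, mask = NULL,
                              species = NULL) {
  rec <- as_tibble(records)
  n_in <- nrow(rec)
  if (is.null(species)) {
    if ("species" %in% names(rec) && any(!is.na(rec$species)))
      species <- rec$species[!is.na(rec$species)][1]
    else species <- "unknown"
  }
  rec$lon <- suppressWarnings(as.numeric(rec$lon))
  rec$lat <- suppressWarnings(as.numeric(rec$lat))
  reason <- rep(NA_character_, n_in)

  reason[is.na(rec$lon) | is.na(rec$lat)] <- "incomplete"

  ok <- is.na(reason)
  bad_range <- ok & (abs(rec$lon) > 180 | abs(rec$lat) > 90 |
                       (rec$lon == 0 & rec$lat == 0))
  reason[bad_range] <- "invalid"

  ok <- is.na(reason)
  if (!is.null(bounds) || !is.null(mask)) {
    if (is.null(bounds) && !is.null(mask)) bounds <- mask$spec
    bb <- if (inherits(bounds, "grid_spec")) {
      c(bounds$xllcorner, bounds$xllcorner + bounds$ncols * bounds$cellsize,
        bounds$yllcorner, bounds$yllcorner + bounds$nrows * bounds$cellsize)
    } else bounds
    oob <- ok & (rec$lon < bb[1] | rec$lon > bb[2] |
                   rec$lat < bb[3] | rec$lat > bb[4])
    if (!is.null(mask)) {
      inb <- ok & !oob
      if (any(inb)) {
        rc <- cell_of(rec$lon[inb], rec$lat[inb], mask$spec)
        mv <- mask$values[cbind(rc$row, rc$col)]
        masked <- is.na(mv) | mv == 0
        idx <- which(inb)[masked]
        oob[idx] <- TRUE
      }
    }
    reason[oob] <- "out_of_bounds"
  }

  ok <- is.na(reason)
  key <- paste(rec$lon, rec$lat)
  dup <- rep(FALSE, n_in)
  dup[ok] <- duplicated(key[ok])
  reason[dup] <- "duplicate"

  kept <- rec[is.na(reason), , drop = FALSE]
  removed <- rec[!is.na(reason), , drop = FALSE]
  removed$reason <- reason[!is.na(reason)]
  prov <- c(incomplete = sum(reason == "incomplete", na.rm = TRUE),
            invalid = sum(reason == "invalid", na.rm = TRUE),
            out_of_bounds = sum(reason == "out_of_bounds", na.rm = TRUE),
            duplicate = sum(reason == "duplicate", na.rm = TRUE))
  if (nrow(kept) == 0L)
    warn("no occurrence records survived cleaning")
  structure(kept,
            species = species, provenance = prov, removed = removed,
            class = c("occurrence_set", class(kept)))
}

#' Provenance counts of a cleaned occurrence set
#'
#' @param occ An `occurrence_set` from [clean_occurrences()] or
#'   [thin_occurrences()].
#' @return Named integer vector of records removed per cleaning rule.
#' @export
occ_provenance <- function(occ) attr(occ, "provenance")

#' Spatially thin occurrences to one record per grid cell
#'
#' Overlays a thinning grid of square cells (default 2.5 arc-minutes) anchored
#' at `origin` and keeps, for each occupied cell, the first record in input
#' order. Output preserves input order; thinning is idempotent.
#'
#' @param occ Data frame with `lon`, `lat` (typically an `occurrence_set`).
#' @param cellsize Thinning cell size in degrees; default `2.5/60`.
#' @param origin Length-2 numeric `c(lon, lat)` anchor of the thinning grid
#'   (typically the environmental grid's lower-left corner). Defaults to the
#'   floor of the data extent.
#' @return Tibble of retained records (class `occurrence_set`); attribute
#'   `thinned` holds the number of records removed.
#' @export
thin_occurrences <- function(occ, cellsize = 2.5 / 60, origin = NULL) {
  occ_tbl <- as_tibble(occ)
  if (nrow(occ_tbl) == 0L) return(occ)
  if (is.null(origin)) origin <- c(floor(min(occ_tbl$lon)), floor(min(occ_tbl$lat)))
  colb <- floor((occ_tbl$lon - origin[1]) / cellsize)
  rowb <- floor((occ_tbl$lat - origin[2]) / cellsize)
  key <- paste(rowb, colb)
  keep <- !duplicated(key)
  out <- occ_tbl[keep, , drop = FALSE]
  structure(out,
            species = attr(occ, "species") %||% "unknown",
            provenance = attr(occ, "provenance"),
            thinned = sum(!keep),
            thin_cellsize = cellsize, thin_origin = origin,
            class = unique(c("occurrence_set", class(out))))
}

#' Read occurrence records from CSV
#'
#' Expects columns `species`, `lon`, `lat` and optionally `source`/`id`.
#'
#' @param path CSV path.
#' @return Tibble of records.
#' @export
read_occurrences <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write occurrence records (and their audit trail) to CSV
#'
#' @param occ An `occurrence_set`.
#' @param path Output CSV path for retained records.
#' @param audit_path Optional path for the removed-records audit CSV.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path, audit_path = NULL) {
  out <- as_tibble(occ)
  if (!"species" %in% names(out))
    out <- bind_cols(tibble(species = attr(occ, "species") %||% "unknown"), out)
  readr::write_csv(out, path, progress = FALSE)
  if (!is.null(audit_path) && !is.null(attr(occ, "removed")))
    readr::write_csv(attr(occ, "removed"), audit_path, progress = FALSE)
  invisible(path)
}
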