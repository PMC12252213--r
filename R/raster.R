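#' Grid geometry for a regular lon/lat raster
#'
#' A `grid_spec` describes a regular geographic grid of square cells: the
#' number of columns and rows, the lower-left *corner* of the grid, the cell
#' size in decimal degrees, and the sentinel used for nodata cells on disk.
#' Row 1 of a raster matrix is the northernmost row (the ESRI ASCII grid
#' convention); internally nodata cells are stored as `NA`.
#'
#' @param ncols,nrows Grid dimensions (positive integers).
#' @param xllcorner,yllcorner Longitude/latitude of the lower-left corner, in
#'   decimal degrees.
#' @param cellsize Cell edge length in decimal degrees (cells are square).
#' @param nodata_value Sentinel written for nodata cells in ASCII output.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(ncols, nrows, xllcorner, yllcorner, cellsize,
                      nodata_value = -9999) {
  ncols <- as.integer(ncols); nrows <- as.integer(nrows)
  if (is.na(ncols) || is.na(nrows) || ncols < 1L || nrows < 1L)
    abort("ncols and nrows must be integers >= 1", class = "nichetrack_spec_error")
  if (!is.finite(cellsize) || cellsize <= 0)
    abort("cellsize must be > 0", class = "nichetrack_spec_error")
  tol <- 1e-9
  if (xllcorner < -180 - tol || xllcorner + ncols * cellsize > 180 + tol ||
      yllcorner < -90 - tol || yllcorner + nrows * cellsize > 90 + tol)
    abort("grid must fit within [-180,180] x [-90,90]",
          class = "nichetrack_spec_error")
  structure(list(ncols = ncols, nrows = nrows,
                 xllcorner = xllcorner, yllcorner = yllcorner,
                 cellsize = cellsize, nodata_value = nodata_value),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d cols x %d rows, cellsize %g deg, ll corner (%g, %g)\n",
              x$ncols, x$nrows, x$cellsize, x$xllcorner, x$yllcorner))
  invisible(x)
}

#' Test whether two grid specs share the same geometry
#'
#' Two specs are aligned iff ncols, nrows, the lower-left corner and the
#' cellsize agree within 1e-9 degrees. The nodata sentinel is not part of the
#' geometry.
#'
#' @param a,b `grid_spec` objects.
#' @return Logical scalar.
#' @export
grids_aligned <- function(a, b) {
  a$ncols == b$ncols && a$nrows == b$nrows &&
    abs(a$xllcorner - b$xllcorner) <= 1e-9 &&
    abs(a$yllcorner - b$yllcorner) <= 1e-9 &&
    abs(a$cellsize - b$cellsize) <= 1e-9
}

# name the first geometry field on which two specs differ (for error messages)
misaligned_field <- function(a, b) {
  if (a$ncols != b$ncols) return("ncols")
  if (a$nrows != b$nrows) return("nrows")
  if (abs(a$xllcorner - b$xllcorner) > 1e-9) return("xllcorner")
  if (abs(a$yllcorner - b$yllcorner) > 1e-9) return("yllcorner")
  "cellsize"
}

#' Construct a raster layer
#'
#' @param values Numeric matrix, `nrows x ncols`; row 1 is the northernmost
#'   row. Nodata cells are `NA`.
#' @param spec A [grid_spec()].
#' @param name Nonempty layer name (e.g. `"bio14"`).
#' @return An object of class `sdm_raster`.
#' @export
new_raster <- function(values, spec, name) {
  values <- as.matrix(values)
  if (!identical(dim(values), c(spec$nrows, spec$ncols)))
    abort(sprintf("values must be %d x %d, got %d x %d",
                  spec$nrows, spec$ncols, nrow(values), ncol(values)),
          class = "nichetrack_spec_error")
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    abort("name must be a nonempty string", class = "nichetrack_spec_error")
  if (any(is.infinite(values)))
    abort("raster values must be finite or NA", class = "nichetrack_spec_error")
  structure(list(spec = spec, values = unname(values), name = name),
            class = "sdm_raster")
}

#' @export
print.sdm_raster <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<sdm_raster> '%s' %dx%d, %d nodata, range [%g, %g]\n",
              x$name, x$spec$nrows, x$spec$ncols, sum(is.na(x$values)),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Read an ESRI ASCII grid
#'
#' Parses the 5-6 line header (`ncols`, `nrows`, `xllcorner`/`xllcenter`,
#' `yllcorner`/`yllcenter`, `cellsize`, optional `NODATA_value`) followed by
#' `nrows x ncols` numeric tokens. Center registration is converted to the
#' canonical corner registration by subtracting `cellsize/2`. Nodata tokens
#' become `NA`.
#'
#' @param path Path to a `.asc` file.
#' @param name Layer name; defaults to the file name without extension.
#' @return An `sdm_raster`.
#' @export
read_ascii_grid <- function(path, name = NULL) {
  if (!file.exists(path))
    abort(paste0("file not found: ", path), class = "nichetrack_io_error")
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1L
  repeat {
    if (i > length(lines)) break
    parts <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (length(parts) == 2L &&
        key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
                   "yllcenter", "cellsize", "nodata_value")) {
      hdr[[key]] <- as.numeric(parts[2]); i <- i + 1L
    } else break
  }
  for (key in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[key]]))
      abort(paste0("malformed ASCII grid header: missing key '", key, "'"),
            class = "nichetrack_format_error")
  }
  if (is.null(hdr$xllcorner) && is.null(hdr$xllcenter))
    abort("malformed ASCII grid header: missing key 'xllcorner'",
          class = "nichetrack_format_error")
  if (is.null(hdr$yllcorner) && is.null(hdr$yllcenter))
    abort("malformed ASCII grid header: missing key 'yllcorner'",
          class = "nichetrack_format_error")
  xll <- hdr$xllcorner %||% (hdr$xllcenter - hdr$cellsize / 2)
  yll <- hdr$yllcorner %||% (hdr$yllcenter - hdr$cellsize / 2)
  nodata <- hdr$nodata_value %||% -9999
  spec <- grid_spec(hdr$ncols, hdr$nrows, xll, yll, hdr$cellsize, nodata)
  body <- paste(lines[seq.int(i, length(lines))], collapse = " ")
  toks <- scan(text = body, what = numeric(), quiet = TRUE)
  want <- spec$nrows * spec$ncols
  if (length(toks) != want)
    abort(sprintf("ASCII grid body: expected %d values, found %d",
                  want, length(toks)),
          class = "nichetrack_format_error")
  vals <- matrix(toks, nrow = spec$nrows, ncol = spec$ncols, byrow = TRUE)
  vals[vals == nodata] <- NA_real_
  new_raster(vals, spec,
             name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write an ESRI ASCII grid
#'
#' Emits corner registration and full double precision (`%.17g`), so a
#' write/read round trip reproduces finite values bitwise. Nodata cells are
#' written as the spec's `nodata_value`.
#'
#' @param raster An `sdm_raster`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(raster, path) {
  spec <- raster$spec
  hdr <- c(sprintf("ncols %d", spec$ncols),
           sprintf("nrows %d", spec$nrows),
           sprintf("xllcorner %.17g", spec$xllcorner),
           sprintf("yllcorner %.17g", spec$yllcorner),
           sprintf("cellsize %.17g", spec$cellsize),
           sprintf("NODATA_value %.17g", spec$nodata_value))
  vals <- raster$values
  vals[is.na(vals)] <- spec$nodata_value
  rows <- apply(vals, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  ok <- tryCatch({
    writeLines(c(hdr, rows), path); TRUE
  }, error = function(e) FALSE, warning = function(e) FALSE)
  if (!ok) abort(paste0("cannot write ASCII grid to ", path),
                 class = "nichetrack_io_error")
  invisible(path)
}

#' Assemble aligned rasters into a stack
#'
#' @param rasters List of `sdm_raster` layers sharing one grid geometry and
#'   with unique names.
#' @param mask Optional `sdm_raster`; cells that are `NA` or `0` are excluded
#'   from the study region.
#' @return An object of class `sdm_stack`.
#' @export
assemble_stack <- function(rasters, mask = NULL) {
  if (length(rasters) == 0L)
    abort("need at least one raster", class = "nichetrack_spec_error")
  nms <- vapply(rasters, function(r) r$name, character(1))
  if (anyDuplicated(nms))
    abort(paste0("duplicate layer name: ", nms[duplicated(nms)][1]),
          class = "nichetrack_spec_error")
  ref <- rasters[[1]]$spec
  for (r in rasters[-1]) {
    if (!grids_aligned(ref, r$spec))
      abort(sprintf("layer '%s' is misaligned with '%s' (field %s differs)",
                    r$name, rasters[[1]]$name, misaligned_field(ref, r$spec)),
            class = "nichetrack_alignment_error")
  }
  if (!is.null(mask) && !grids_aligned(ref, mask$spec))
    abort("mask is misaligned with the stack",
          class = "nichetrack_alignment_error")
  structure(list(layers = setNames(rasters, nms), mask = mask, spec = ref),
            class = "sdm_stack")
}

#' @export
print.sdm_stack <- function(x, ...) {
  cat(sprintf("<sdm_stack> %d layers (%s) on %dx%d grid%s\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              x$spec$nrows, x$spec$ncols,
              if (is.null(x$mask)) "" else ", masked"))
  invisible(x)
}

stack_names <- function(stack) names(stack$layers)

#' Map lon/lat points to grid cells
#'
#' Cells are half-open `[west, east) x [south, north)`; points exactly on the
#' grid's north or east outer edge map to the last row/column. Rows are
#' 1-based with row 1 the northernmost row.
#'
#' @param lon,lat Numeric vectors of coordinates (degrees).
#' @param spec A [grid_spec()].
#' @return Tibble with integer columns `row`, `col`.
#' @export
cell_of <- function(lon, lat, spec) {
  tol <- 1e-9
  east <- spec$xllcorner + spec$ncols * spec$cellsize
  north <- spec$yllcorner + spec$nrows * spec$cellsize
  bad <- lon < spec$xllcorner - tol | lon > east + tol |
    lat < spec$yllcorner - tol | lat > north + tol
  if (any(bad))
    abort(sprintf("point(s) outside grid bounds: %s",
                  paste(sprintf("(%g, %g)", lon[bad], lat[bad]), collapse = ", ")),
          class = "nichetrack_bounds_error")
  col <- floor((lon - spec$xllcorner) / spec$cellsize) + 1L
  rowb <- floor((lat - spec$yllcorner) / spec$cellsize) + 1L # 1 = south band
  col <- pmin(pmax(col, 1L), spec$ncols)
  rowb <- pmin(pmax(rowb, 1L), spec$nrows)
  tibble(row = as.integer(spec$nrows - rowb + 1L), col = as.integer(col))
}

#' Cell-center coordinates for grid cells
#'
#' Inverse of [cell_of()] up to the cell interior: returns the lon/lat of each
#' cell's center.
#'
#' @param row,col 1-based row (north first) and column indices.
#' @param spec A [grid_spec()].
#' @return Tibble with columns `lon`, `lat`.
#' @export
cell_center <- function(row, col, spec) {
  tibble(lon = spec$xllcorner + (col - 0.5) * spec$cellsize,
         lat = spec$yllcorner + (spec$nrows - row + 0.5) * spec$cellsize)
}

#' Extract layer values at points
#'
#' @param points Data frame with columns `lon`, `lat` (plus anything else,
#'   carried through).
#' @param stack An `sdm_stack`.
#' @return Tibble: `point_id`, `lon`, `lat`, one column per layer, and a
#'   logical `nodata` flag set when any layer (or the mask) is nodata at the
#'   point. Flagged rows are retained, never dropped.
#' @export
extract_at_points <- function(points, stack) {
  points <- as_tibble(points)
  rc <- cell_of(points$lon, points$lat, stack$spec)
  idx <- cbind(rc$row, rc$col)
  out <- tibble(point_id = seq_len(nrow(points)),
                lon = points$lon, lat = points$lat)
  for (nm in stack_names(stack)) out[[nm]] <- stack$layers[[nm]]$values[idx]
  nod <- rowSums(is.na(as.matrix(out[stack_names(stack)]))) > 0
  if (!is.null(stack$mask)) {
    mv <- stack$mask$values[idx]
    nod <- nod | is.na(mv) | mv == 0
  }
  out$nodata <- nod
  out
}

#' Geodesic cell area by grid row
#'
#' Spherical-Earth area of one cell in the given row:
#' `R^2 * dlon_rad * (sin(phi_north) - sin(phi_south))` with
#' `R = 6371.0088` km, evaluated at the row's cell edges. Strictly positive
#' and decreasing toward the poles.
#'
#' @param spec A [grid_spec()].
#' @param row 1-based row indices (row 1 = northernmost).
#' @return Numeric vector of cell areas in km^2.
#' @export
cell_area_km2 <- function(spec, row) {
  R <- 6371.0088
  phi_n <- (spec$yllcorner + (spec$nrows - row + 1) * spec$cellsize) * pi / 180
  phi_s <- (spec$yllcorner + (spec$nrows - row) * spec$cellsize) * pi / 180
  R^2 * (spec$cellsize * pi / 180) * (sin(phi_n) - sin(phi_s))
}

#' Raster cells as a tibble
#'
#' Tidy accessor: one row per cell with indices, center coordinates, area and
#' value (or one column per layer for a stack). Masked-out cells are dropped
#' when the stack carries a mask.
#'
#' @param x An `sdm_raster` or `sdm_stack`.
#' @param drop_na Drop cells that are nodata in every layer (default `FALSE`).
#' @return Tibble with `row`, `col`, `lon`, `lat`, `area_km2`, value columns.
#' @export
cells <- function(x, drop_na = FALSE) {
  spec <- x$spec
  row <- rep(seq_len(spec$nrows), times = spec$ncols)
  col <- rep(seq_len(spec$ncols), each = spec$nrows)
  cc <- cell_center(row, col, spec)
  out <- tibble(row = row, col = col, lon = cc$lon, lat = cc$lat,
                area_km2 = cell_area_km2(spec, row))
  if (inherits(x, "sdm_raster")) {
    out[[x$name]] <- as.vector(x$values)
    val_cols <- x$name
  } else {
    for (nm in stack_names(x)) out[[nm]] <- as.vector(x$layers[[nm]]$values)
    if (!is.null(x$mask)) {
      mv <- as.vector(x$mask$values)
      out <- out[!is.na(mv) & mv != 0, , drop = FALSE]
    }
    val_cols <- stack_names(x)
  }
  if (drop_na) {
    keep <- rowSums(!is.na(as.matrix(out[val_cols]))) > 0
    out <- out[keep, , drop = FALSE]
  }
  out
}

# build a raster from a cells()-style tibble of (row, col, value)
raster_from_cells <- function(df, spec, value_col, name) {
  m <- matrix(NA_real_, spec$nrows, spec$ncols)
  m[cbind(df$row, df$col)] <- df[[value_col]]
  new_raster(m, spec, name)
}
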