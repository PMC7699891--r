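#' @keywords internal
"_PACKAGE"

#' Canonical land-use classes
#'
#' The seven landscape classes used throughout the package, as a named
#' integer vector (code = value, label = name).
#'
#' @format Named integer vector of length 7.
#' @export
landuse_classes <- c(
  cultivated = 1L, grass = 2L, forest = 3L, built_up = 4L,
  water = 5L, shrub = 6L, unused = 7L
)

#' Construct a categorical land-use raster
#'
#' A land-use raster is an integer matrix (row-major, north-up, cell-center
#' registration) plus georeference metadata. Every non-nodata cell must hold
#' one of the declared class codes.
#'
#' @param grid Integer matrix of class codes.
#' @param cell_size Cell edge length in metres (> 0).
#' @param origin Numeric length-2: (x, y) of the lower-left corner.
#' @param nodata Integer sentinel for missing cells.
#' @param classes Named integer vector of valid codes (default
#'   [landuse_classes]).
#' @return An object of class `land_raster`.
#' @export
land_raster <- function(grid, cell_size = 30, origin = c(0, 0),
                        nodata = -9999L, classes = landuse_classes) {
  grid <- as.matrix(grid)
  if (length(grid) == 0L) stop("empty raster grid")
  if (!is.numeric(cell_size) || cell_size <= 0) stop("cell_size must be > 0")
  storage.mode(grid) <- "integer"
  valid <- grid != nodata & !is.na(grid)
  if (!all(grid[valid] %in% classes)) {
    bad <- setdiff(unique(grid[valid]), classes)
    stop("grid holds codes outside the class set: ", paste(bad, collapse = ", "))
  }
  grid[is.na(grid)] <- as.integer(nodata)
  structure(
    list(grid = grid, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), nodata = as.integer(nodata),
         classes = classes),
    class = "land_raster"
  )
}

#' Construct a continuous-valued raster
#'
#' @param grid Numeric matrix; `NA` marks nodata.
#' @param cell_size Cell edge length in metres.
#' @param origin Numeric length-2 lower-left corner.
#' @param units Free-text unit string (e.g. "mm", "m").
#' @return An object of class `cont_raster`.
#' @export
cont_raster <- function(grid, cell_size = 30, origin = c(0, 0), units = "") {
  grid <- as.matrix(grid)
  if (length(grid) == 0L) stop("empty raster grid")
  storage.mode(grid) <- "double"
  if (any(is.infinite(grid))) stop("non-finite (infinite) values in raster")
  structure(
    list(grid = grid, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), units = units),
    class = "cont_raster"
  )
}

#' Construct a per-pixel ecosystem-service raster
#'
#' Wraps a continuous surface with the service name, its indicator
#' direction, and units. The nitrogen-export surface (WP) is the only
#' negative indicator: larger values mean worse water purification.
#'
#' @param grid Numeric matrix; `NA` marks nodata.
#' @param service_name One of `"CS"`, `"FR"`, `"SC"`, `"WP"`, `"HQ"`, `"CP"`.
#' @param direction `"positive"` or `"negative"`.
#' @param units Unit string.
#' @inheritParams cont_raster
#' @return An object of class `service_raster` (also a `cont_raster`).
#' @export
service_raster <- function(grid, service_name, direction = "positive",
                           cell_size = 30, origin = c(0, 0), units = "") {
  service_name <- match.arg(service_name, c("CS", "FR", "SC", "WP", "HQ", "CP"))
  direction <- match.arg(direction, c("positive", "negative"))
  if (direction == "negative" && service_name != "WP") {
    stop("only WP (nitrogen export) is a negative indicator")
  }
  r <- cont_raster(grid, cell_size, origin, units)
  r$service_name <- service_name
  r$direction <- direction
  class(r) <- c("service_raster", "cont_raster")
  r
}

#' @export
print.land_raster <- function(x, ...) {
  a <- class_areas(x)
  cat(sprintf("land_raster: %d x %d cells @ %g m, %d classes\n",
              nrow(x$grid), ncol(x$grid), x$cell_size, length(x$classes)))
  print(round(a, 4))
  invisible(x)
}

#' @export
print.cont_raster <- function(x, ...) {
  v <- x$grid[!is.na(x$grid)]
  cat(sprintf("%s: %d x %d cells @ %g m [%s], range %.4g .. %.4g\n",
              if (inherits(x, "service_raster")) paste0("service ", x$service_name)
              else "cont_raster",
              nrow(x$grid), ncol(x$grid), x$cell_size, x$units,
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Valid-cell logical mask of a raster
#' @param r A `land_raster` or `cont_raster`.
#' @return Logical matrix, `TRUE` where the cell carries data.
#' @export
valid_mask <- function(r) {
  if (inherits(r, "land_raster")) r$grid != r$nodata else !is.na(r$grid)
}

#' Test whether rasters share a common grid
#'
#' Rasters are aligned iff they have identical shape, cell size and origin.
#' Every pipeline stage refuses misaligned inputs.
#'
#' @param ... Two or more rasters.
#' @param strict If `TRUE`, raise an error instead of returning `FALSE`.
#' @return Logical scalar.
#' @export
align_check <- function(..., strict = FALSE) {
  rs <- list(...)
  if (length(rs) == 1L && is.list(rs[[1]]) && !inherits(rs[[1]], c("land_raster", "cont_raster"))) {
    rs <- rs[[1]]
  }
  if (length(rs) < 2L) stop("align_check needs at least two rasters")
  ref <- rs[[1]]
  ok <- all(vapply(rs[-1], function(r) {
    identical(dim(r$grid), dim(ref$grid)) &&
      isTRUE(all.equal(r$cell_size, ref$cell_size)) &&
      isTRUE(all.equal(r$origin, ref$origin))
  }, logical(1)))
  if (!ok && strict) stop("rasters are not aligned (shape/cell_size/origin differ)")
  ok
}

#' Per-class areas of a land-use raster
#'
#' @param lu A `land_raster`.
#' @return Named numeric vector of areas in km^2, one entry per declared
#'   class (absent classes report 0). Areas sum to the total non-nodata
#'   area.
#' @export
class_areas <- function(lu) {
  stopifnot(inherits(lu, "land_raster"))
  cell_km2 <- lu$cell_size^2 / 1e6
  counts <- vapply(lu$classes, function(k) sum(lu$grid == k), numeric(1))
  counts * cell_km2
}

#' Per-class cell counts
#' @param lu A `land_raster`.
#' @return Named integer vector of cell counts per declared class.
#' @export
class_counts <- function(lu) {
  vapply(lu$classes, function(k) sum(lu$grid == k), integer(1))
}

## ---- ESRI ASCII grid I/O -------------------------------------------------
## The format is six header lines (ncols, nrows, xllcorner, yllcorner,
## cellsize, NODATA_value) followed by nrows whitespace-separated rows,
## north row first.

#' Write a raster as an ESRI ASCII grid
#'
#' @param r A `land_raster` or `cont_raster`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path) {
  g <- r$grid
  nodata <- if (inherits(r, "land_raster")) r$nodata else -9999
  if (!inherits(r, "land_raster")) g[is.na(g)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(g)),
    sprintf("nrows %d", nrow(g)),
    sprintf("xllcorner %.10g", r$origin[1]),
    sprintf("yllcorner %.10g", r$origin[2]),
    sprintf("cellsize %.10g", r$cell_size),
    sprintf("NODATA_value %.10g", as.numeric(nodata))
  ), con)
  # row 1 of the matrix is the northernmost row, as stored
  write.table(g, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_ascii_header <- function(lines) {
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  hdr
}

#' Read an ESRI ASCII grid as a continuous raster
#'
#' @param path File path.
#' @param units Unit string to attach.
#' @return A `cont_raster`; nodata cells become `NA`.
#' @export
read_ascii_grid <- function(path, units = "") {
  if (!file.exists(path)) stop("cannot read raster: ", path)
  lines <- readLines(path)
  hdr <- read_ascii_header(lines)
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  g <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  g[g == hdr$nodata_value] <- NA_real_
  cont_raster(g, cell_size = hdr$cellsize,
              origin = c(hdr$xllcorner, hdr$yllcorner), units = units)
}

#' Read a categorical land-use raster
#'
#' Codes are remapped through `class_map`; codes absent from the map become
#' nodata and their count is reported with a warning.
#'
#' @param path ESRI ASCII grid path.
#' @param class_map Named integer vector mapping file codes (names) to class
#'   codes (values); default identity over [landuse_classes].
#' @param classes Valid class set of the result.
#' @return A `land_raster`.
#' @export
read_landuse <- function(path, class_map = stats::setNames(landuse_classes,
                                                           landuse_classes),
                         classes = landuse_classes) {
  r <- read_ascii_grid(path)
  g <- r$grid
  if (all(is.na(g))) stop("all-nodata land-use raster: ", path)
  out <- matrix(NA_integer_, nrow(g), ncol(g))
  known <- !is.na(g) & as.character(g) %in% names(class_map)
  out[known] <- as.integer(class_map[as.character(g[known])])
  n_unknown <- sum(!is.na(g) & !known)
  if (n_unknown > 0) {
    warning(sprintf("%d cells held codes absent from class_map; set to nodata",
                    n_unknown))
  }
  land_raster(out, cell_size = r$cell_size, origin = r$origin,
              classes = classes)
}

#' Write a land-use raster to an ESRI ASCII grid
#' @param lu A `land_raster`.
#' @param path Output path.
#' @export
write_landuse <- function(lu, path) write_ascii_grid(lu, path)

## ---- biophysical table ---------------------------------------------------

#' Validate a per-class biophysical parameter table
#'
#' Checks one row per land-use class and the documented ranges: carbon
#' densities (Ca, Cb, Cs, Cd, Mg C/ha) non-negative; USLE C and support-
#' practice factors, habitat suitability and threat sensitivities in [0, 1];
#' nitrogen export coefficient (kg/ha/yr) and root depth (mm) non-negative;
#' Kc positive.
#'
#' @param tab Data frame with a `class` column and the parameter columns.
#' @param classes Class set the table must cover.
#' @return `tab`, invisibly, or an error.
#' @export
validate_biophys <- function(tab, classes = landuse_classes) {
  need <- c("class", "Ca", "Cb", "Cs", "Cd", "usle_C", "usle_P",
            "habitat_H", "pol", "Kc", "root_depth")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("biophysical table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!setequal(tab$class, classes)) stop("biophysical table must have one row per class")
  bounded <- c("usle_C", "usle_P", "habitat_H",
               grep("^sens_", names(tab), value = TRUE))
  for (col in bounded) {
    if (any(tab[[col]] < 0 | tab[[col]] > 1)) stop(col, " outside [0, 1]")
  }
  for (col in c("Ca", "Cb", "Cs", "Cd", "pol", "root_depth")) {
    if (any(tab[[col]] < 0)) stop(col, " must be non-negative")
  }
  if (any(tab$Kc <= 0)) stop("Kc must be positive")
  invisible(tab)
}

#' Look up a per-class parameter over a land-use grid
#' @param lu A `land_raster`.
#' @param tab Biophysical table (one row per class).
#' @param col Column name to look up.
#' @return Numeric matrix aligned with `lu`, `NA` on nodata cells.
#' @export
class_lookup <- function(lu, tab, col) {
  if (!col %in% names(tab)) stop("no column '", col, "' in table")
  lut <- stats::setNames(tab[[col]], tab$class)
  out <- matrix(NA_real_, nrow(lu$grid), ncol(lu$grid))
  ok <- valid_mask(lu)
  out[ok] <- lut[as.character(lu$grid[ok])]
  out
}

## ---- small internal grid helpers ----------------------------------------

# Offsets of the 8 Moore neighbours in fixed order (ties in D8 and roulette
# tie-breaks depend on this order staying stable): E, SE, S, SW, W, NW, N, NE.
moore_offsets <- function() {
  cbind(dr = c(0, 1, 1, 1, 0, -1, -1, -1),
        dc = c(1, 1, 0, -1, -1, -1, 0, 1))
}

# Shift a matrix by (dr, dc), padding with `fill`.
shift_mat <- function(m, dr, dc, fill = NA) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  rok <- rs >= 1 & rs <= nr; cok <- cs >= 1 & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

# 1D squared distance transform (lower envelope of parabolas), exact.
edt_1d <- function(f) {
  n <- length(f)
  d <- numeric(n); v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
      if (s <= z[k] && k > 1L) k <- k - 1L else break
    }
    k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

# Euclidean distance (metres) from every cell to the nearest TRUE cell of
# `mask`; Inf when mask is empty. Exact EDT via separable parabola envelopes.
distance_to <- function(mask, cell_size = 1) {
  nr <- nrow(mask); nc <- ncol(mask)
  if (!any(mask)) return(matrix(Inf, nr, nc))
  big <- (nr + nc)^2 * 4
  f <- matrix(big, nr, nc)
  f[mask] <- 0
  if (nc > 1) f <- t(apply(f, 1, edt_1d)) else f <- f
  if (nr > 1) f <- apply(f, 2, edt_1d)
  sqrt(f) * cell_size
}
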