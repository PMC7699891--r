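## Water-mediated services: Budyko annual water yield, flood regulation,
## and nitrogen export routed over D8 flow paths.

#' Fill depressions in a DEM
#'
#' Planchon–Darboux style filling: water levels start at +Inf everywhere
#' except the grid edge and are iteratively lowered to
#' `max(z, min(neighbour) + eps)`. With `eps > 0` every interior cell of the
#' result has a strictly descending D8 path to the grid edge.
#'
#' @param dem A `cont_raster` of elevations (no `NA` cells).
#' @param eps Minimum per-step descent imposed inside filled depressions (m).
#' @return A `cont_raster` of filled elevations.
#' @export
fill_pits <- function(dem, eps = 1e-4) {
  z <- dem$grid
  if (any(is.na(z))) stop("fill_pits expects a complete (no-NA) DEM")
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3 || nc < 3) stop("DEM too small to route (< 3 x 3)")
  w <- matrix(Inf, nr, nc)
  edge <- matrix(FALSE, nr, nc)
  edge[1, ] <- TRUE; edge[nr, ] <- TRUE; edge[, 1] <- TRUE; edge[, nc] <- TRUE
  w[edge] <- z[edge]
  off <- moore_offsets()
  repeat {
    m <- matrix(Inf, nr, nc)
    for (k in seq_len(nrow(off))) {
      m <- pmin(m, shift_mat(w, off[k, 1], off[k, 2], fill = Inf) + eps)
    }
    w_new <- pmax(z, pmin(w, m))
    w_new[edge] <- z[edge]
    if (max(abs(w_new - w)[is.finite(w)]) < eps / 10 && !any(is.infinite(w_new))) {
      w <- w_new
      break
    }
    if (identical(w_new, w)) { w <- w_new; break }
    w <- w_new
  }
  cont_raster(w, dem$cell_size, dem$origin, units = dem$units)
}

#' Build a D8 flow graph from a DEM
#'
#' Pit-fills the DEM, then links every cell to its steepest-descent Moore
#' neighbour (drop divided by centre distance; ties broken by the fixed
#' neighbour order E, SE, S, SW, W, NW, N, NE). Cells with no lower
#' neighbour are outlets. The returned topological order lists cells by
#' strictly decreasing filled elevation, so accumulation can run in one
#' pass.
#'
#' @param dem A `cont_raster` of elevations.
#' @param eps Fill gradient passed to [fill_pits()].
#' @return A `flow_graph`: list with `receiver` (column-major cell index of
#'   the downslope neighbour, 0 for outlets), `order` (cell indices, upslope
#'   first), `filled` (the filled DEM), `dim`, `cell_size`.
#' @export
build_flow_graph <- function(dem, eps = 1e-4) {
  filled <- fill_pits(dem, eps)
  w <- filled$grid
  nr <- nrow(w); nc <- ncol(w)
  off <- moore_offsets()
  dist <- ifelse(off[, 1] != 0 & off[, 2] != 0, sqrt(2), 1) * dem$cell_size
  best_drop <- matrix(0, nr, nc)
  receiver <- matrix(0L, nr, nc)
  cell_id <- matrix(seq_len(nr * nc), nr, nc)
  for (k in seq_len(nrow(off))) {
    nb_w <- shift_mat(w, -off[k, 1], -off[k, 2], fill = Inf)
    nb_id <- shift_mat(cell_id, -off[k, 1], -off[k, 2], fill = 0L)
    drop <- (w - nb_w) / dist[k]
    better <- drop > best_drop
    best_drop[better] <- drop[better]
    receiver[better] <- nb_id[better]
  }
  ord <- order(w, decreasing = TRUE)
  structure(
    list(receiver = as.integer(receiver), order = as.integer(ord),
         filled = filled, dim = c(nr, nc), cell_size = dem$cell_size),
    class = "flow_graph"
  )
}

#' Accumulate a quantity down the flow graph
#'
#' Each cell's accumulated value is its own weight plus the accumulation of
#' every upslope cell draining through it (D8). With unit weights this is
#' the contributing-area cell count.
#'
#' @param flow A `flow_graph`.
#' @param weights Numeric matrix aligned with the DEM, or a scalar (default
#'   1). `NA` weights are treated as 0 for routing.
#' @return Numeric matrix of accumulated values (includes the cell itself).
#' @export
flow_accumulate <- function(flow, weights = 1) {
  n <- prod(flow$dim)
  if (length(weights) == 1L) {
    acc <- rep(as.numeric(weights), n)
  } else {
    acc <- as.numeric(weights)
    if (length(acc) != n) stop("weights not aligned with flow graph")
    acc[is.na(acc)] <- 0
  }
  rec <- flow$receiver
  for (i in flow$order) {
    r <- rec[i]
    if (r > 0L) acc[r] <- acc[r] + acc[i]
  }
  matrix(acc, flow$dim[1], flow$dim[2])
}

#' Watershed (basin) labels of a flow graph
#'
#' Every cell is labelled with the outlet it ultimately drains to.
#'
#' @param flow A `flow_graph`.
#' @return Integer matrix of basin ids (1..n_outlets).
#' @export
watersheds <- function(flow) {
  n <- prod(flow$dim)
  rec <- flow$receiver
  basin <- integer(n)
  next_id <- 0L
  for (i in rev(flow$order)) {   # downstream cells first
    r <- rec[i]
    if (r == 0L) {
      next_id <- next_id + 1L
      basin[i] <- next_id
    } else {
      basin[i] <- basin[r]
    }
  }
  matrix(basin, flow$dim[1], flow$dim[2])
}

#' Annual water yield (Budyko curve)
#'
#' Per cell, the evaporative fraction follows the Budyko-type curve
#' `AET/P = 1 + PET'/P - (1 + (PET'/P)^w)^(1/w)` with effective potential
#' evapotranspiration `PET' = Kc(class) * PET`, and yield
#' `Y = (1 - AET/P) * P` (mm). Open-water cells evaporate freely:
#' `Y = max(P - PET', 0)`. Cells with `P = 0` yield 0.
#'
#' @param precip Precipitation raster (mm), `cont_raster`.
#' @param pet Reference potential-evapotranspiration raster (mm).
#' @param lu Land-use raster (supplies per-class `Kc`).
#' @param table Biophysical table with a `Kc` column.
#' @param omega Budyko shape parameter, scalar >= 1 or aligned matrix.
#' @param water_class Class code(s) treated as open water.
#' @return List: `raster` (a `service_raster`, name "FR" source "mm" —
#'   actually the yield surface, positive = more runoff), `aet` matrix, and
#'   the mean yield. The yield raster is returned as a `cont_raster` with
#'   units "mm".
#' @export
water_yield <- function(precip, pet, lu, table, omega = 3,
                        water_class = landuse_classes[["water"]]) {
  align_check(precip, pet, lu, strict = TRUE)
  if (any(omega < 1)) stop("Budyko omega must be >= 1")
  p <- precip$grid
  if (any(p < 0, na.rm = TRUE) || any(pet$grid < 0, na.rm = TRUE)) {
    stop("negative precipitation or PET")
  }
  kc <- class_lookup(lu, table, "Kc")
  pet_eff <- kc * pet$grid
  ratio <- ifelse(p > 0, pet_eff / p, Inf)
  aet_frac <- 1 + ratio - (1 + ratio^omega)^(1 / omega)
  y <- (1 - aet_frac) * p
  y[p == 0] <- 0
  is_water <- lu$grid %in% water_class
  y[is_water] <- pmax(p[is_water] - pet_eff[is_water], 0)
  bad <- !valid_mask(lu) | is.na(p) | is.na(pet$grid)
  y[bad] <- NA_real_
  aet <- p - y
  list(
    raster = cont_raster(y, precip$cell_size, precip$origin, units = "mm"),
    aet = aet,
    mean = mean(y, na.rm = TRUE)
  )
}

#' Flood-regulation capacity from annual water yield
#'
#' `FR = (Ymax - Y) / (Ymax - Ymin)`: cells that shed the most water
#' regulate floods least. When comparing several maps, pass joint
#' `extremes` so the surfaces share a scale.
#'
#' @param yield Water-yield `cont_raster` (mm).
#' @param extremes Optional `c(min, max)` to normalize against; defaults to
#'   the raster's own range.
#' @return List: `raster` (a `service_raster` "FR" in [0, 1]) and its mean.
#' @export
flood_regulation <- function(yield, extremes = NULL) {
  y <- yield$grid
  if (is.null(extremes)) extremes <- range(y, na.rm = TRUE)
  if (diff(extremes) <= 0) {
    warning("degenerate (constant) water yield; FR set to 1 everywhere")
    fr <- ifelse(is.na(y), NA_real_, 1)
  } else {
    fr <- (extremes[2] - y) / (extremes[2] - extremes[1])
    fr <- pmin(pmax(fr, 0), 1)
  }
  list(
    raster = service_raster(fr, "FR", "positive", yield$cell_size,
                            yield$origin, units = ""),
    mean = mean(fr, na.rm = TRUE)
  )
}

#' Log-accumulated runoff index
#'
#' `lambda = log(sum of water yield over the flow path above the cell,
#' including the cell)`, natural log. Cells whose accumulated yield is zero
#' (or negative input) are `NA`.
#'
#' @param flow A `flow_graph`.
#' @param yield Water-yield `cont_raster` (mm, >= 0).
#' @return Numeric matrix of runoff indices.
#' @export
runoff_index <- function(flow, yield) {
  y <- yield$grid
  if (any(y < 0, na.rm = TRUE)) stop("negative water yield")
  acc <- flow_accumulate(flow, y)
  lam <- ifelse(acc > 0, log(acc), NA_real_)
  lam[is.na(y)] <- NA_real_
  lam
}

#' Nitrogen export (water purification, negative indicator)
#'
#' Per cell, the adjusted load is `ALV = HSS * pol * cell_ha`, where
#' `HSS = lambda / mean(lambda over the cell's watershed)` is the hydrologic
#' sensitivity score and `pol` the per-class nitrogen export coefficient
#' (kg/ha/yr). Watersheds are the D8 basins of the flow graph. Mean HSS is
#' 1 in every watershed by construction.
#'
#' @param lu Land-use raster.
#' @param table Biophysical table with a `pol` column.
#' @param flow A `flow_graph` aligned with `lu`.
#' @param yield Water-yield `cont_raster` (mm).
#' @return List: `raster` (`service_raster` "WP", kg/yr per cell, negative
#'   indicator), `hss` matrix, `total` (kg/yr), `by_watershed` data frame.
#' @export
nitrogen_export <- function(lu, table, flow, yield) {
  align_check(lu, yield, strict = TRUE)
  lam <- runoff_index(flow, yield)
  basin <- watersheds(flow)
  lam_mean <- rep(NA_real_, max(basin))
  ok <- !is.na(lam)
  means <- tapply(lam[ok], basin[ok], mean)
  lam_mean[as.integer(names(means))] <- means
  if (any(!is.na(means) & means == 0)) stop("watershed mean runoff index is 0")
  hss <- lam / lam_mean[basin]
  cell_ha <- lu$cell_size^2 / 1e4
  pol <- class_lookup(lu, table, "pol")
  alv <- hss * pol * cell_ha
  alv[!valid_mask(lu)] <- NA_real_
  bw <- data.frame(
    watershed = sort(unique(basin[ok])),
    export_kg = as.numeric(tapply(alv[ok], basin[ok], sum, na.rm = TRUE))
  )
  list(
    raster = service_raster(alv, "WP", "negative", lu$cell_size, lu$origin,
                            units = "kg/yr"),
    hss = hss,
    total = sum(alv, na.rm = TRUE),
    by_watershed = bw
  )
}
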