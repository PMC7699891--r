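## Land-based services: carbon storage, soil conservation (RKLS - USLE),
## habitat quality under distance-decayed threats, district crop production.

#' Carbon storage per cell and landscape total
#'
#' `CS = A_x * (Ca + Cb + Cs + Cd)` with `A_x` the cell area in hectares
#' and the four pools (aboveground, belowground, soil, dead matter) read
#' per class from the biophysical table (Mg C / ha).
#'
#' @param lu A `land_raster`.
#' @param table Biophysical table with columns Ca, Cb, Cs, Cd.
#' @return List: `raster` (`service_raster` "CS", Mg C per cell) and
#'   `total` (Mg C).
#' @export
carbon_storage <- function(lu, table) {
  dens <- class_lookup(lu, table, "Ca") + class_lookup(lu, table, "Cb") +
    class_lookup(lu, table, "Cs") + class_lookup(lu, table, "Cd")
  cell_ha <- lu$cell_size^2 / 1e4
  cs <- dens * cell_ha
  list(
    raster = service_raster(cs, "CS", "positive", lu$cell_size, lu$origin,
                            units = "Mg C"),
    total = sum(cs, na.rm = TRUE)
  )
}

#' USLE LS (topographic) factor
#'
#' `LS = (A_s / 22.13)^0.5 * (sin(theta) / 0.0896)^1.35` with `A_s` the
#' unit contributing area (D8 contributing cells x cell width, metres),
#' capped at a 122 m slope length to bound ridge artifacts.
#'
#' @param flow A `flow_graph`.
#' @param dem The DEM the graph was built from.
#' @param cap Slope-length cap in metres (default 122).
#' @return Numeric matrix of LS values.
#' @export
ls_factor <- function(flow, dem, cap = 122) {
  n_up <- flow_accumulate(flow, 1)
  a_s <- pmin(n_up * dem$cell_size, cap)
  theta <- slope_raster(dem)$grid
  (a_s / 22.13)^0.5 * (sin(theta) / 0.0896)^1.35
}

#' Soil conservation (RKLS minus USLE)
#'
#' `usle = R * K * LS * C * P_practice` is actual erosion under cover and
#' support practices, `RKLS = R * K * LS` is potential (bare-soil) erosion,
#' and the service is the soil retained, `SC = RKLS - usle =
#' RKLS * (1 - C * P_practice)` (tons/cell/yr after scaling by cell area
#' in ha).
#'
#' @param erosivity Rainfall-erosivity raster R (MJ mm / (ha h yr)).
#' @param erodibility Soil-erodibility raster K (t ha h / (ha MJ mm)).
#' @param dem DEM raster.
#' @param lu Land-use raster.
#' @param table Biophysical table with `usle_C` and `usle_P` columns.
#' @param flow Optional pre-built `flow_graph` (built from `dem` if NULL).
#' @return List: `raster` (`service_raster` "SC", tons/yr per cell),
#'   `rkls`, `usle` matrices (tons/yr per cell), `total` (tons/yr).
#' @export
soil_conservation <- function(erosivity, erodibility, dem, lu, table,
                              flow = NULL) {
  align_check(erosivity, erodibility, dem, lu, strict = TRUE)
  if (any(erosivity$grid < 0, na.rm = TRUE) ||
      any(erodibility$grid < 0, na.rm = TRUE)) stop("R and K must be >= 0")
  if (is.null(flow)) flow <- build_flow_graph(dem)
  ls <- ls_factor(flow, dem)
  cfac <- class_lookup(lu, table, "usle_C")
  pfac <- class_lookup(lu, table, "usle_P")
  if (any(cfac * pfac > 1, na.rm = TRUE)) stop("C x P_practice exceeds 1")
  cell_ha <- lu$cell_size^2 / 1e4
  rkls <- erosivity$grid * erodibility$grid * ls * cell_ha
  usle <- rkls * cfac * pfac
  sc <- rkls - usle
  sc[!valid_mask(lu)] <- NA_real_
  list(
    raster = service_raster(sc, "SC", "positive", lu$cell_size, lu$origin,
                            units = "t/yr"),
    rkls = rkls, usle = usle,
    total = sum(sc, na.rm = TRUE)
  )
}

#' Specify a habitat threat
#'
#' @param class Threat source: a land-use class label (cells of that class
#'   are sources) or a logical matrix of source cells.
#' @param max_dist Maximum influence distance (m), > 0.
#' @param weight Relative threat weight in [0, 1].
#' @param decay `"linear"` or `"exponential"` distance decay.
#' @return A `threat_spec`.
#' @export
threat_spec <- function(class, max_dist, weight = 1, decay = c("linear", "exponential")) {
  decay <- match.arg(decay)
  if (max_dist <= 0) stop("max_dist must be > 0")
  if (weight < 0 || weight > 1) stop("weight must be in [0, 1]")
  structure(list(class = class, max_dist = max_dist, weight = weight,
                 decay = decay), class = "threat_spec")
}

#' Habitat quality under distance-decayed threats
#'
#' Per threat r, the impact at a cell is
#' `i_r = weight_r * decay(d / max_dist_r)` with linear decay `1 - d/dmax`
#' or exponential decay `exp(-2.99 d / dmax)`, zero beyond `max_dist`. The
#' total degradation is the sensitivity-weighted sum over threats clipped
#' to [0, 1] (clipping rather than weight-renormalization keeps Q monotone
#' in the threat set: removing a threat can never lower quality), and
#' habitat quality is `Q = H * (1 - D)`: 1 is the best attainable quality.
#'
#' Threat sensitivities are read from table columns `sens_<threat class>`
#' (a missing column means "insensitive"). A threat class absent from the
#' map contributes zero impact, with a warning.
#'
#' @param lu A `land_raster`.
#' @param table Biophysical table with `habitat_H` and sensitivity columns.
#' @param threats List of [threat_spec()] objects.
#' @return List: `raster` (`service_raster` "HQ" in [0, 1]), `degradation`
#'   matrix, `mean` habitat quality.
#' @export
habitat_quality <- function(lu, table, threats = list()) {
  h <- class_lookup(lu, table, "habitat_H")
  n_thr <- length(threats)
  if (n_thr == 0L) {
    q <- h
    deg <- matrix(0, nrow(h), ncol(h))
  } else {
    deg <- matrix(0, nrow(lu$grid), ncol(lu$grid))
    for (t in threats) {
      if (is.matrix(t$class)) {
        src <- t$class
        sens_col <- NULL
      } else {
        src <- matrix(lu$grid == landuse_classes[[t$class]],
                      nrow(lu$grid), ncol(lu$grid))
        sens_col <- paste0("sens_", t$class)
      }
      if (!any(src)) {
        warning("threat class '", t$class, "' absent from the map; impact 0")
        next
      }
      d <- distance_to(src, lu$cell_size)
      imp <- switch(t$decay,
                    linear = pmax(1 - d / t$max_dist, 0),
                    exponential = ifelse(d > t$max_dist, 0,
                                         exp(-2.99 * d / t$max_dist)))
      sens <- if (!is.null(sens_col) && sens_col %in% names(table)) {
        class_lookup(lu, table, sens_col)
      } else matrix(1, nrow(lu$grid), ncol(lu$grid))
      deg <- deg + t$weight * imp * sens
    }
    deg <- pmin(pmax(deg, 0), 1)
    q <- h * (1 - deg)
  }
  q[!valid_mask(lu)] <- NA_real_
  list(
    raster = service_raster(q, "HQ", "positive", lu$cell_size, lu$origin,
                            units = ""),
    degradation = deg,
    mean = mean(q, na.rm = TRUE)
  )
}

#' District crop production
#'
#' `PRO_G = sum_i A_i * R_Gi * P_Gi` and likewise for vegetables and
#' fruits, over districts i: `A_i` district area (ha), `R_*` the area
#' proportion under each crop, `P_*` the yield (t/ha). When a land-use map
#' and a reference map are supplied, each district's production is scaled
#' by its change in cultivated cells, so scenarios feed through. The CP
#' raster spreads each district's total evenly over its cultivated cells
#' (so the service can enter the summed indicator and correlations on the
#' common grid); the tonnage totals are the authoritative output.
#'
#' @param districts District table (columns district, A, R_G, R_V, R_F,
#'   P_G, P_V, P_F).
#' @param district_raster Integer matrix of district ids, aligned with any
#'   supplied `lu`.
#' @param lu Optional `land_raster` for the cultivated-area scaling and the
#'   CP surface.
#' @param ref_lu Optional baseline `land_raster`; scaling factor is
#'   cultivated cells in `lu` / cultivated cells in `ref_lu` per district.
#' @return List: `by_district` data frame (grain, vegetable, fruit, total
#'   tons), `total` (tons), and `raster` (`service_raster` "CP", tons per
#'   cultivated cell; `NULL` when `lu` is missing).
#' @export
crop_production <- function(districts, district_raster, lu = NULL,
                            ref_lu = NULL) {
  need <- c("district", "A", "R_G", "R_V", "R_F", "P_G", "P_V", "P_F")
  if (!all(need %in% names(districts))) stop("district table lacks required columns")
  if (any(districts$R_G + districts$R_V + districts$R_F > 1 + 1e-9)) {
    stop("crop area proportions exceed the district area")
  }
  if (any(districts[c("P_G", "P_V", "P_F")] < 0)) stop("yields must be >= 0")
  scale <- rep(1, nrow(districts))
  if (!is.null(lu) && !is.null(ref_lu)) {
    cult <- landuse_classes[["cultivated"]]
    for (i in seq_len(nrow(districts))) {
      d <- districts$district[i]
      in_d <- district_raster == d
      n_ref <- sum(ref_lu$grid[in_d] == cult)
      n_now <- sum(lu$grid[in_d] == cult)
      if (n_ref > 0) scale[i] <- n_now / n_ref
    }
  }
  grain <- districts$A * districts$R_G * districts$P_G * scale
  veg <- districts$A * districts$R_V * districts$P_V * scale
  fruit <- districts$A * districts$R_F * districts$P_F * scale
  by_d <- data.frame(district = districts$district, grain = grain,
                     vegetable = veg, fruit = fruit,
                     total = grain + veg + fruit)
  ras <- NULL
  if (!is.null(lu)) {
    cult <- landuse_classes[["cultivated"]]
    cp <- matrix(0, nrow(lu$grid), ncol(lu$grid))
    for (i in seq_len(nrow(by_d))) {
      cells <- which(district_raster == by_d$district[i] & lu$grid == cult)
      if (length(cells)) cp[cells] <- by_d$total[i] / length(cells)
    }
    # cultivated cells in a district with no table row are an error
    seen <- unique(district_raster[lu$grid == cult])
    if (!all(seen %in% districts$district)) {
      stop("district(s) with cultivated cells but no table row: ",
           paste(setdiff(seen, districts$district), collapse = ", "))
    }
    cp[!valid_mask(lu)] <- NA_real_
    ras <- service_raster(cp, "CP", "positive", lu$cell_size, lu$origin,
                          units = "t")
  }
  list(by_district = by_d, total = sum(by_d$total), raster = ras)
}
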