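## Fully synthetic study regions: paired land-use maps with a known
## transition matrix, driver stacks, climate/soil layers and parameter
## tables, so the whole pipeline is testable without external data.

#' Specification of a synthetic study region
#'
#' @param shape Integer length-2, (rows, cols).
#' @param cell_size Cell edge (m), default 30 as in typical land-use grids.
#' @param seed Integer; fixes every generated layer bit-identically.
#' @param class_fractions Named numeric over the 7 classes, summing to 1.
#' @param true_transition 7x7 row-stochastic matrix: the ground-truth
#'   class-transition probabilities applied between the two generated maps.
#' @param driver_count Number of driver layers to emit (default 14).
#' @param autocorr Spatial autocorrelation length (cells) of generated
#'   fields.
#' @param relief Relief amplitude of the DEM (m).
#' @param min_elev Minimum elevation (m).
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(shape = c(100, 100), cell_size = 30, seed = 1L,
                           class_fractions = c(cultivated = 0.14, grass = 0.10,
                                               forest = 0.38, built_up = 0.06,
                                               water = 0.04, shrub = 0.26,
                                               unused = 0.02),
                           true_transition = default_transition(),
                           driver_count = 14L, autocorr = 8,
                           relief = 800, min_elev = 20) {
  stopifnot(length(shape) == 2, all(shape >= 3))
  if (abs(sum(class_fractions) - 1) > 1e-8) stop("class_fractions must sum to 1")
  if (!all(names(class_fractions) == names(landuse_classes))) {
    stop("class_fractions must be named over the 7 canonical classes")
  }
  rs <- rowSums(true_transition)
  if (any(abs(rs - 1) > 1e-9)) stop("true_transition rows must sum to 1")
  if (any(true_transition < 0 | true_transition > 1)) stop("transition entries outside [0,1]")
  structure(
    list(shape = as.integer(shape), cell_size = cell_size, seed = as.integer(seed),
         class_fractions = class_fractions, true_transition = true_transition,
         driver_count = as.integer(driver_count), autocorr = autocorr,
         relief = relief, min_elev = min_elev),
    class = "synthetic_spec"
  )
}

#' Default ground-truth transition matrix
#'
#' A mild urbanising/afforesting regime: most land persists; cultivated
#' land leaks to built-up and forest, grass and shrub to forest, unused to
#' grass — the kind of net change a 15-year interval in a peri-urban
#' mountain region shows.
#'
#' @return 7x7 row-stochastic matrix with class-named dimnames.
#' @export
default_transition <- function() {
  cls <- names(landuse_classes)
  m <- diag(7)
  dimnames(m) <- list(cls, cls)
  m["cultivated", ] <- c(0.82, 0.02, 0.06, 0.08, 0.00, 0.02, 0.00)
  m["grass", ]      <- c(0.03, 0.85, 0.08, 0.02, 0.00, 0.02, 0.00)
  m["forest", ]     <- c(0.00, 0.01, 0.97, 0.01, 0.00, 0.01, 0.00)
  m["built_up", ]   <- c(0.02, 0.00, 0.00, 0.98, 0.00, 0.00, 0.00)
  m["water", ]      <- c(0.02, 0.00, 0.00, 0.03, 0.95, 0.00, 0.00)
  m["shrub", ]      <- c(0.00, 0.02, 0.08, 0.01, 0.00, 0.89, 0.00)
  m["unused", ]     <- c(0.04, 0.10, 0.02, 0.04, 0.00, 0.00, 0.80)
  m
}

# Gaussian-smoothed white noise with edge renormalisation; the kernel sd
# (in cells) sets the autocorrelation length.
gaussian_field <- function(nr, nc, sigma) {
  noise <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (sigma <= 0) return(noise)
  h <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-h:h, sd = sigma)
  smooth_1d <- function(m, along_rows) {
    acc <- matrix(0, nrow(m), ncol(m))
    norm <- matrix(0, nrow(m), ncol(m))
    ones <- matrix(1, nrow(m), ncol(m))
    for (i in seq_along(w)) {
      s <- i - h - 1L
      if (along_rows) {
        acc <- acc + shift_mat(m, 0, s, fill = 0) * w[i]
        norm <- norm + shift_mat(ones, 0, s, fill = 0) * w[i]
      } else {
        acc <- acc + shift_mat(m, s, 0, fill = 0) * w[i]
        norm <- norm + shift_mat(ones, s, 0, fill = 0) * w[i]
      }
    }
    acc / norm
  }
  smooth_1d(smooth_1d(noise, TRUE), FALSE)
}

# Rescale a matrix to [lo, hi]; constant input maps to lo.
rescale01 <- function(m, lo = 0, hi = 1) {
  rng <- range(m, na.rm = TRUE)
  if (diff(rng) == 0) return(matrix(lo, nrow(m), ncol(m)))
  lo + (m - rng[1]) / (rng[2] - rng[1]) * (hi - lo)
}

#' Generate a synthetic DEM
#'
#' A smoothed random field scaled to `[min_elev, min_elev + relief]`. After
#' pit filling every cell has a monotone descending D8 path to the edge, so
#' the hydrology stages can route over it.
#'
#' @param spec A `synthetic_spec`.
#' @return A `cont_raster` of elevations (m).
#' @export
make_dem <- function(spec) {
  if (any(spec$shape < 3)) stop("degenerate DEM shape (< 3 x 3)")
  set.seed(stage_seed(spec$seed, "dem"))
  f <- gaussian_field(spec$shape[1], spec$shape[2], spec$autocorr)
  # gentle regional tilt keeps large depressions rare
  tilt <- outer(seq_len(spec$shape[1]), seq_len(spec$shape[2]),
                function(r, c) 0.3 * r / spec$shape[1] + 0.2 * c / spec$shape[2])
  z <- rescale01(f + tilt * stats::sd(f) * 2, spec$min_elev,
                 spec$min_elev + spec$relief)
  cont_raster(z, spec$cell_size, units = "m")
}

# Elevation ordering of classes used to lay out the initial map:
# water in valley floors, built-up and cultivated on low ground, grass on
# mid slopes, shrub and forest on high ground, unused land highest.
class_elevation_order <- c("water", "built_up", "cultivated", "grass",
                           "shrub", "forest", "unused")

#' Generate a pair of land-use maps with known transitions
#'
#' The initial map `t0` assigns classes by banding a fuzzed elevation
#' percentile (water low, forest/shrub high), which reproduces the
#' elevation structure of a mountain conservation area and makes the DEM a
#' genuinely informative driver. The later map `t1` applies the spec's
#' ground-truth transition matrix class-wise: within each origin class,
#' cells are ranked by a smooth random field and contiguous rank blocks
#' (sized by randomized rounding of the transition row) switch to each
#' target, so changes arrive as spatial clusters rather than salt-and-
#' pepper flips. Realized frequencies converge to the ground truth as the
#' cell count grows.
#'
#' @param spec A `synthetic_spec`.
#' @param dem The DEM from [make_dem()] (aligned).
#' @return List with `t0`, `t1` (both `land_raster`).
#' @export
make_landuse_pair <- function(spec, dem) {
  if (!all(dim(dem$grid) == spec$shape)) stop("dem not aligned with spec")
  set.seed(stage_seed(spec$seed, "landuse"))
  nr <- spec$shape[1]; nc <- spec$shape[2]; n <- nr * nc
  fr <- spec$class_fractions
  # fuzzed elevation percentile -> quantile bands sized by class fractions
  fuzz <- gaussian_field(nr, nc, spec$autocorr / 2)
  key <- rank(dem$grid + fuzz * stats::sd(dem$grid) * 0.35,
              ties.method = "first")
  band_sizes <- diff(round(cumsum(c(0, fr[class_elevation_order])) * n))
  if (any(band_sizes < 0) || sum(band_sizes) != n) stop("infeasible class_fractions")
  codes_by_band <- rep(landuse_classes[class_elevation_order], band_sizes)
  t0 <- matrix(0L, nr, nc)
  t0[order(key)] <- as.integer(codes_by_band)

  # apply the ground-truth transitions with clustered, adjacency-seeking
  # change: cells switching to class j prefer cells close to existing
  # class-j patches (smooth affinity + noise), so the changes grow from
  # the patch edges and a neighbourhood-aware allocator can learn them
  t1 <- t0
  M <- spec$true_transition
  decay_m <- max(2, spec$autocorr) * spec$cell_size
  affinity <- lapply(seq_len(7), function(j) {
    mask <- t0 == j
    base <- if (any(mask)) exp(-distance_to(mask, spec$cell_size) / decay_m)
            else matrix(0, nr, nc)
    base + 0.25 * rescale01(gaussian_field(nr, nc, spec$autocorr / 2))
  })
  for (i in seq_len(7)) {
    cells <- which(t0 == i)
    ni <- length(cells)
    if (ni == 0L) next
    p <- M[i, ]
    counts <- floor(p * ni)
    rem <- ni - sum(counts)
    if (rem > 0) {
      frac <- p * ni - counts
      bump <- order(frac, decreasing = TRUE)[seq_len(rem)]
      counts[bump] <- counts[bump] + 1L
    }
    remaining <- cells
    targets <- setdiff(order(counts, decreasing = TRUE), i)
    for (j in targets) {
      if (counts[j] == 0L || !length(remaining)) next
      take <- remaining[order(affinity[[j]][remaining],
                              decreasing = TRUE)[seq_len(min(counts[j], length(remaining)))]]
      t1[take] <- as.integer(j)
      remaining <- setdiff(remaining, take)
    }
  }
  list(
    t0 = land_raster(t0, spec$cell_size),
    t1 = land_raster(t1, spec$cell_size)
  )
}

#' Generate the driver stack
#'
#' Emits the standard 14 change drivers: terrain derivatives of the DEM
#' (slope, aspect, relief amplitude), socio-economic and climate fields as
#' autocorrelated noise (GDP, population, precipitation, temperature with
#' an elevation lapse, soil attribute), and distance surfaces to randomly
#' seeded roads, rivers (valley cells), residential areas (sampled from the
#' built-up class), traffic stations and hazard points. The DEM itself is
#' included; temperature and the terrain layers are genuinely informative
#' of class membership because the initial map is elevation-banded.
#'
#' @param spec A `synthetic_spec`.
#' @param dem DEM raster.
#' @param lu Land-use raster used to seed residential distances.
#' @return Named list of `cont_raster` layers.
#' @export
make_drivers <- function(spec, dem, lu) {
  align_check(dem, lu, strict = TRUE)
  set.seed(stage_seed(spec$seed, "drivers"))
  nr <- spec$shape[1]; nc <- spec$shape[2]
  cs <- spec$cell_size
  z <- dem$grid
  sl <- slope_raster(dem)
  asp <- aspect_raster(dem)

  focal_range <- matrix(0, nr, nc)
  off <- moore_offsets()
  mx <- z; mn <- z
  for (k in seq_len(nrow(off))) {
    nb <- shift_mat(z, off[k, 1], off[k, 2], fill = NA)
    mx <- pmax(mx, nb, na.rm = TRUE); mn <- pmin(mn, nb, na.rm = TRUE)
  }
  focal_range <- mx - mn

  smooth <- function(lo, hi) {
    cont_raster(rescale01(gaussian_field(nr, nc, spec$autocorr), lo, hi), cs)
  }
  seed_cells <- function(n_feat, bias = NULL) {
    prob <- if (is.null(bias)) NULL else rescale01(bias, 0.01, 1)
    idx <- sample.int(nr * nc, n_feat, prob = prob)
    m <- matrix(FALSE, nr, nc); m[idx] <- TRUE; m
  }
  dist_layer <- function(mask) cont_raster(distance_to(mask, cs), cs, units = "m")

  rivers <- seed_cells(max(5L, nr * nc %/% 400L), bias = max(z) - z)
  roads <- seed_cells(max(5L, nr * nc %/% 500L), bias = max(z) - z)
  resid_mask <- matrix(lu$grid == landuse_classes[["built_up"]], nr, nc)
  if (!any(resid_mask)) resid_mask <- seed_cells(3L)
  stations <- seed_cells(max(3L, nr * nc %/% 1500L))
  hazards <- seed_cells(max(3L, nr * nc %/% 1500L), bias = sl$grid)

  drivers <- list(
    dem = dem,
    slope = sl,
    aspect = asp,
    relief = cont_raster(focal_range, cs, units = "m"),
    gdp = smooth(50, 5000),
    precipitation = cont_raster(
      rescale01(gaussian_field(nr, nc, spec$autocorr), 450, 700) +
        0.08 * (z - min(z)), cs, units = "mm"),
    temperature = cont_raster(
      14 - 0.0065 * (z - min(z)) +
        rescale01(gaussian_field(nr, nc, spec$autocorr), -0.5, 0.5),
      cs, units = "degC"),
    dist_road = dist_layer(roads),
    dist_residential = dist_layer(resid_mask),
    dist_station = dist_layer(stations),
    dist_river = dist_layer(rivers),
    dist_hazard = dist_layer(hazards),
    soil = smooth(0, 1),
    population = smooth(10, 2000)
  )
  drivers[seq_len(min(spec$driver_count, length(drivers)))]
}

#' Slope raster (radians) from a DEM
#' @param dem A `cont_raster` of elevations.
#' @return A `cont_raster` of slope angles (radians), central differences.
#' @export
slope_raster <- function(dem) {
  z <- dem$grid; cs <- dem$cell_size
  dzdx <- (shift_mat(z, 0, -1, NA) - shift_mat(z, 0, 1, NA)) / (2 * cs)
  dzdy <- (shift_mat(z, -1, 0, NA) - shift_mat(z, 1, 0, NA)) / (2 * cs)
  # one-sided differences on the border
  dzdx[is.na(dzdx)] <- 0; dzdy[is.na(dzdy)] <- 0
  cont_raster(atan(sqrt(dzdx^2 + dzdy^2)), cs, dem$origin, units = "rad")
}

#' Aspect raster (radians from east, CCW) from a DEM
#' @param dem A `cont_raster` of elevations.
#' @return A `cont_raster`; flat cells report 0.
#' @export
aspect_raster <- function(dem) {
  z <- dem$grid; cs <- dem$cell_size
  dzdx <- (shift_mat(z, 0, -1, NA) - shift_mat(z, 0, 1, NA)) / (2 * cs)
  dzdy <- (shift_mat(z, -1, 0, NA) - shift_mat(z, 1, 0, NA)) / (2 * cs)
  dzdx[is.na(dzdx)] <- 0; dzdy[is.na(dzdy)] <- 0
  cont_raster(atan2(-dzdy, -dzdx), cs, dem$origin, units = "rad")
}

#' Generate parameter tables for a synthetic region
#'
#' Produces a biophysical table with plausible, range-respecting values
#' (forest carbon-rich and erosion-resistant, cultivated land nutrient-
#' leaky, built-up land with zero habitat suitability and zero cover
#' factor), a district crop table, the default service weights, and the
#' default threat specifications (built-up and cultivated land as threats).
#'
#' @param spec A `synthetic_spec`.
#' @return List: `biophys`, `districts`, `weights`, `threats`.
#' @export
make_tables <- function(spec) {
  cls <- names(landuse_classes)
  biophys <- data.frame(
    class = as.integer(landuse_classes),
    label = cls,
    #           cult  grass forest built  water shrub unused
    Ca        = c(5.7,  3.0, 45.0,  1.2,  0.0, 24.0,  0.6),
    Cb        = c(1.1,  8.0,  9.5,  0.3,  0.0,  6.0,  0.2),
    Cs        = c(80,  100,  140,   30,    0,  120,   40),
    Cd        = c(0.5,  1.0,  3.5,  0.0,  0.0,  2.0,  0.1),
    usle_C    = c(0.22, 0.08, 0.003, 0.0, 0.0, 0.01, 0.30),
    usle_P    = c(0.35, 1.0,  1.0,   1.0, 1.0, 1.0,  1.0),
    habitat_H = c(0.40, 0.60, 1.00,  0.0, 0.70, 0.85, 0.10),
    sens_built_up  = c(0.50, 0.60, 0.80, 0.0, 0.70, 0.75, 0.20),
    sens_cultivated = c(0.00, 0.35, 0.50, 0.0, 0.45, 0.45, 0.10),
    pol       = c(11.0, 3.0,  1.8,  8.0,  0.0,  2.2,  4.0),
    Kc        = c(0.65, 0.65, 1.00, 0.30, 1.10, 0.80, 0.20),
    root_depth = c(500, 700, 3000,  10,    1, 2000,  200)
  )
  validate_biophys(biophys)
  districts <- data.frame(
    district = 1:4,
    A = rep(NA_real_, 4),            # filled from the district raster (ha)
    R_G = c(0.30, 0.20, 0.10, 0.05),
    R_V = c(0.15, 0.20, 0.05, 0.05),
    R_F = c(0.10, 0.15, 0.30, 0.20),
    P_G = c(5.5, 5.0, 4.5, 4.0),
    P_V = c(30, 28, 24, 20),
    P_F = c(10, 11, 12, 9)
  )
  threats <- list(
    threat_spec("built_up", max_dist = 1200, weight = 1.0, decay = "exponential"),
    threat_spec("cultivated", max_dist = 500, weight = 0.6, decay = "linear")
  )
  list(biophys = biophys, districts = districts,
       weights = default_weights(), threats = threats)
}

#' Default ecosystem-service weights
#'
#' The weighting used for the summed indicator: carbon storage 0.1596,
#' flood regulation 0.1688, water purification 0.0875, soil conservation
#' 0.1396, habitat quality 0.1574, crop production 0.0964. The weights do
#' not sum to 1 and are used as-is unless renormalization is requested.
#'
#' @return Named numeric vector over CS, FR, WP, SC, HQ, CP.
#' @export
default_weights <- function() {
  c(CS = 0.1596, FR = 0.1688, WP = 0.0875, SC = 0.1396, HQ = 0.1574,
    CP = 0.0964)
}

#' Generate a complete synthetic study region
#'
#' Runs every generator in sequence and assembles climate, soil and
#' erosivity layers plus a 2x2 quadrant district raster, with the district
#' areas filled in from the grid. The manifest records the ground-truth
#' transition matrix.
#'
#' @param spec A `synthetic_spec`.
#' @return List: `spec`, `dem`, `t0`, `t1`, `drivers`, `precip`, `pet`,
#'   `erosivity`, `erodibility`, `paw` (plant-available water fraction),
#'   `districts` (raster), `tables`, `manifest`.
#' @export
synth_region <- function(spec) {
  dem <- make_dem(spec)
  pair <- make_landuse_pair(spec, dem)
  drivers <- make_drivers(spec, dem, pair$t0)
  tables <- make_tables(spec)
  set.seed(stage_seed(spec$seed, "climate"))
  nr <- spec$shape[1]; nc <- spec$shape[2]; cs <- spec$cell_size
  precip <- drivers$precipitation
  pet <- cont_raster(
    rescale01(gaussian_field(nr, nc, spec$autocorr), 850, 1100) -
      0.05 * (dem$grid - min(dem$grid)), cs, units = "mm")
  pet$grid[pet$grid < 0] <- 0
  erosivity <- cont_raster(rescale01(gaussian_field(nr, nc, spec$autocorr),
                                     1500, 5000), cs, units = "MJ mm/(ha h yr)")
  erodibility <- cont_raster(rescale01(gaussian_field(nr, nc, spec$autocorr),
                                       0.08, 0.45), cs, units = "t ha h/(ha MJ mm)")
  paw <- cont_raster(rescale01(gaussian_field(nr, nc, spec$autocorr),
                               0.05, 0.25), cs, units = "")
  dist_grid <- matrix(1L, nr, nc)
  dist_grid[seq_len(nr) > nr / 2, ] <- dist_grid[seq_len(nr) > nr / 2, ] + 2L
  dist_grid[, seq_len(nc) > nc / 2] <- dist_grid[, seq_len(nc) > nc / 2] + 1L
  tables$districts$A <- vapply(1:4, function(d) {
    sum(dist_grid == d) * cs^2 / 1e4
  }, numeric(1))
  list(
    spec = spec, dem = dem, t0 = pair$t0, t1 = pair$t1, drivers = drivers,
    precip = precip, pet = pet, erosivity = erosivity,
    erodibility = erodibility, paw = paw,
    districts = dist_grid, tables = tables,
    manifest = list(seed = spec$seed, shape = spec$shape,
                    true_transition = spec$true_transition)
  )
}

# Derive a reproducible, stage-specific seed (< 2^31) from a global seed.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483647)
}
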