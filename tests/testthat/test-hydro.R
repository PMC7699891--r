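test_that("Budyko water yield matches direct evaluation and limits", {
  tab <- unit_kc_table()
  lu <- toy_lu(rep(1, 9), nrow = 3)   # cultivated everywhere, Kc = 1
  mk <- function(v) cont_raster(matrix(v, 3, 3), 30)
  # P = PET = 1000, omega = 3: AET/P = 2 - 2^(1/3), Y = P (2^(1/3) - 1)
  wy <- water_yield(mk(1000), mk(1000), lu, tab, omega = 3)
  expect_equal(wy$raster$grid[1, 1], 1000 * (2^(1 / 3) - 1), tolerance = 1e-9)
  expect_equal(wy$raster$grid[1, 1], 259.921, tolerance = 1e-3)
  # PET -> 0 gives AET -> 0, Y -> P
  wy0 <- water_yield(mk(800), mk(0), lu, tab)
  expect_equal(wy0$raster$grid, matrix(800, 3, 3))
  # P = 0 cells are defined as zero yield
  wyz <- water_yield(mk(0), mk(500), lu, tab)
  expect_true(all(wyz$raster$grid == 0))
  expect_error(water_yield(mk(-1), mk(500), lu, tab), "negative")
  expect_error(water_yield(mk(1), mk(1), lu, tab, omega = 0.5), "omega")
})

test_that("Budyko bounds hold over random draws and omega is monotone", {
  tab <- unit_kc_table()
  set.seed(42)
  n <- 100
  lu <- toy_lu(rep(1, n * n), nrow = n)
  p <- matrix(runif(n * n, 1, 2000), n, n)
  pet <- matrix(runif(n * n, 0, 2500), n, n)
  wy <- water_yield(cont_raster(p, 30), cont_raster(pet, 30), lu, tab)
  aet <- wy$aet
  expect_true(all(aet >= -1e-9))
  expect_true(all(aet <= pmin(p, pet) + 1e-9))
  # higher omega -> more evapotranspiration -> less yield
  wy_hi <- water_yield(cont_raster(p, 30), cont_raster(pet, 30), lu, tab,
                       omega = 5)
  expect_true(all(wy_hi$raster$grid <= wy$raster$grid + 1e-9))
})

test_that("flood regulation rescales yield extremes to {1, 0}", {
  y <- cont_raster(matrix(c(0, 50, 100, 25, 75, 100, 0, 50, 25), 3, 3), 30)
  fr <- flood_regulation(y)
  expect_equal(fr$raster$grid[y$grid == 0], c(1, 1))
  expect_equal(fr$raster$grid[y$grid == 100], c(0, 0))
  expect_equal(fr$raster$grid[y$grid == 50], c(0.5, 0.5))
  expect_warning(fr2 <- flood_regulation(cont_raster(matrix(5, 3, 3), 30)),
                 "degenerate")
  expect_true(all(fr2$raster$grid == 1))
  # FR is invariant to affine rescaling of the yield surface
  y2 <- cont_raster(y$grid * 3.7 + 12, 30)
  expect_equal(flood_regulation(y2)$raster$grid, fr$raster$grid)
})

test_that("D8 routing drains an east-sloping plane east", {
  z <- matrix(rep(seq(50, 10, length.out = 10), each = 8), 8, 10)
  flow <- build_flow_graph(cont_raster(z, 30))
  rec <- matrix(flow$receiver, 8, 10)
  id <- matrix(seq_len(80), 8, 10)
  # every non-eastern-border cell drains to its eastern neighbour
  expect_true(all(rec[, -10] == id[, -1]))
  # eastern border cells are outlets
  expect_true(all(rec[, 10] == 0))
})

test_that("pit filling removes interior pits and routes every cell out", {
  z <- matrix(100, 9, 9) + outer(1:9, 1:9, function(r, c) r + c)
  z[5, 5] <- 1   # deep interior pit
  dem <- cont_raster(z, 30)
  flow <- build_flow_graph(dem)
  # no cycles and every cell reaches an outlet
  for (i in seq_len(81)) {
    j <- i; steps <- 0
    while (flow$receiver[j] != 0L) {
      j <- flow$receiver[j]; steps <- steps + 1
      expect_lt(steps, 100)
    }
  }
  expect_true(all(flow$filled$grid >= z - 1e-12))
})

test_that("flow accumulation equals exhaustive path enumeration", {
  set.seed(8)
  for (trial in 1:4) {
    n <- sample(6:20, 1)
    z <- matrix(rnorm(n * n, 100, 10), n, n)
    flow <- build_flow_graph(cont_raster(z, 30))
    expect_equal(flow_accumulate(flow), brute_force_accumulation(flow))
    w <- matrix(runif(n * n), n, n)
    expect_equal(flow_accumulate(flow, w), brute_force_accumulation(flow, w))
  }
  # accumulation over all outlets partitions the grid: totals = cell count
  z <- outer(1:9, 1:9, function(r, c) abs(c - 5) * 10 + r)   # V-valley
  flow <- build_flow_graph(cont_raster(z, 30))
  acc <- flow_accumulate(flow)
  expect_equal(sum(acc[flow$receiver == 0]), 81)
  # basin membership count equals the accumulation at its outlet
  basin <- watersheds(flow)
  outlet_cells <- which(flow$receiver == 0)
  for (i in outlet_cells) {
    expect_equal(acc[i], sum(basin == basin[i]))
  }
})

test_that("runoff index accumulates and is monotone downstream", {
  # east-flowing chain of 3 interior cells with uniform yield
  z <- matrix(rep(c(30, 20, 10), each = 3), 3, 3)
  flow <- build_flow_graph(cont_raster(z, 30))
  y <- cont_raster(matrix(exp(1), 3, 3), 30)
  acc <- flow_accumulate(flow, y$grid)
  expect_equal(sort(unique(round(as.vector(acc / exp(1)), 9))), c(1, 2, 3))
  lam <- runoff_index(flow, y)
  # headwater cells (accumulation = e) have lambda = 1, natural log
  expect_equal(unique(lam[acc == exp(1)]), 1)
  # monotone along each west-to-east path
  expect_true(all(lam[, 1] <= lam[, 2] & lam[, 2] <= lam[, 3]))
  expect_error(runoff_index(flow, cont_raster(matrix(-1, 3, 3), 30)),
               "negative")
})

test_that("nitrogen export scales with pol and HSS averages 1 per basin", {
  r <- small_region()
  flow <- build_flow_graph(r$dem)
  tab <- r$tables$biophys
  wy <- water_yield(r$precip, r$pet, r$t1, tab)
  ne <- nitrogen_export(r$t1, tab, flow, wy$raster)
  basin <- watersheds(flow)
  ok <- !is.na(ne$hss)
  means <- tapply(ne$hss[ok], basin[ok], mean)
  expect_true(all(abs(means - 1) < 1e-6))
  # pol = 0 class exports nothing regardless of HSS
  water_cells <- r$t1$grid == landuse_classes[["water"]]
  expect_true(all(ne$raster$grid[water_cells & ok] == 0))
  # doubling pol doubles the landscape total (linearity)
  tab2 <- tab; tab2$pol <- tab2$pol * 2
  ne2 <- nitrogen_export(r$t1, tab2, flow, wy$raster)
  expect_equal(ne2$total, 2 * ne$total, tolerance = 1e-12)
})
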