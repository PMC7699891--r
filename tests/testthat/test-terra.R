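test_that("carbon storage is cell area times summed pool densities", {
  tab <- make_tables(synthetic_spec(seed = 1))$biophys
  tab[tab$class == 1, c("Ca", "Cb", "Cs", "Cd")] <- c(40, 10, 60, 2)
  lu <- toy_lu(1, nrow = 1)
  cs <- carbon_storage(lu, tab)
  expect_equal(cs$raster$grid[1, 1], 0.09 * 112)   # 10.08 Mg C per 30 m cell
  expect_equal(cs$total, 10.08)

  # zero densities give zero storage
  tab0 <- tab
  tab0[c("Ca", "Cb", "Cs", "Cd")] <- 0
  expect_equal(carbon_storage(small_region()$t1, tab0)$total, 0)

  # aggregation oracle: total equals sum over classes of area_ha x density
  r <- small_region()
  cs2 <- carbon_storage(r$t1, r$tables$biophys)
  b <- r$tables$biophys
  dens <- b$Ca + b$Cb + b$Cs + b$Cd
  area_ha <- class_counts(r$t1) * 0.09
  expect_equal(cs2$total, sum(area_ha * dens[match(landuse_classes, b$class)]),
               tolerance = 1e-9)
})

test_that("soil conservation factorizes as RKLS (1 - C P)", {
  r <- small_region()
  sc <- soil_conservation(r$erosivity, r$erodibility, r$dem, r$t1,
                          r$tables$biophys)
  cfac <- class_lookup(r$t1, r$tables$biophys, "usle_C")
  pfac <- class_lookup(r$t1, r$tables$biophys, "usle_P")
  # cell-exact identity SC = RKLS - usle = RKLS (1 - C P)
  expect_equal(sc$raster$grid, sc$rkls - sc$usle, tolerance = 1e-12)
  expect_equal(sc$raster$grid, sc$rkls * (1 - cfac * pfac), tolerance = 1e-12)
  # zero-cover classes (water, built-up) retain everything: SC = RKLS
  zero_c <- cfac == 0
  expect_equal(sc$raster$grid[zero_c], sc$rkls[zero_c])
  # retention is non-negative for any valid table
  expect_true(all(sc$raster$grid >= 0, na.rm = TRUE))
  # invalid table rejected
  bad <- r$tables$biophys; bad$usle_C <- 1; bad$usle_P <- 1.0
  bad$usle_C[1] <- 1; bad$usle_P[1] <- 1.01
  expect_error(validate_biophys(bad), "usle_P")
})

test_that("LS factor responds to contributing area and caps slope length", {
  z <- matrix(rep(seq(100, 10, length.out = 20), each = 10), 10, 20)
  dem <- cont_raster(z, 30)
  flow <- build_flow_graph(dem)
  ls <- ls_factor(flow, dem)
  # interior row: LS grows with accumulated area until the 122 m cap
  acc <- flow_accumulate(flow)
  capped <- acc * 30 >= 122
  expect_true(all(diff(ls[5, 1:4]) > 0))
  # constant once capped (interior cells; border slope is one-sided zero)
  inner <- which(capped[5, ] & seq_len(20) < 20)
  expect_equal(length(unique(round(ls[5, inner], 9))), 1L)
})

test_that("habitat quality degrades with threat proximity and sensitivity", {
  tab <- make_tables(synthetic_spec(seed = 1))$biophys
  # a forest strip with one built-up threat cell in the corner
  g <- matrix(3L, 9, 9); g[1, 1] <- 4L
  lu <- land_raster(g, 30)
  thr <- list(threat_spec("built_up", max_dist = 300, weight = 1, decay = "linear"))
  hq <- habitat_quality(lu, tab, thr)
  h_forest <- tab$habitat_H[tab$class == 3]
  # adjacent cell is more degraded than a distant one (monotone decay)
  expect_lt(hq$raster$grid[1, 2], hq$raster$grid[9, 9])
  # beyond max_dist the threat has no effect: Q = H
  expect_equal(hq$raster$grid[9, 9], h_forest)
  # no threats anywhere: Q = H for every class
  hq0 <- habitat_quality(lu, tab, list())
  expect_equal(hq0$raster$grid, class_lookup(lu, tab, "habitat_H"))
  # zero sensitivity leaves Q = H regardless of threats
  tab_ins <- tab; tab_ins$sens_built_up <- 0
  hq_ins <- habitat_quality(lu, tab_ins, thr)
  expect_equal(hq_ins$raster$grid[2, 2], h_forest)
  # absent threat class warns and contributes nothing
  g2 <- matrix(3L, 5, 5)
  expect_warning(
    hq_abs <- habitat_quality(land_raster(g2, 30), tab,
                              list(threat_spec("cultivated", 300, 1))),
    "absent")
  expect_equal(hq_abs$raster$grid, matrix(h_forest, 5, 5))
  # Q bounded in [0, 1]; removing a threat never decreases Q
  r <- small_region()
  hq_full <- habitat_quality(r$t1, r$tables$biophys, r$tables$threats)
  expect_true(all(hq_full$raster$grid >= 0 & hq_full$raster$grid <= 1,
                  na.rm = TRUE))
  hq_less <- habitat_quality(r$t1, r$tables$biophys, r$tables$threats[1])
  expect_true(all(hq_less$raster$grid >= hq_full$raster$grid - 1e-12,
                  na.rm = TRUE))
})

test_that("crop production is the district sum of area x share x yield", {
  d <- data.frame(district = 1, A = 100, R_G = 0.5, R_V = 0, R_F = 0,
                  P_G = 5, P_V = 30, P_F = 10)
  dr <- matrix(1L, 4, 4)
  cp <- crop_production(d, dr)
  expect_equal(cp$by_district$grain, 250)
  expect_equal(cp$total, 250)
  # zero shares produce nothing; halving areas halves totals
  d0 <- d; d0$R_G <- 0
  expect_equal(crop_production(d0, dr)$total, 0)
  dh <- d; dh$A <- 50
  expect_equal(crop_production(dh, dr)$total, cp$total / 2)

  # CP surface spreads the district total over its cultivated cells
  g <- matrix(c(rep(1L, 4), rep(3L, 12)), 4, 4)
  lu <- land_raster(g, 30)
  cp2 <- crop_production(d, dr, lu)
  expect_equal(sum(cp2$raster$grid[g == 1]), cp2$total)
  expect_true(all(cp2$raster$grid[g != 1] == 0))
  # a district with cultivated cells but no table row is an error
  dr2 <- dr; dr2[1, 1] <- 9L
  expect_error(crop_production(d, dr2, lu), "no table row")
  # proportions must not exceed the district area
  dbad <- d; dbad$R_V <- 0.6
  expect_error(crop_production(dbad, dr), "exceed")
})
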