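test_that("transition fitting counts cell transitions row-stochastically", {
  # printed toy: 8 cells stay cultivated, 2 become grass
  t0 <- toy_lu(rep(1, 10), nrow = 2)
  t1 <- toy_lu(c(rep(1, 8), 2, 2), nrow = 2)
  M <- fit_transition(t0, t1)
  expect_equal(unname(M["cultivated", c("cultivated", "grass")]), c(0.8, 0.2))
  expect_equal(unname(rowSums(M)), rep(1, 7), tolerance = 1e-12)
  # identity when nothing changes; empty classes keep identity rows
  Mi <- fit_transition(t0, t0)
  expect_equal(unclass(Mi), diag(7), ignore_attr = TRUE)
  expect_error(fit_transition(t0, toy_lu(rep(1, 12), nrow = 3)), "not aligned")
})

test_that("demand projection is the Markov product plus renormalized adjustments", {
  # two-class toy: areas (100, 100) km2, M = [[0.9, 0.1], [0, 1]]
  classes <- c(A = 1L, B = 2L)
  g <- matrix(c(rep(1L, 50), rep(2L, 50)), 10, 10)
  lu <- land_raster(g, cell_size = sqrt(2e6), classes = classes)  # 2 km2/cell
  M <- structure(matrix(c(0.9, 0, 0.1, 1), 2, 2,
                        dimnames = list(names(classes), names(classes))),
                 step = 15, class = c("transition_matrix", "matrix"))
  d <- project_demand(lu, M)
  expect_equal(unname(d), c(90, 110))
  expect_equal(sum(d), sum(class_areas(lu)))

  # identity M returns current areas
  Mi <- structure(diag(2), dimnames = list(names(classes), names(classes)),
                  class = c("transition_matrix", "matrix"))
  expect_equal(unname(project_demand(lu, Mi)), unname(class_areas(lu)))

  # RUD-style boost: built-up demand is 1.5 x Markov, others scaled to
  # conserve the total area
  r <- small_region()
  Mfull <- fit_transition(r$t0, r$t1)
  raw <- project_demand(r$t1, Mfull)
  rud <- project_demand(r$t1, Mfull, scenario_rud(builtup_adjust = 1.5))
  expect_equal(rud[["built_up"]], 1.5 * raw[["built_up"]])
  expect_equal(sum(rud), sum(raw), tolerance = 1e-9)
  others <- setdiff(names(raw), "built_up")
  ratio <- rud[others] / raw[others]
  expect_lt(diff(range(ratio)), 1e-9)   # proportional scale-down
})

test_that("suitability surfaces are calibrated, learnable and reproducible", {
  r <- small_region()
  # pure-noise drivers: mean predicted probability tracks class prevalence
  set.seed(1)
  noise <- list(n1 = cont_raster(matrix(rnorm(3600), 60, 60), 30),
                n2 = cont_raster(matrix(rnorm(3600), 60, 60), 30))
  s_noise <- fit_suitability(r$t1, noise, model = "multinom", seed = 2)
  prev <- class_counts(r$t1) / sum(class_counts(r$t1))
  pm <- apply(matrix(s_noise$prob, ncol = 7), 2, mean)
  expect_true(all(abs(pm - prev) < 0.05))

  # real drivers beat permuted labels out of sample
  s_real <- fit_suitability(r$t1, r$drivers, seed = 2)
  pred <- apply(matrix(s_real$prob, ncol = 7), 1, which.max)
  acc_real <- mean(landuse_classes[pred] == as.vector(r$t1$grid))
  set.seed(3)
  shuf <- r$t1
  shuf$grid <- matrix(sample(as.vector(r$t1$grid)), 60, 60)
  s_perm <- fit_suitability(shuf, r$drivers, seed = 2)
  pred_p <- apply(matrix(s_perm$prob, ncol = 7), 1, which.max)
  acc_perm <- mean(landuse_classes[pred_p] == as.vector(r$t1$grid))
  expect_gt(acc_real, acc_perm + 0.1)

  # a perfectly separable single driver is learned almost exactly
  g <- matrix(rep(1:4, each = 225), 30, 30)
  lu_sep <- land_raster(g, 30)
  driver <- list(x = cont_raster(matrix(rep(c(0, 10, 20, 30), each = 225),
                                        30, 30) + rnorm(900, 0, 0.1), 30))
  s_sep <- fit_suitability(lu_sep, driver, seed = 4, sample_frac = 0.5)
  pred_sep <- apply(matrix(s_sep$prob, ncol = 7), 1, which.max)
  expect_gt(mean(pred_sep == as.vector(g)), 0.95)

  # determinism under seed
  s_a <- fit_suitability(r$t1, r$drivers, seed = 9)
  s_b <- fit_suitability(r$t1, r$drivers, seed = 9)
  expect_identical(s_a$prob, s_b$prob)
  # per-cell probabilities sum to 1
  expect_equal(rowSums(matrix(s_a$prob, ncol = 7))[1:100], rep(1, 100),
               tolerance = 1e-6)
})

test_that("CA allocation meets demand and honours constraints", {
  r <- small_region()
  suit <- fit_suitability(r$t1, r$drivers, seed = 2)
  M <- fit_transition(r$t0, r$t1)

  # nothing to allocate: output equals input
  same <- allocate_ca(r$t1, suit, class_areas(r$t1), seed = 1)
  expect_identical(same$grid, r$t1$grid)
  expect_true(attr(same, "converged"))

  # demand satisfaction within 1% per class, several seeds
  dem <- project_demand(r$t1, M, scenario_rud())
  cell_km2 <- 900 / 1e6
  for (sd in 1:5) {
    out <- allocate_ca(r$t1, suit, dem, scenario_rud(), seed = sd)
    got <- class_counts(out)
    want <- dem / cell_km2
    expect_true(all(abs(got - want) <= pmax(0.01 * want, 1.5)))
  }

  # frozen cells never change; forbidden conversions never occur
  mask <- matrix(FALSE, 60, 60); mask[1:30, 1:30] <- TRUE
  allowed <- matrix(TRUE, 7, 7)
  allowed[landuse_classes[["forest"]], landuse_classes[["built_up"]]] <- FALSE
  sc <- scenario_config("custom", restriction_mask = mask, allowed = allowed)
  # demand may be infeasible under these constraints: reported, not forced
  out <- suppressWarnings(allocate_ca(r$t1, suit, dem, sc, seed = 3))
  expect_true(all(out$grid[mask] == r$t1$grid[mask]))
  was_forest <- r$t1$grid == landuse_classes[["forest"]]
  expect_false(any(out$grid[was_forest] == landuse_classes[["built_up"]]))

  # conversions favour suitable cells: converted-to-built-up cells sit
  # above the median built-up suitability of the donor pool
  out_r <- allocate_ca(r$t1, suit, dem, scenario_rud(), seed = 7)
  conv <- which(out_r$grid == 4 & r$t1$grid != 4)
  pb <- matrix(suit$prob, ncol = 7)[, 4]
  donors <- which(r$t1$grid != 4)
  expect_gt(mean(pb[conv]), median(pb[donors], na.rm = TRUE))

  # conservation: total cells and valid codes
  expect_equal(sum(class_counts(out_r)), sum(valid_mask(r$t1)))
  expect_true(all(out_r$grid %in% c(landuse_classes, out_r$nodata)))

  # infeasible demand errors out
  bad <- class_areas(r$t1) * 2
  expect_error(allocate_ca(r$t1, suit, bad, seed = 1), "exceeds")
})

test_that("figure of merit equals B/(A+B+C+D) on hand counts", {
  # 10 cells: 7 observed changes (5 missed, 2 hit), 3 false alarms
  t0 <- toy_lu(rep(1, 10), nrow = 2)
  t1 <- toy_lu(c(rep(2, 7), rep(1, 3)), nrow = 2)
  sim <- toy_lu(c(rep(1, 5), 2, 2, rep(3, 3)), nrow = 2)
  f <- figure_of_merit(t0, t1, sim)
  expect_equal(c(f$A, f$B, f$C, f$D), c(5, 2, 0, 3))
  expect_equal(f$fom, 0.2)

  expect_equal(figure_of_merit(t0, t1, t1)$fom, 1)      # perfect simulation
  expect_equal(figure_of_merit(t0, t1, t0)$fom, 0)      # pure persistence
  expect_error(figure_of_merit(t0, t0, t0), "no observed change")

  # wrong-class changes populate C
  sim2 <- toy_lu(c(rep(3, 7), rep(1, 3)), nrow = 2)
  f2 <- figure_of_merit(t0, t1, sim2)
  expect_equal(f2$C, 7)
  expect_equal(f2$fom, 0)
})
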