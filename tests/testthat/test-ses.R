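test_that("standardization maps extremes to {0,1} and flips the negative indicator", {
  pos <- service_raster(matrix(c(2, 4, 6, 2, 4, 6), 2, 3), "CS")
  s <- standardize(pos)
  expect_equal(sort(unique(as.vector(s$grid))), c(0, 0.5, 1))
  neg <- service_raster(matrix(c(2, 4, 6, 2, 4, 6), 2, 3), "WP",
                        direction = "negative")
  sn <- standardize(neg)
  expect_equal(sn$grid[pos$grid == 6], c(0, 0))   # worst where export peaks
  expect_equal(sn$grid[pos$grid == 2], c(1, 1))
  # idempotent on an already standardized layer with the same extremes
  expect_equal(standardize(s, c(0, 1))$grid, s$grid)
  # degenerate range errors
  expect_error(standardize(service_raster(matrix(5, 2, 2), "CS")),
               "degenerate")
  # joint extremes clip out-of-domain values
  s2 <- standardize(pos, extremes = c(3, 5))
  expect_true(all(s2$grid >= 0 & s2$grid <= 1))
})

test_that("the summed indicator is the weighted sum with printed defaults", {
  ones <- lapply(c(CS = "CS", FR = "FR", SC = "SC", WP = "WP",
                   HQ = "HQ", CP = "CP"),
                 function(nm) service_raster(matrix(1, 3, 3), nm))
  s <- ses_surface(ones)
  expect_equal(unique(as.vector(s$raster$grid)),
               0.1596 + 0.1688 + 0.0875 + 0.1396 + 0.1574 + 0.0964)
  zeros <- lapply(ones, function(r) { r$grid[] <- 0; r })
  expect_equal(unique(as.vector(ses_surface(zeros)$raster$grid)), 0)
  # monotone: raising one service never lowers SES
  up <- ones; up$CP$grid[2, 2] <- 2
  expect_true(all(ses_surface(up)$raster$grid >= s$raster$grid))
  # missing layers refused; renormalized weights sum to 1
  expect_error(ses_surface(ones[-1]), "missing service")
  expect_equal(sum(ses_surface(ones, renormalize = TRUE)$weights), 1)
})

test_that("sample points are distinct valid cells and reproducible", {
  set.seed(2)
  g <- matrix(rnorm(400), 20, 20); g[1:5] <- NA
  svc <- list(CS = service_raster(g, "CS"),
              HQ = service_raster(g * 2 + 1, "HQ"))
  pts <- sample_points(svc, n = 100, seed = 5)
  expect_equal(nrow(pts), 100)
  expect_false(anyDuplicated(pts$cell) > 0)
  expect_true(all(!is.na(pts$CS)))
  expect_identical(pts, sample_points(svc, n = 100, seed = 5))
  # exhaustive sample when n equals the valid-cell count
  pts_all <- sample_points(svc, n = 395, seed = 1)
  expect_equal(nrow(pts_all), 395)
  expect_error(sample_points(svc, n = 396, seed = 1), "exceeds")
  # sample mean close to population mean (CLT bound, 3 SE)
  pop <- g[!is.na(g)]
  se <- sd(pop) / sqrt(100)
  expect_lt(abs(mean(pts$CS) - mean(pop)), 3 * se + 1e-12)
})

test_that("correlations recover planted structure and flag degeneracy", {
  set.seed(9)
  x <- rnorm(2000)
  pts <- data.frame(cell = 1:2000, row = 1, col = 1,
                    CS = x, HQ = -x, SC = rnorm(2000))
  class(pts) <- c("sample_points", "data.frame")
  cc <- correlate_services(pts, "spearman")
  expect_equal(diag(cc$r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(cc$r["CS", "HQ"], -1)
  expect_equal(cc$r, t(cc$r))
  # zero-variance service flagged, not crashed
  pts$SC <- 5
  cc2 <- correlate_services(pts, "spearman")
  expect_true(cc2$flagged[["SC"]])
  expect_true(is.na(cc2$r["CS", "SC"]))
  expect_error(correlate_services(pts[1:2, ], "spearman"), "at least 3")

  # planted rank correlation 0.9 via a Gaussian copula is recovered
  rho_pearson <- 2 * sin(pi * 0.9 / 6)
  z1 <- rnorm(2000)
  z2 <- rho_pearson * z1 + sqrt(1 - rho_pearson^2) * rnorm(2000)
  pts3 <- data.frame(cell = 1:2000, row = 1, col = 1, CS = z1, HQ = z2)
  class(pts3) <- c("sample_points", "data.frame")
  r_hat <- correlate_services(pts3, "spearman")$r["CS", "HQ"]
  expect_lt(abs(r_hat - 0.9), 0.05)
})
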