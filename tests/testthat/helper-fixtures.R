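# Shared fixtures, built in code and memoised per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# A small complete synthetic region (60 x 60 unless asked otherwise).
small_region <- function(shape = c(60, 60), seed = 7) {
  key <- paste0("region_", paste(shape, collapse = "x"), "_", seed)
  cached(key, synth_region(synthetic_spec(shape = shape, seed = seed)))
}

# A tiny hand-made land raster from a vector of codes.
toy_lu <- function(codes, nrow, cell_size = 30, classes = landuse_classes) {
  land_raster(matrix(as.integer(codes), nrow = nrow), cell_size = cell_size,
              classes = classes)
}

# Brute-force D8 accumulation: walk every cell's receiver chain and add its
# weight to every cell on the path (the exhaustive path-enumeration oracle).
brute_force_accumulation <- function(flow, weights = 1) {
  n <- prod(flow$dim)
  w <- if (length(weights) == 1L) rep(weights, n) else as.numeric(weights)
  acc <- numeric(n)
  for (i in seq_len(n)) {
    j <- i
    repeat {
      acc[j] <- acc[j] + w[i]
      j <- flow$receiver[j]
      if (j == 0L) break
    }
  }
  matrix(acc, flow$dim[1], flow$dim[2])
}

# A biophysical table whose Kc is 1 everywhere (so effective PET = PET).
unit_kc_table <- function() {
  tab <- make_tables(synthetic_spec(seed = 1))$biophys
  tab$Kc <- 1
  tab
}
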