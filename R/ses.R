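## Min-max standardization of service surfaces, the weighted summed
## indicator, and trade-off/synergy correlations over random sample points.

#' Joint min/max extremes over several service rasters
#'
#' When maps from several years or scenarios are compared, the
#' standardization extremes must be computed over all of them jointly,
#' otherwise per-map min-max rescaling makes means incomparable.
#'
#' @param rasters List of `service_raster`/`cont_raster` for one service.
#' @return `c(min, max)` over all non-NA cells.
#' @export
joint_extremes <- function(rasters) {
  v <- unlist(lapply(rasters, function(r) r$grid[!is.na(r$grid)]))
  range(v)
}

#' Min-max standardize a service surface
#'
#' Positive indicators map to `(E - Emin) / (Emax - Emin)`; the negative
#' indicator (nitrogen export, WP) is flipped, `(Emax - E) / (Emax -
#' Emin)`, so 1 always means best performance. Values are clipped to
#' [0, 1] when joint extremes narrower than the map's range are supplied.
#'
#' @param service A `service_raster`.
#' @param extremes Optional `c(min, max)` standardization domain; defaults
#'   to the raster's own range.
#' @return A `service_raster` on [0, 1] with direction `"positive"`.
#' @export
standardize <- function(service, extremes = NULL) {
  stopifnot(inherits(service, "service_raster"))
  e <- service$grid
  if (is.null(extremes)) extremes <- range(e, na.rm = TRUE)
  if (!(extremes[2] > extremes[1])) stop("degenerate standardization range")
  s <- if (service$direction == "negative") {
    (extremes[2] - e) / (extremes[2] - extremes[1])
  } else {
    (e - extremes[1]) / (extremes[2] - extremes[1])
  }
  s <- pmin(pmax(s, 0), 1)
  service_raster(s, service$service_name, "positive", service$cell_size,
                 service$origin, units = "")
}

#' Weighted sum of standardized ecosystem services
#'
#' `SES = sum_i w_i * S_i` over the six standardized surfaces. With the
#' default weights the attainable maximum is their sum (0.8093); weights
#' are used as printed unless `renormalize = TRUE` scales them to sum to 1.
#'
#' @param services Named list (CS, FR, SC, WP, HQ, CP) of standardized
#'   `service_raster`s.
#' @param weights Named weights (default [default_weights()]).
#' @param renormalize Scale weights to sum to 1 (default `FALSE`).
#' @return List: `raster` (`cont_raster`), `mean` over valid cells,
#'   `weights` used.
#' @export
ses_surface <- function(services, weights = default_weights(),
                        renormalize = FALSE) {
  need <- c("CS", "FR", "SC", "WP", "HQ", "CP")
  if (!all(need %in% names(services))) {
    stop("missing service layer(s): ",
         paste(setdiff(need, names(services)), collapse = ", "))
  }
  if (any(weights < 0)) stop("weights must be >= 0")
  if (renormalize) weights <- weights / sum(weights)
  ref <- services[[need[1]]]
  align_check(services, strict = TRUE)
  ses <- matrix(0, nrow(ref$grid), ncol(ref$grid))
  for (nm in need) ses <- ses + weights[[nm]] * services[[nm]]$grid
  list(
    raster = cont_raster(ses, ref$cell_size, ref$origin, units = ""),
    mean = mean(ses, na.rm = TRUE),
    weights = weights
  )
}

#' Draw random sample points and extract service values
#'
#' Uniform random distinct cells over the joint valid mask of all
#' services; the extracted values drive the trade-off correlations.
#'
#' @param services Named list of `service_raster`s (or `cont_raster`s).
#' @param n Number of points (default 2000).
#' @param seed RNG seed.
#' @return A `sample_points` data frame: `cell`, `row`, `col`, one column
#'   per service.
#' @export
sample_points <- function(services, n = 2000, seed = 1L) {
  masks <- lapply(services, function(r) !is.na(r$grid))
  joint <- Reduce("&", masks)
  idx <- which(joint)
  if (n > length(idx)) stop("n exceeds the number of jointly valid cells")
  set.seed(stage_seed(seed, "sample_points"))
  take <- sort(sample(idx, n))
  nr <- nrow(services[[1]]$grid)
  out <- data.frame(cell = take,
                    row = ((take - 1L) %% nr) + 1L,
                    col = ((take - 1L) %/% nr) + 1L)
  for (nm in names(services)) out[[nm]] <- services[[nm]]$grid[take]
  class(out) <- c("sample_points", "data.frame")
  out
}

#' Pairwise trade-off/synergy correlations at sample points
#'
#' Spearman rank correlation by default (positive = synergy, negative =
#' trade-off); Pearson available. Zero-variance services are flagged and
#' their coefficients set to `NA` rather than erroring.
#'
#' @param points A `sample_points` data frame.
#' @param method `"spearman"` or `"pearson"`.
#' @return List: `r` (correlation matrix), `p` (two-tailed p-values),
#'   `method`, `flagged` (logical vector of zero-variance services).
#' @export
correlate_services <- function(points, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  cols <- setdiff(names(points), c("cell", "row", "col"))
  if (nrow(points) < 3) stop("need at least 3 points")
  x <- as.matrix(as.data.frame(points)[, cols, drop = FALSE])
  k <- ncol(x)
  r <- matrix(NA_real_, k, k, dimnames = list(cols, cols))
  p <- r
  flagged <- apply(x, 2, function(v) stats::sd(v) == 0)
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (flagged[i] || flagged[j]) next
      ct <- suppressWarnings(
        stats::cor.test(x[, i], x[, j], method = method, exact = FALSE))
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(r = r, p = p, method = method, flagged = flagged)
}
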