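## Markov transition demand, trainable suitability surfaces, CA allocation
## with self-adaptive inertia/competition, scenario constraints, and
## figure-of-merit validation.

#' Fit a class-transition probability matrix from two maps
#'
#' `M[i, j] = n(i -> j) / n(i)` counted over jointly valid cells. Classes
#' absent at the start date keep an identity row.
#'
#' @param lu_t0,lu_t1 Aligned `land_raster`s with the same class set.
#' @param step Interval length in years (metadata only; the matrix is
#'   applied once per projection of the same length).
#' @return A `transition_matrix`: the 7x7 matrix with a `step` attribute.
#' @export
fit_transition <- function(lu_t0, lu_t1, step = 15) {
  align_check(lu_t0, lu_t1, strict = TRUE)
  if (!identical(lu_t0$classes, lu_t1$classes)) stop("class sets differ")
  k <- length(lu_t0$classes)
  ok <- valid_mask(lu_t0) & valid_mask(lu_t1)
  tab <- table(factor(lu_t0$grid[ok], levels = lu_t0$classes),
               factor(lu_t1$grid[ok], levels = lu_t1$classes))
  m <- unclass(tab / pmax(rowSums(tab), 1))
  empty <- rowSums(tab) == 0
  m[empty, ] <- diag(k)[empty, ]
  dimnames(m) <- list(names(lu_t0$classes), names(lu_t0$classes))
  structure(m, step = step, class = c("transition_matrix", "matrix"))
}

#' Project per-class area demand with a Markov step
#'
#' Applies the transition matrix once to the current class areas, then any
#' scenario demand adjustments: classes with a multiplicative factor != 1
#' are fixed at factor x Markov value and the remaining classes are scaled
#' proportionally so the total area is conserved; an optional per-class
#' demand floor (fraction of total area) is enforced the same way.
#'
#' @param lu_t0 Base `land_raster`.
#' @param M A `transition_matrix`.
#' @param scenario Optional `scenario_config` carrying `demand_adjust` and
#'   `demand_floor`.
#' @return Named numeric vector of target areas (km^2), summing to the
#'   current total area.
#' @export
project_demand <- function(lu_t0, M, scenario = NULL) {
  a <- class_areas(lu_t0)
  demand <- as.numeric(a %*% unclass(M))
  names(demand) <- names(a)
  total <- sum(a)
  if (!is.null(scenario)) {
    adj <- scenario$demand_adjust
    fixed <- abs(adj - 1) > 1e-12
    demand[fixed] <- demand[fixed] * adj[fixed]
    if (any(!fixed)) {
      resid <- total - sum(demand[fixed])
      if (resid < 0) stop("demand adjustment implies negative area for the remaining classes")
      demand[!fixed] <- demand[!fixed] * resid / sum(demand[!fixed])
    }
    if (!is.null(scenario$demand_floor)) {
      fl <- scenario$demand_floor * total
      low <- !is.na(fl) & demand < fl
      if (any(low)) {
        demand[low] <- fl[low]
        rest <- !low
        resid <- total - sum(demand[low])
        if (resid < 0) stop("demand floors exceed the landscape area")
        demand[rest] <- demand[rest] * resid / sum(demand[rest])
      }
    }
  }
  if (any(demand < 0)) stop("negative demand after adjustment")
  demand
}

#' Scenario configuration for the CA allocator
#'
#' @param name Scenario label ("BAU", "ELP", "RUD" or custom).
#' @param restriction_mask Logical matrix; `TRUE` cells are frozen (never
#'   change class).
#' @param allowed 7x7 logical conversion-permission matrix (from, to);
#'   diagonal is always permitted.
#' @param demand_adjust Named per-class multiplicative factors applied to
#'   the Markov demand (default all 1).
#' @param demand_floor Optional named per-class minimum demand as a
#'   fraction of total area (`NA` = no floor).
#' @return A `scenario_config`.
#' @export
scenario_config <- function(name = "custom", restriction_mask = NULL,
                            allowed = NULL, demand_adjust = NULL,
                            demand_floor = NULL) {
  k <- length(landuse_classes)
  if (is.null(allowed)) allowed <- matrix(TRUE, k, k)
  diag(allowed) <- TRUE
  if (is.null(demand_adjust)) {
    demand_adjust <- stats::setNames(rep(1, k), names(landuse_classes))
  }
  structure(
    list(name = name, restriction_mask = restriction_mask, allowed = allowed,
         demand_adjust = demand_adjust, demand_floor = demand_floor),
    class = "scenario_config"
  )
}

#' Business-as-usual scenario: raw Markov demand, no constraints
#' @return A `scenario_config`.
#' @export
scenario_bau <- function() scenario_config("BAU")

#' Ecological-protection scenario
#'
#' Nature reserves, reservoirs and basic farmland are frozen via the
#' restriction mask; demand favours forest; conversions of forest or water
#' into built-up land are forbidden; cultivated land can be given a demand
#' floor (fraction of total area).
#'
#' @param restriction_mask Logical matrix of protected cells.
#' @param forest_adjust Multiplier on forest demand (default 1.15).
#' @param cultivated_floor Minimum cultivated-land share of total area
#'   (default 0.07; `NULL` to disable).
#' @return A `scenario_config`.
#' @export
scenario_elp <- function(restriction_mask = NULL, forest_adjust = 1.15,
                         cultivated_floor = 0.07) {
  k <- length(landuse_classes)
  allowed <- matrix(TRUE, k, k)
  allowed[landuse_classes[["forest"]], landuse_classes[["built_up"]]] <- FALSE
  allowed[landuse_classes[["water"]], landuse_classes[["built_up"]]] <- FALSE
  adj <- stats::setNames(rep(1, k), names(landuse_classes))
  adj["forest"] <- forest_adjust
  floor <- NULL
  if (!is.null(cultivated_floor)) {
    floor <- stats::setNames(rep(NA_real_, k), names(landuse_classes))
    floor["cultivated"] <- cultivated_floor
  }
  scenario_config("ELP", restriction_mask, allowed, adj, floor)
}

#' Rapid-urban-development scenario
#'
#' Built-up demand is boosted; basic farmland (an optional mask) is frozen.
#'
#' @param builtup_adjust Multiplier on built-up demand (default 1.5).
#' @param farmland_mask Optional logical matrix of basic-farmland cells to
#'   freeze.
#' @return A `scenario_config`.
#' @export
scenario_rud <- function(builtup_adjust = 1.5, farmland_mask = NULL) {
  adj <- stats::setNames(rep(1, length(landuse_classes)), names(landuse_classes))
  adj["built_up"] <- builtup_adjust
  scenario_config("RUD", farmland_mask, NULL, adj)
}

#' Fit per-class suitability surfaces from drivers
#'
#' Trains a multiclass probabilistic classifier — by default a single-
#' hidden-layer neural network (softmax output), alternatively multinomial
#' logistic regression — on a uniform random sample of cells, then predicts
#' an occurrence-probability surface per class, normalized per cell. If the
#' uniform sample misses a class present on the map, the sample is retaken
#' stratified by class.
#'
#' @param lu `land_raster` supplying the training labels.
#' @param drivers Named list of aligned `cont_raster` layers.
#' @param model `"nnet"` or `"multinom"`.
#' @param sample_frac Fraction of valid cells to train on, in (0, 1].
#' @param seed Integer RNG seed (training sample and network init).
#' @param hidden Hidden-layer size for the network.
#' @return A `suitability_stack`: list with `prob` (rows x cols x 7 array),
#'   `model`, `sample_frac`, `seed`.
#' @export
fit_suitability <- function(lu, drivers, model = c("nnet", "multinom"),
                            sample_frac = 0.1, seed = 1L, hidden = 8L) {
  model <- match.arg(model)
  stopifnot(sample_frac > 0, sample_frac <= 1)
  for (d in drivers) align_check(lu, d, strict = TRUE)
  set.seed(stage_seed(seed, paste0("suitability_", model)))
  x <- vapply(drivers, function(d) as.numeric(d$grid),
              numeric(length(lu$grid)))
  colnames(x) <- names(drivers)
  ok <- valid_mask(lu) & apply(x, 1, function(r) all(is.finite(r)))
  idx_ok <- which(ok)
  n_train <- max(length(lu$classes) * 5L, round(length(idx_ok) * sample_frac))
  take <- sample(idx_ok, min(n_train, length(idx_ok)))
  present <- sort(unique(lu$grid[idx_ok]))
  if (!all(present %in% lu$grid[take])) {
    # stratified refit: guarantee every mapped class appears in the sample
    take <- unlist(lapply(present, function(k) {
      cells <- idx_ok[lu$grid[idx_ok] == k]
      sample(cells, max(1L, round(length(cells) * sample_frac)))
    }))
  }
  ctr <- colMeans(x[take, , drop = FALSE])
  scl <- apply(x[take, , drop = FALSE], 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  y <- factor(lu$grid[take], levels = lu$classes)
  train <- data.frame(xs[take, , drop = FALSE])
  if (model == "nnet") {
    cls_mat <- nnet::class.ind(y)
    fit <- nnet::nnet(train, cls_mat, size = hidden, softmax = TRUE,
                      maxit = 250, decay = 5e-4, trace = FALSE,
                      MaxNWts = 20000)
    pr <- stats::predict(fit, data.frame(xs), type = "raw")
  } else {
    dat <- cbind(class = y, train)
    fit <- nnet::multinom(class ~ ., data = dat, trace = FALSE,
                          MaxNWts = 20000, maxit = 300)
    pr <- stats::predict(fit, data.frame(xs), type = "probs")
    if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)  # two-class edge case
  }
  prob_full <- matrix(0, length(lu$grid), length(lu$classes))
  colnames(prob_full) <- as.character(lu$classes)
  got <- intersect(colnames(pr), colnames(prob_full))
  prob_full[, got] <- pr[, got]
  prob_full <- pmax(prob_full, 1e-8)
  prob_full <- prob_full / rowSums(prob_full)
  prob_full[!ok, ] <- NA_real_
  arr <- array(prob_full, dim = c(dim(lu$grid), length(lu$classes)))
  structure(
    list(prob = arr, model = model, sample_frac = sample_frac,
         seed = seed, classes = lu$classes),
    class = "suitability_stack"
  )
}

#' Allocate land-use change with a constrained cellular automaton
#'
#' Iterative competition: per iteration, the conversion weight of a cell
#' toward class k is suitability_k x Moore-3x3 neighbourhood enrichment of
#' k (floored at 0.01) x a self-adaptive per-class inertia x the scenario's
#' conversion permission. Each under-demand class draws winners from the
#' permitted donor cells (cells of over-demand classes) by repeated
#' roulette wheel over these weights — weighted sampling without
#' replacement — bounded by each donor class's surplus, so higher-
#' suitability cells convert more often. Inertia self-adapts every
#' iteration,
#' `inertia_k <- inertia_k * (1 + eta * gap_k / demand_k)` clipped to
#' [0.1, 10], boosting under-allocated classes. Frozen cells never change;
#' forbidden conversions never occur. Iteration stops when every class is
#' within `tol` cells of demand or `max_iter` is reached (non-convergence
#' returns the best state with a warning and `converged = FALSE`).
#'
#' @param lu_t0 Starting `land_raster`.
#' @param suitability A `suitability_stack`.
#' @param demand Named per-class target areas (km^2), summing to the map
#'   total.
#' @param scenario A `scenario_config` (default BAU: unconstrained).
#' @param max_iter Maximum CA iterations (default 300).
#' @param seed RNG seed for the roulette draws.
#' @param eta Inertia adaptation rate (default 0.1).
#' @param tol Demand tolerance in cells; default
#'   `max(1, 0.001 * class demand)` per class.
#' @param step_frac Fraction of each remaining gap converted per iteration
#'   (at least 25 cells), so change grows in neighbourhood-guided clusters.
#' @return A `land_raster` with attributes `converged`, `iterations`,
#'   `final_gap` (cells).
#' @export
allocate_ca <- function(lu_t0, suitability, demand, scenario = scenario_bau(),
                        max_iter = 300L, seed = 1L, eta = 0.1, tol = NULL,
                        step_frac = 0.25) {
  k <- length(lu_t0$classes)
  cell_km2 <- lu_t0$cell_size^2 / 1e6
  n_valid <- sum(valid_mask(lu_t0))
  if (sum(demand) > n_valid * cell_km2 * (1 + 1e-6)) stop("demand exceeds the landscape area")
  demand_cells <- round(demand / cell_km2)
  # force exact feasibility: residual cells go to the largest class
  excess <- n_valid - sum(demand_cells)
  demand_cells[which.max(demand_cells)] <- demand_cells[which.max(demand_cells)] + excess
  if (any(demand_cells < 0)) stop("infeasible (negative) cell demand")
  if (is.null(tol)) tol <- pmax(1, 0.001 * demand_cells)
  set.seed(stage_seed(seed, "allocate_ca"))

  grid <- lu_t0$grid
  ok <- valid_mask(lu_t0)
  frozen <- if (is.null(scenario$restriction_mask)) {
    matrix(FALSE, nrow(grid), ncol(grid))
  } else scenario$restriction_mask
  allowed <- scenario$allowed
  prob <- matrix(suitability$prob, ncol = k)
  off <- moore_offsets()

  neigh_frac <- function(g) {
    out <- matrix(0, length(g), k)
    cnt <- matrix(0, nrow(g), ncol(g))
    for (kk in seq_len(k)) {
      is_k <- matrix(as.numeric(g == lu_t0$classes[kk]), nrow(g), ncol(g))
      s <- matrix(0, nrow(g), ncol(g))
      for (o in seq_len(nrow(off))) {
        s <- s + shift_mat(is_k, off[o, 1], off[o, 2], fill = 0)
      }
      out[, kk] <- as.numeric(s)
      cnt <- cnt + s
    }
    out / pmax(as.numeric(cnt), 1)
  }

  counts <- vapply(lu_t0$classes, function(cc) sum(grid[ok] == cc), numeric(1))
  inertia <- rep(1, k)
  converged <- all(abs(demand_cells - counts) <= tol)
  iter <- 0L
  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    gap <- demand_cells - counts
    inertia <- inertia * (1 + eta * gap / pmax(demand_cells, 1))
    inertia <- pmin(pmax(inertia, 0.1), 10)
    under <- which(gap > tol / 2)
    over <- which(gap < -tol / 2)
    if (!length(under) || !length(over)) break
    donors <- which(ok & !frozen & matrix(grid %in% lu_t0$classes[over],
                                          nrow(grid), ncol(grid)))
    if (!length(donors)) break
    nf <- pmax(neigh_frac(grid), 0.01)
    cur <- match(grid[donors], lu_t0$classes)
    # competition round: every under-demand class draws its winners from
    # the permitted donor cells by repeated roulette over the conversion
    # weight (suitability x neighbourhood x inertia); sampling without
    # replacement proportional to weight == Gumbel-perturbed ranking
    prop_cell <- integer(0); prop_tgt <- integer(0); prop_key <- numeric(0)
    for (j in seq_along(under)) {
      tgt <- under[j]
      w <- prob[donors, tgt] * nf[donors, tgt] * inertia[tgt] *
        allowed[cbind(cur, tgt)]
      cand <- which(w > 0 & !is.na(w))
      if (!length(cand)) next
      key <- log(w[cand]) - log(-log(stats::runif(length(cand))))
      prop_cell <- c(prop_cell, cand)
      prop_tgt <- c(prop_tgt, rep.int(j, length(cand)))
      prop_key <- c(prop_key, key)
    }
    if (!length(prop_cell)) break
    ordp <- order(prop_key, decreasing = TRUE)
    # grow toward demand over several rounds so the updating neighbourhood
    # term can cluster the changes
    need <- pmin(pmax(gap[under], 0), pmax(ceiling(step_frac * gap[under]), 25))
    surplus <- pmax(-gap, 0)
    taken <- logical(length(donors))
    changed <- FALSE
    for (m in ordp) {
      dcell <- prop_cell[m]; j <- prop_tgt[m]; src <- cur[dcell]
      if (!taken[dcell] && need[j] > 0 && surplus[src] > 0) {
        grid[donors[dcell]] <- lu_t0$classes[under[j]]
        taken[dcell] <- TRUE
        need[j] <- need[j] - 1
        surplus[src] <- surplus[src] - 1
        changed <- TRUE
      }
      if (all(need <= 0)) break
    }
    if (!changed) break
    counts <- vapply(lu_t0$classes, function(cc) sum(grid[ok] == cc), numeric(1))
    converged <- all(abs(demand_cells - counts) <= tol)
  }
  if (!converged) warning("allocate_ca did not converge to demand within max_iter")
  out <- land_raster(grid, lu_t0$cell_size, lu_t0$origin, lu_t0$nodata,
                     lu_t0$classes)
  attr(out, "converged") <- converged
  attr(out, "iterations") <- iter
  attr(out, "final_gap") <- demand_cells - counts
  out
}

#' Figure of merit for simulated change
#'
#' With A = observed-change cells simulated as persistence (misses),
#' B = observed-change cells simulated as the correct new class (hits),
#' C = observed-change cells simulated as a wrong change, and D =
#' observed-persistence cells simulated as change (false alarms):
#' `FoM = B / (A + B + C + D)`.
#'
#' @param observed_t0,observed_t1,simulated_t1 Aligned `land_raster`s.
#' @return List: `fom`, `A`, `B`, `C`, `D`.
#' @export
figure_of_merit <- function(observed_t0, observed_t1, simulated_t1) {
  align_check(observed_t0, observed_t1, simulated_t1, strict = TRUE)
  ok <- valid_mask(observed_t0) & valid_mask(observed_t1) &
    valid_mask(simulated_t1)
  o0 <- observed_t0$grid[ok]; o1 <- observed_t1$grid[ok]
  s1 <- simulated_t1$grid[ok]
  chg <- o0 != o1
  if (!any(chg)) stop("no observed change; figure of merit is undefined")
  A <- sum(chg & s1 == o0)
  B <- sum(chg & s1 == o1)
  C <- sum(chg & s1 != o0 & s1 != o1)
  D <- sum(!chg & s1 != o0)
  list(fom = B / (A + B + C + D), A = A, B = B, C = C, D = D)
}
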