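#' Synthetic landscapes, virtual species and park-like coverage layers
#'
#' The generator produces gridded study systems with the statistical
#' structure the gap analysis assumes: spatially autocorrelated predictors
#' grouped into correlated sets, Bernoulli presence/absence driven by a
#' logistic model with a smooth spatial trend, and a protected-area layer of
#' a few contiguous "parks" occupying a small fraction of the territory with
#' fractional coverage on park-edge cells.
#'
#' @param nx,ny lattice dimensions in cells (`nx * ny >= 25`).
#' @param n_sets number of predictor sets.
#' @param vars_per_set variables per set.
#' @param correlation within-set correlation level in [0, 1): the target
#'   Pearson correlation between any two variables of the same set.
#' @param smoothness length-scale (in cells) of the Gaussian smoothing
#'   kernel applied to the white-noise fields; larger values give smoother,
#'   more autocorrelated predictors.
#' @param set_names optional character vector of set names; defaults to the
#'   classic atlas sets (climate, topography, lithology, landuse, human)
#'   recycled as needed.
#' @param seed integer seed.
#' @return list describing the configuration, of class `landscape_config`.
#' @export
landscape_config <- function(nx = 50, ny = 50, n_sets = 5, vars_per_set = 4,
                             correlation = 0.7, smoothness = 3,
                             set_names = NULL, seed = 1) {
  if (nx * ny < 25) stop("nx * ny must be at least 25", call. = FALSE)
  if (correlation < 0 || correlation >= 1)
    stop("correlation must be in [0, 1)", call. = FALSE)
  defaults <- c("climate", "topography", "lithology", "landuse", "human")
  if (is.null(set_names))
    set_names <- rep_len(defaults, n_sets)
  set_names <- make.unique(set_names[seq_len(n_sets)], sep = "_")
  structure(list(nx = nx, ny = ny, n_sets = n_sets,
                 vars_per_set = vars_per_set, correlation = correlation,
                 smoothness = smoothness, set_names = set_names,
                 seed = as.integer(seed)),
            class = "landscape_config")
}

# Standardized smoothed-Gaussian random field on an nx x ny lattice:
# white noise convolved with a separable Gaussian kernel, reflected at the
# edges, then scaled to mean 0 / sd 1.
smooth_field <- function(nx, ny, smoothness) {
  z <- matrix(stats::rnorm(nx * ny), nrow = ny, ncol = nx)
  if (smoothness > 0) {
    r <- max(1L, ceiling(3 * smoothness))
    k <- stats::dnorm(-r:r, sd = smoothness)
    k <- k / sum(k)
    conv1 <- function(v) {
      n <- length(v)
      pad <- c(rev(v[seq_len(min(r, n))]), v,
               rev(v[seq(max(1L, n - r + 1L), n)]))
      # pad may be short for tiny grids; extend by recycling
      while (length(pad) < n + 2L * r) pad <- c(pad[1L], pad, pad[length(pad)])
      out <- stats::filter(pad, k, sides = 2)
      as.numeric(out[(r + 1L):(r + n)])
    }
    z <- apply(z, 2L, conv1)           # smooth down columns
    z <- t(apply(z, 1L, conv1))        # smooth along rows
  }
  as.numeric(scale(as.vector(z)))
}

#' Generate a synthetic landscape: grid plus correlated predictors
#'
#' Builds a regular unit-spaced lattice (cell area 1, `P = 0`) and, for each
#' predictor set, a shared latent smoothed-Gaussian field. Each variable is a
#' mixture `sqrt(rho) * latent + sqrt(1 - rho) * own_field` of the set latent
#' and an independent field, so any two variables of a set have expected
#' correlation `rho`. All fields are standardized.
#'
#' @param config a [landscape_config()].
#' @return list with elements `cells` (a [cell_table()] with `P = 0`) and
#'   `predictors` (a [predictor_matrix()]).
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(config$seed)
  nx <- config$nx; ny <- config$ny
  grid <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  cells <- cell_table(cell_id = sprintf("c%05d", seq_len(nx * ny)),
                      x = grid$x, y = grid$y)
  rho <- config$correlation
  cols <- list()
  set_map <- character(0)
  for (s in seq_len(config$n_sets)) {
    latent <- smooth_field(nx, ny, config$smoothness)
    for (v in seq_len(config$vars_per_set)) {
      own <- smooth_field(nx, ny, config$smoothness)
      f <- sqrt(rho) * latent + sqrt(1 - rho) * own
      nm <- sprintf("%s_%d", config$set_names[s], v)
      cols[[nm]] <- as.numeric(scale(f))
      set_map[nm] <- config$set_names[s]
    }
  }
  predictors <- predictor_matrix(do.call(cbind, cols), set_map, cells)
  list(cells = cells, predictors = predictors)
}

#' Virtual species configuration
#'
#' @param betas named numeric vector of true coefficients over existing
#'   predictor names.
#' @param target_prevalence desired fraction of presence cells, strictly
#'   inside (0, 1); the intercept is calibrated by root finding so the mean
#'   Bernoulli probability hits this target to within 1e-4.
#' @param spatial_trend_weight non-negative weight of a smooth spatial trend
#'   (a seeded random cubic polynomial of standardized coordinates,
#'   standardized to unit variance) added to the linear predictor.
#' @param seed integer seed.
#' @return list of class `virtual_species_config`.
#' @export
virtual_species_config <- function(betas, target_prevalence = 0.3,
                                   spatial_trend_weight = 0, seed = 1) {
  if (target_prevalence <= 0 || target_prevalence >= 1)
    stop("target_prevalence must be strictly inside (0, 1)", call. = FALSE)
  if (spatial_trend_weight < 0)
    stop("spatial_trend_weight must be >= 0", call. = FALSE)
  structure(list(betas = betas, target_prevalence = target_prevalence,
                 spatial_trend_weight = spatial_trend_weight,
                 seed = as.integer(seed)),
            class = "virtual_species_config")
}

cubic_terms <- function(x, y) {
  X <- as.numeric(scale(x)); Y <- as.numeric(scale(y))
  cbind(X = X, Y = Y, X2 = X^2, XY = X * Y, Y2 = Y^2,
        X3 = X^3, X2Y = X^2 * Y, XY2 = X * Y^2, Y3 = Y^3)
}

#' Generate a virtual species with known favourability truth
#'
#' Presence is drawn `Bernoulli(plogis(y_j))` with
#' `y_j = intercept + X beta + w * trend`. The intercept is calibrated so the
#' expected prevalence equals `target_prevalence`. The returned true
#' favourability applies the favourability transform to the true logit using
#' the *realized* presence/absence counts, so the fitted surface of a
#' well-specified model is directly comparable to it.
#'
#' @param landscape output of [generate_landscape()].
#' @param vconfig a [virtual_species_config()].
#' @param name species column name.
#' @param group taxonomic group label.
#' @return list with `dataset` (a one-species [species_dataset()]), `true_F`
#'   (true favourability per cell; `NA` if the realized presence vector is
#'   degenerate), `true_logit`, `intercept`, `achieved_prevalence`.
#' @export
generate_species <- function(landscape, vconfig, name = "sp1",
                             group = "other") {
  stopifnot(inherits(vconfig, "virtual_species_config"))
  cells <- landscape$cells
  X <- landscape$predictors$data
  unknown <- setdiff(names(vconfig$betas), colnames(X))
  if (length(unknown) > 0L)
    stop(sprintf("true_betas reference unknown predictor(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  set.seed(vconfig$seed)
  eta <- as.numeric(X[, names(vconfig$betas), drop = FALSE] %*% vconfig$betas)
  if (vconfig$spatial_trend_weight > 0) {
    tcoef <- stats::rnorm(9)
    trend <- as.numeric(cubic_terms(cells$x, cells$y) %*% tcoef)
    trend <- as.numeric(scale(trend))
    eta <- eta + vconfig$spatial_trend_weight * trend
  }
  f <- function(a) mean(stats::plogis(a + eta)) - vconfig$target_prevalence
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0) {
    achieved <- mean(stats::plogis(sign(f(lo)) * 50 + eta))
    warning(sprintf("target prevalence %.4g unreachable; achieved %.4g",
                    vconfig$target_prevalence, achieved), call. = FALSE)
    a <- if (f(lo) > 0) lo else hi
  } else {
    a <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  }
  y <- a + eta
  pr <- stats::plogis(y)
  presence <- stats::rbinom(length(pr), 1L, pr)
  n1 <- sum(presence); n0 <- length(presence) - n1
  ds <- withCallingHandlers(
    species_dataset(matrix(presence, ncol = 1,
                           dimnames = list(NULL, name)),
                    cells, groups = stats::setNames(group, name)),
    warning = function(w) invokeRestart("muffleWarning"))
  true_F <- if (n1 > 0L && n0 > 0L) favourability(y, n1, n0) else
    rep(NA_real_, length(y))
  list(dataset = ds, true_F = as.numeric(true_F), true_logit = y,
       intercept = a, achieved_prevalence = mean(pr))
}

#' Coverage (park network) configuration
#'
#' @param n_parks number of contiguous park blocks.
#' @param coverage_fraction target area-weighted coverage fraction `c` in
#'   (0, 1); the Spanish National Park network motivating the method covers
#'   0.00667 of the mainland.
#' @param placement `"random"` or `"favourability_biased"`; biased placement
#'   seeds parks at the highest values of `surface`.
#' @param surface per-cell surface used by biased placement.
#' @param seed integer seed.
#' @return list of class `coverage_config`.
#' @export
coverage_config <- function(n_parks = 3, coverage_fraction = 0.00667,
                            placement = c("random", "favourability_biased"),
                            surface = NULL, seed = 1) {
  placement <- match.arg(placement)
  if (coverage_fraction < 0 || coverage_fraction >= 1)
    stop("coverage_fraction must be in [0, 1)", call. = FALSE)
  if (n_parks < 1) stop("n_parks must be positive", call. = FALSE)
  if (placement == "favourability_biased" && is.null(surface))
    stop("favourability_biased placement needs a surface", call. = FALSE)
  structure(list(n_parks = as.integer(n_parks),
                 coverage_fraction = coverage_fraction,
                 placement = placement, surface = surface,
                 seed = as.integer(seed)),
            class = "coverage_config")
}

# Grow one contiguous blob of `size` cells from `seed_cell` by breadth-first
# search over 4-neighbours, avoiding already occupied cells. For biased
# placement the frontier is expanded towards high surface values; otherwise
# expansion order is randomized to vary blob shapes.
grow_park <- function(seed_cell, size, nx, ny, occupied, surface = NULL) {
  neighbours <- function(i) {
    x <- (i - 1L) %% nx + 1L
    y <- (i - 1L) %/% nx + 1L
    out <- integer(0)
    if (x > 1L) out <- c(out, i - 1L)
    if (x < nx) out <- c(out, i + 1L)
    if (y > 1L) out <- c(out, i - nx)
    if (y < ny) out <- c(out, i + nx)
    out
  }
  park <- seed_cell
  frontier <- setdiff(neighbours(seed_cell), which(occupied))
  while (length(park) < size && length(frontier) > 0L) {
    nxt <- if (is.null(surface)) frontier[sample.int(length(frontier), 1L)]
           else frontier[which.max(surface[frontier])]
    park <- c(park, nxt)
    frontier <- setdiff(unique(c(frontier, neighbours(nxt))),
                        c(park, which(occupied)))
  }
  park
}

#' Generate a park-like coverage layer
#'
#' Places `n_parks` contiguous blocks on the lattice, sets interior park
#' cells to full coverage and park-edge cells to a uniform(0,1) fraction,
#' then rescales all coverage values so the realized area-weighted coverage
#' fraction equals `coverage_fraction` to within 1e-6 (a cap-and-iterate
#' rescale is used when scaling up, so no value exceeds 1).
#'
#' @param cells a [cell_table()] on a regular lattice.
#' @param cconfig a [coverage_config()].
#' @return a copy of `cells` with the `P` column filled.
#' @export
generate_coverage <- function(cells, cconfig) {
  stopifnot(inherits(cells, "cell_table"), inherits(cconfig, "coverage_config"))
  lat <- infer_lattice(cells)
  if (is.null(lat))
    stop("generate_coverage needs cells on a regular lattice", call. = FALSE)
  nx <- length(lat$xs); ny <- length(lat$ys)
  n <- nrow(cells)
  # map lattice (ix, iy) to the canonical row index
  cell_at <- integer(n)
  cell_at[(lat$iy - 1L) * nx + lat$ix] <- seq_len(n)
  out <- cells
  out$P <- rep(0, n)
  if (cconfig$coverage_fraction == 0) return(out)
  set.seed(cconfig$seed)
  total_area <- sum(cells$area)
  target <- cconfig$coverage_fraction * total_area
  mean_area <- total_area / n
  # enough park cells that the raw draw overshoots the target on average
  k_total <- min(n, max(cconfig$n_parks, ceiling(1.5 * target / mean_area)))
  per_park <- ceiling(k_total / cconfig$n_parks)
  occupied <- logical(n)      # indexed in lattice order (iy-1)*nx + ix
  surface_lattice <- NULL
  if (cconfig$placement == "favourability_biased") {
    surface_lattice <- numeric(n)
    surface_lattice[(lat$iy - 1L) * nx + lat$ix] <- cconfig$surface
  }
  park_cells <- integer(0)
  for (p in seq_len(cconfig$n_parks)) {
    free <- which(!occupied)
    if (length(free) == 0L) break
    seed_cell <- if (is.null(surface_lattice)) free[sample.int(length(free), 1L)]
                 else free[which.max(surface_lattice[free])]
    blob <- grow_park(seed_cell, per_park, nx, ny, occupied, surface_lattice)
    occupied[blob] <- TRUE
    park_cells <- c(park_cells, blob)
  }
  # boundary: park cell with at least one non-park 4-neighbour (or grid edge)
  is_boundary <- vapply(park_cells, function(i) {
    x <- (i - 1L) %% nx + 1L; y <- (i - 1L) %/% nx + 1L
    if (x == 1L || x == nx || y == 1L || y == ny) return(TRUE)
    !all(occupied[c(i - 1L, i + 1L, i - nx, i + nx)])
  }, logical(1))
  P_lattice <- numeric(n)
  P_lattice[park_cells] <- ifelse(is_boundary,
                                  stats::runif(length(park_cells)), 1)
  P <- numeric(n)
  P[cell_at[park_cells]] <- P_lattice[park_cells]
  # rescale to hit the target coverage exactly; cap at 1 when scaling up
  for (iter in 1:100) {
    realized <- sum(P * cells$area)
    if (abs(realized / total_area - cconfig$coverage_fraction) <= 1e-9) break
    if (realized <= 0)
      stop("coverage_fraction exceeds what the park blocks can absorb",
           call. = FALSE)
    s <- target / realized
    if (s <= 1) { P <- P * s; next }
    free_cap <- P < 1
    if (!any(free_cap))
      stop("coverage_fraction exceeds what the park blocks can absorb",
           call. = FALSE)
    deficit <- target - sum(P[!free_cap] * cells$area[!free_cap])
    s2 <- deficit / sum(P[free_cap] * cells$area[free_cap])
    P[free_cap] <- pmin(1, P[free_cap] * s2)
  }
  if (abs(sum(P * cells$area) / total_area - cconfig$coverage_fraction) > 1e-6)
    stop("coverage_fraction exceeds what the park blocks can absorb",
         call. = FALSE)
  out$P <- P
  out
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: landscape, several virtual species, and a coverage
#' layer, with per-component seeds derived from one master seed by fixed
#' offsets so each component is independently reproducible.
#'
#' @param config a [landscape_config()]; its seed is the master seed.
#' @param species_configs list of [virtual_species_config()]s; their seeds
#'   are replaced by derived seeds. Names become species names.
#' @param cconfig a [coverage_config()] (seed likewise derived).
#' @param groups optional character vector of group labels per species.
#' @return list with `cells` (coverage filled), `predictors`, `dataset`
#'   (multi-species), `true_F` (matrix), `seeds` used.
#' @export
simulate_study <- function(config, species_configs, cconfig, groups = NULL) {
  master <- config$seed
  land <- generate_landscape(config)
  nsp <- length(species_configs)
  if (is.null(names(species_configs)))
    names(species_configs) <- sprintf("sp%d", seq_len(nsp))
  if (is.null(groups)) groups <- rep("other", nsp)
  pres <- matrix(0L, nrow(land$cells), nsp,
                 dimnames = list(NULL, names(species_configs)))
  true_F <- matrix(NA_real_, nrow(land$cells), nsp,
                   dimnames = list(NULL, names(species_configs)))
  seeds <- c(landscape = master)
  for (i in seq_len(nsp)) {
    vc <- species_configs[[i]]
    vc$seed <- (master + 1000L * i) %% .Machine$integer.max
    seeds[names(species_configs)[i]] <- vc$seed
    sp <- generate_species(land, vc, name = names(species_configs)[i],
                           group = groups[i])
    pres[, i] <- sp$dataset$presence[, 1L]
    true_F[, i] <- sp$true_F
  }
  cconfig$seed <- (master + 999983L) %% .Machine$integer.max
  seeds["coverage"] <- cconfig$seed
  cells <- generate_coverage(land$cells, cconfig)
  ds <- suppressWarnings(
    species_dataset(pres, cells, stats::setNames(groups, colnames(pres))))
  list(cells = cells, predictors = land$predictors, dataset = ds,
       true_F = true_F, seeds = seeds)
}
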