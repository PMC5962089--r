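# Predictor screening: correlation pruning, trend surface, FDR filtering.

test_that("pruning is a no-op when no within-set pair exceeds the threshold", {
  cells <- make_lattice_cells(10, 10)
  set.seed(1)
  m <- cbind(a = rnorm(100), b = rnorm(100), c = rnorm(100))
  pm <- predictor_matrix(m, c(a = "climate", b = "climate", c = "topo"),
                         cells)
  pres <- rbinom(100, 1, 0.4)
  out <- prune_correlated(pm, pres)
  expect_equal(out$survivors, c("a", "b", "c"))
  expect_equal(nrow(out$dropped), 0)
})

test_that("among three collinear variables only the most significant survives", {
  cells <- make_lattice_cells(20, 20)
  set.seed(42)
  n <- 400
  base <- rnorm(n)
  # A, B, C pairwise highly correlated; presence driven by B
  A <- base + rnorm(n, sd = 0.2)
  B <- base + rnorm(n, sd = 0.2)
  C <- base + rnorm(n, sd = 0.2)
  pres <- rbinom(n, 1, plogis(2 * B))
  r <- cor(cbind(A, B, C))
  expect_true(all(r[upper.tri(r)] > 0.9))
  pm <- predictor_matrix(cbind(A = A, B = B, C = C),
                         c(A = "climate", B = "climate", C = "climate"),
                         cells)
  out <- prune_correlated(pm, pres)
  # B must have the smallest univariate p for the fixture to be meaningful
  expect_equal(names(which.min(out$p)), "B")
  expect_equal(out$survivors, "B")
  expect_equal(nrow(out$dropped), 2)
  expect_true(all(out$dropped$cause == "correlation"))
})

test_that("duplicated columns resolve by column order and constants are dropped", {
  cells <- make_lattice_cells(10, 10)
  set.seed(2)
  x <- rnorm(100)
  pres <- rbinom(100, 1, 0.5)
  pm <- predictor_matrix(cbind(first = x, second = x, flat = rep(1, 100)),
                         c(first = "climate", second = "climate",
                           flat = "climate"), cells)
  out <- prune_correlated(pm, pres)
  expect_equal(out$survivors, "first")        # tie in p -> earlier kept
  expect_true("zero variance" %in% out$dropped$cause)
  expect_equal(out$dropped$dropped[out$dropped$cause == "correlation"],
               "second")
})

test_that("pruned sets contain no within-set pair above the threshold", {
  lc <- landscape_config(nx = 25, ny = 25, n_sets = 2, vars_per_set = 5,
                         correlation = 0.9, seed = 10)
  land <- generate_landscape(lc)
  set.seed(10)
  pres <- rbinom(625, 1, 0.3)
  out <- prune_correlated(land$predictors, pres)
  expect_gte(length(out$survivors), 2)   # at least one survivor per set
  expect_equal(nrow(out$dropped) + length(out$survivors), 10)
  for (set in unique(land$predictors$set_map)) {
    vars <- intersect(out$survivors,
                      names(land$predictors$set_map)[
                        land$predictors$set_map == set])
    if (length(vars) > 1) {
      r <- cor(land$predictors$data[, vars])
      expect_true(all(abs(r[upper.tri(r)]) <= 0.8))
    }
  }
})

test_that("trend surface retains little structure under the null", {
  # random labels: backward AIC keeps each of the 9 noise terms with
  # probability ~ P(chi2_1 > 2) ~ 0.16, so most replicates retain at most
  # two terms and on average fewer than two (simulation-derived bound)
  cells <- make_lattice_cells(15, 15)
  n_terms <- integer(20)
  for (s in 1:20) {
    set.seed(s)
    pres <- rbinom(225, 1, 0.4)
    ts <- suppressWarnings(trend_surface_descriptor(cells, pres))
    n_terms[s] <- length(ts$terms)
  }
  expect_gt(sum(n_terms <= 2), 10)
  expect_lt(mean(n_terms), 3)
})

test_that("trend surface tracks a real west-east gradient", {
  cells <- make_lattice_cells(15, 15)
  # steep but noisy logistic gradient in x (a hard threshold would be
  # perfectly separable and trip the separation fallback)
  set.seed(7)
  pres_east <- rbinom(225, 1, plogis(1.5 * (cells$x - 7.5)))
  ts <- trend_surface_descriptor(cells, pres_east)
  expect_false(ts$separation)
  expect_true(length(ts$terms) > 0)
  expect_true(any(grepl("X", ts$terms)))
  expect_gt(cor(ts$descriptor, cells$x, method = "spearman"), 0.9)
  # determinism
  ts2 <- trend_surface_descriptor(cells, pres_east)
  expect_identical(ts$descriptor, ts2$descriptor)
})

test_that("complete spatial separation falls back to a constant descriptor", {
  cells <- make_lattice_cells(15, 15)
  pres_split <- as.integer(cells$x > 7.5)   # perfectly separable in x
  ts <- trend_surface_descriptor(cells, pres_split)
  expect_true(ts$separation)
  expect_equal(length(ts$terms), 0)
  expect_equal(length(unique(ts$descriptor)), 1)
})

test_that("BH selection matches the printed-list example and edge cases", {
  expect_equal(fdr_select(c(0.001, 0.01, 0.03, 0.2), q = 0.05),
               c(TRUE, TRUE, TRUE, FALSE))
  expect_false(any(fdr_select(rep(1, 5), q = 0.05)))
  expect_true(fdr_select(0.049, q = 0.05))    # m = 1 reduces to p <= q
  expect_false(fdr_select(0.051, q = 0.05))
})

test_that("BH decisions equal the brute-force step-up definition", {
  set.seed(123)
  for (i in 1:1000) {
    m <- sample(1:12, 1)
    p <- round(runif(m), 3)   # rounding forces frequent ties
    q <- sample(c(0.01, 0.05, 0.1, 0.25), 1)
    expect_identical(fdr_select(p, q), bh_bruteforce(p, q))
  }
})

test_that("FDR filtering controls the family-wise survivor rate under the null", {
  # pure-noise landscape: fraction of species with >= 1 survivor <= q + 3 SD
  cells <- make_lattice_cells(12, 12)
  set.seed(99)
  n_species <- 200
  m <- matrix(rnorm(144 * 6), 144, 6,
              dimnames = list(NULL, paste0("v", 1:6)))
  hits <- 0L
  for (i in seq_len(n_species)) {
    pres <- rbinom(144, 1, 0.35)
    fdr <- fdr_filter(m, pres, q = 0.05)
    if (any(fdr$retained)) hits <- hits + 1L
  }
  q <- 0.05
  bound <- q + 3 * sqrt(q * (1 - q) / n_species)
  expect_lte(hits / n_species, bound)
})

test_that("screen_predictors composes the three stages", {
  lc <- landscape_config(nx = 25, ny = 25, n_sets = 2, vars_per_set = 3,
                         correlation = 0.85, seed = 17)
  land <- generate_landscape(lc)
  vc <- virtual_species_config(c(climate_1 = 1.2), 0.3, seed = 17)
  sp <- generate_species(land, vc)
  scr <- screen_predictors(land$predictors, sp$dataset$presence[, 1],
                           land$cells)
  expect_s3_class(scr, "screening_report")
  expect_true(all(scr$survivors %in% scr$fdr$variable))
  expect_true(all(scr$fdr$retained[match(scr$survivors, scr$fdr$variable)]))
  # the informative variable's set keeps a strongly related survivor
  expect_true(any(grepl("climate|spatial", scr$survivors)))
  expect_equal(colnames(scr$data), scr$survivors)
})
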