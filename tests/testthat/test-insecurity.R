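# Insecurity Index, Security, Representativeness and the permutation null.

test_that("per-cell insecurity follows F * (1 - P)", {
  cells <- cell_table(c("a", "b", "c"), x = 1:3, y = rep(1, 3),
                      P = c(1, 0, 0.25))
  I <- cell_insecurity(c(0.5, 0.7, 0.8), cells)
  expect_equal(I, c(0, 0.7, 0.6))
  expect_error(cell_insecurity(c(0.5, 0.7), cells), "length")
})

test_that("overall insecurity is the favourability-weighted complement of coverage", {
  cells <- cell_table(c("a", "b"), x = 1:2, y = c(1, 1), P = c(1, 0))
  F <- c(0.5, 0.5)
  I <- cell_insecurity(F, cells)
  expect_equal(I, c(0, 0.5))
  expect_equal(overall_insecurity(I, F), 0.5)
  # all P = 0 -> I_i = 1; all P = 1 -> I_i = 0
  c0 <- cell_table(c("a", "b"), x = 1:2, y = c(1, 1), P = 0)
  c1 <- cell_table(c("a", "b"), x = 1:2, y = c(1, 1), P = 1)
  expect_equal(overall_insecurity(cell_insecurity(F, c0), F), 1)
  expect_equal(overall_insecurity(cell_insecurity(F, c1), F), 0)
  expect_error(overall_insecurity(c(0, 0), c(0, 0)), "sum\\(F\\) = 0")
})

test_that("the ratio identity I_i = 1 - sum(F*P)/sum(F) holds to 1e-12", {
  set.seed(50)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    cells <- cell_table(sprintf("c%d", 1:n), x = 1:n, y = rep(1, n),
                        P = runif(n))
    F <- runif(n)
    I_i <- overall_insecurity(cell_insecurity(F, cells), F)
    expect_equal(I_i, 1 - sum(F * cells$P) / sum(F), tolerance = 1e-12)
    expect_true(all(cell_insecurity(F, cells) <= F + 1e-15))
  }
})

test_that("representativeness matches published-scale arithmetic and errors on c = 0", {
  expect_equal(round(representativeness(1 - 0.875, 0.00667), 3), 18.741)
  expect_equal(representativeness(0, 0.00667), 0)   # zero security
  expect_error(representativeness(0.5, 0), "c <= 0")
})

test_that("occurrence representativeness follows the coverage of presence cells", {
  cells <- cell_table(c("a", "b", "c"), x = 1:3, y = rep(1, 3),
                      P = c(0.5, 0, 1))
  occ <- occurrence_representativeness(c(1, 1, 0), cells, c = 0.5)
  expect_equal(occ$S_occ, 0.25)
  expect_equal(occ$R_occ, 0.5)
  # fully covered range -> S_occ = 1, R_occ = 1/c
  occ2 <- occurrence_representativeness(c(0, 0, 1), cells, c = 0.5)
  expect_equal(occ2$S_occ, 1)
  expect_equal(occ2$R_occ, 2)
  # uncovered range -> 0
  occ3 <- occurrence_representativeness(c(0, 1, 0), cells, c = 0.5)
  expect_equal(occ3$R_occ, 0)
  expect_error(occurrence_representativeness(c(0, 0, 0), cells),
               "no presences")
})

test_that("group maps sum and normalize by the study-area maximum", {
  expect_equal(group_insecurity_map(list(c(0.2, 0.4), c(0.1, 0.1))),
               c(0.6, 1.0))
  one <- c(0.1, 0.3, 0.6)
  expect_equal(group_insecurity_map(list(one)), one / 0.6)
  expect_equal(group_insecurity_map(list(one, one)), one / 0.6)
  expect_warning(z <- group_insecurity_map(list(c(0, 0))), "all-zero")
  expect_equal(z, c(0, 0))
  expect_error(group_insecurity_map(list(1:3, 1:2)), "aligned")
})

test_that("monotonicity: increasing any P weakly decreases I_i and increases R", {
  set.seed(8)
  n <- 40
  cells <- cell_table(sprintf("c%d", 1:n), x = 1:n, y = rep(1, n),
                      P = runif(n, 0, 0.9))
  F <- runif(n)
  I0 <- overall_insecurity(cell_insecurity(F, cells), F)
  for (j in sample(n, 5)) {
    bumped <- cells
    bumped$P[j] <- bumped$P[j] + 0.1
    I1 <- overall_insecurity(cell_insecurity(F, bumped), F)
    expect_lte(I1, I0)
    expect_gte(representativeness(1 - I1, coverage_fraction(cells)),
               representativeness(1 - I0, coverage_fraction(cells)))
  }
})

test_that("flat coverage makes every permutation a tie, counted as zero", {
  cells <- make_lattice_cells(5, 5, P = 0.3)
  rnd <- randomization_test(runif(25), cells, n_reps = 20, seed = 1)
  expect_equal(rnd$times_actual_gt_random, 0)
  expect_true(all(rnd$random_S == rnd$actual_S))
})

test_that("randomization is deterministic given the seed", {
  cells <- make_lattice_cells(6, 6, P = c(rep(1, 3), rep(0, 33)))
  F <- runif(36)
  a <- randomization_test(F, cells, n_reps = 20, seed = 42)
  b <- randomization_test(F, cells, n_reps = 20, seed = 42)
  expect_identical(a$random_S, b$random_S)
})

test_that("Monte-Carlo permutation counts match exhaustive enumeration on 3 cells", {
  cells <- cell_table(c("a", "b", "c"), x = 1:3, y = rep(1, 3),
                      P = c(0.9, 0.2, 0))
  F <- c(0.8, 0.3, 0.1)
  security <- function(P) 1 - sum(F * (1 - P)) / sum(F)
  actual <- security(cells$P)
  perms <- all_perms(cells$P)                       # all 6 orderings
  exhaustive_gt <- mean(sapply(perms, function(P) actual > security(P)))
  rnd <- randomization_test(F, cells, n_reps = 600, seed = 9)
  mc_gt <- rnd$times_actual_gt_random / 600
  sd_bound <- 3 * sqrt(exhaustive_gt * (1 - exhaustive_gt) / 600)
  expect_lt(abs(mc_gt - exhaustive_gt), max(sd_bound, 1e-12))
})

test_that("under permuted coverage the expected Representativeness is 1", {
  set.seed(33)
  cells <- make_lattice_cells(20, 20)
  cells$P[sample(400, 20)] <- runif(20, 0.3, 1)
  F <- runif(400)
  c_frac <- coverage_fraction(cells)
  rnd <- randomization_test(F, cells, n_reps = 200, seed = 14)
  R_rand <- rnd$random_S / c_frac
  se <- sd(R_rand) / sqrt(length(R_rand))
  expect_lt(abs(mean(R_rand) - 1), 3 * se)
})

test_that("assess_species composes the component operations exactly", {
  set.seed(20)
  cells <- make_lattice_cells(8, 8)
  cells$P <- runif(64, 0, 0.5)
  F <- runif(64)
  pres <- rbinom(64, 1, F)
  if (sum(pres) == 0) pres[1] <- 1L
  a <- assess_species(F, pres, cells, n_reps = 10, seed = 3)
  expect_equal(a$I_surface, cell_insecurity(F, cells))
  expect_equal(a$I_overall, overall_insecurity(a$I_surface, F))
  expect_equal(a$S + a$I_overall, 1)
  expect_equal(a$R, representativeness(a$S, coverage_fraction(cells)))
  expect_equal(a$R_occ,
               occurrence_representativeness(pres, cells)$R_occ)
  expect_identical(a$randomization$random_S,
                   randomization_test(F, cells, n_reps = 10, seed = 3)$random_S)
  # uniform F -> R = 1 exactly when c is the area-weighted mean of P
  u <- assess_species(rep(0.4, 64), pres, cells, n_reps = 5, seed = 1)
  expect_equal(u$R, 1)
  # F concentrated in fully protected cells -> I_i = 0, R = 1/c
  cells2 <- make_lattice_cells(4, 4)
  cells2$P <- c(rep(1, 2), rep(0, 14))
  F2 <- c(rep(0.9, 2), rep(0, 14))
  pres2 <- c(1L, 1L, rep(0L, 14))
  m <- assess_species(F2, pres2, cells2, n_reps = 5, seed = 2)
  expect_equal(m$I_overall, 0)
  expect_equal(m$R, 1 / coverage_fraction(cells2))
})
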