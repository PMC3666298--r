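pr_spec <- function() gene_spec(1, search_bounds(c(-10, -10, -10), c(10, 10, 10)))

# population whose elite agrees at chosen loci
agreeing_pop <- function(n, spec, agree_loci, value = 0.5) {
  G <- matrix(runif(n * spec$n_genes, -3, 3), n, spec$n_genes)
  G[, agree_loci] <- value
  G <- isledock:::repair_genes(G, spec)
  new_population(G, sort(runif(n)))   # energies increasing with row index
}

test_that("a locus where all individuals agree is frozen, and only that locus", {
  set.seed(1)
  spec <- pr_spec()
  pop <- agreeing_pop(10, spec, agree_loci = 2)
  mask <- detect_frozen_loci(pop, spec, top_fraction = 1, tolerance = 1e-6)
  expect_true(mask$frozen[2])
  expect_equal(which(mask$frozen), 2L)
  expect_equal(mask$values[2], 0.5)
})

test_that("zero tolerance with all-distinct values freezes nothing", {
  set.seed(2)
  spec <- pr_spec()
  pop <- new_population(matrix(runif(80, -3, 3), 10, spec$n_genes), runif(10))
  pop$genes <- isledock:::repair_genes(pop$genes, spec)
  mask <- detect_frozen_loci(pop, spec, tolerance = 0)
  expect_false(any(mask$frozen))
})

test_that("the frozen-locus count is monotone non-decreasing in the tolerance", {
  set.seed(3)
  spec <- pr_spec()
  for (rep in 1:30) {
    pop <- new_population(
      isledock:::repair_genes(matrix(runif(12 * spec$n_genes, -2, 2), 12), spec),
      runif(12))
    tols <- c(0.01, 0.1, 0.5, 2, 10)
    counts <- vapply(tols, function(tl) {
      sum(detect_frozen_loci(pop, spec, tolerance = tl)$frozen)
    }, numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("no locus is ever frozen beyond its elite-range tolerance", {
  set.seed(4)
  spec <- pr_spec()
  n_checked <- 0L
  for (rep in 1:50) {
    pop <- new_population(
      isledock:::repair_genes(matrix(runif(10 * spec$n_genes, -2, 2), 10), spec),
      runif(10))
    tol <- runif(1, 0.01, 1)
    mask <- detect_frozen_loci(pop, spec, top_fraction = 0.5, tolerance = tol)
    top <- order(pop$energy)[1:5]
    for (j in which(mask$frozen)) {
      vals <- pop$genes[top, j]
      rng <- if (j %in% spec$idx_tors) isledock:::circular_range(vals)
             else max(vals) - min(vals)
      expect_lte(rng, tol)
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 0L)   # contract holds vacuously if nothing froze
})

test_that("torsion loci use the periodic range and circular mean", {
  spec <- pr_spec()
  # angles straddling the +/- pi seam: linear range is huge, periodic range tiny
  G <- matrix(0.1, 4, spec$n_genes)
  G[, spec$idx_quat] <- matrix(runif(16), 4)    # keep quaternion unfrozen
  G <- isledock:::repair_genes(G, spec)
  G[, 8] <- c(pi - 0.02, pi - 0.01, -pi + 0.01, -pi + 0.02)
  pop <- new_population(G, 1:4 / 4)
  mask <- detect_frozen_loci(pop, spec, top_fraction = 1, tolerance = 0.1)
  expect_true(mask$frozen[8])
  expect_lt(abs(abs(mask$values[8]) - pi), 0.05)  # circular mean near the seam
})

test_that("the quaternion block freezes only as a whole and stays normalized", {
  spec <- pr_spec()
  G <- matrix(0.2, 6, spec$n_genes)
  G <- isledock:::repair_genes(G, spec)
  # perturb one quaternion component beyond tolerance
  G[, 5] <- seq(0, 1, length.out = 6)
  G <- isledock:::repair_genes(G, spec)
  pop <- new_population(G, 1:6 / 6)
  mask <- detect_frozen_loci(pop, spec, top_fraction = 1, tolerance = 0.05)
  expect_false(any(mask$frozen[spec$idx_quat]))
  # fully agreeing quaternions freeze as a block with unit norm
  pop2 <- agreeing_pop(6, spec, agree_loci = spec$idx_quat, value = 0.3)
  mask2 <- detect_frozen_loci(pop2, spec, top_fraction = 1, tolerance = 0.05)
  expect_true(all(mask2$frozen[spec$idx_quat]))
  expect_equal(sum(mask2$values[spec$idx_quat]^2), 1, tolerance = 1e-12)
})

test_that("applying an empty mask is the identity", {
  set.seed(5)
  spec <- pr_spec()
  pop <- agreeing_pop(8, spec, agree_loci = 1)
  out <- apply_pattern_reduction(pop, isledock:::empty_frozen_mask(spec))
  expect_identical(out$pop, pop)
})

test_that("after application the frozen loci have zero variance", {
  set.seed(6)
  spec <- pr_spec()
  pop <- new_population(
    isledock:::repair_genes(matrix(runif(10 * spec$n_genes, -0.1, 0.1), 10), spec),
    runif(10))
  mask <- detect_frozen_loci(pop, spec, tolerance = 5)
  expect_true(any(mask$frozen))
  out <- apply_pattern_reduction(pop, mask, energy_fn = function(G) rowSums(G^2))
  for (j in which(mask$frozen)) {
    expect_equal(stats::var(out$pop$genes[, j]), 0)
  }
  # energies refreshed to match the modified genotypes
  expect_equal(out$pop$energy, rowSums(out$pop$genes^2))
  # mask length validation
  bad <- mask; bad$frozen <- bad$frozen[-1]
  expect_error(apply_pattern_reduction(pop, bad), "mask has")
})

test_that("freezing all but one locus makes Solis-Wets cheaper at equal quality", {
  spec <- isledock:::plain_gene_spec(8, lower = -10, upper = 10)
  f <- function(G) rowSums(G^2)
  x <- rep(0.8, 8)
  params <- optimizer_params(sw_max_iter = 200)
  mask <- isledock:::empty_frozen_mask(spec)
  mask$frozen[2:8] <- TRUE
  mask$values[2:8] <- 0
  x_frozen <- x; x_frozen[2:8] <- 0
  set.seed(7)
  frozen_run <- solis_wets(x_frozen, f(matrix(x_frozen, 1)), f, spec, params, mask)
  set.seed(7)
  free_run <- solis_wets(x, f(matrix(x, 1)), f, spec, params)
  # same budget: the 1-dimensional search gets much further
  expect_lt(frozen_run$energy, free_run$energy)
  expect_identical(frozen_run$genes[2:8], rep(0, 7))
})

test_that("the mask releases on stagnation and re-freezes on the detection schedule", {
  spec <- pr_spec()
  # a trapped population: identical individuals, so everything freezes and the
  # best energy can never improve
  G <- isledock:::repair_genes(matrix(0.4, 6, spec$n_genes), spec)
  pop <- new_population(G, rep(1, 6))
  st <- pr_state(redetect = 5L, release = 6L, top_fraction = 0.5, tolerance = 0.01)
  saw_frozen <- FALSE; saw_release <- FALSE
  for (gen in 1:12) {
    out <- isledock:::pr_step(st, pop, spec, gen)
    st <- out$state
    if (any(out$mask$frozen)) saw_frozen <- TRUE
    if (gen > 6 && gen %% 5 != 1 && !any(out$mask$frozen)) saw_release <- TRUE
  }
  expect_true(saw_frozen)
  expect_true(saw_release)
})

test_that("disabling pattern reduction gives a bit-identical trajectory to a run where it never fires", {
  sys <- cached_toy()
  cfg_off <- config_preset("toy", n_pop = 16L, n_islands = 2L, generations = 40L,
                           seed = 3L, pr_enabled = FALSE)
  # enabled but with an unsatisfiable tolerance nothing can ever freeze (a
  # zero tolerance can still catch exact duplicates left by migration), and
  # detection draws no random numbers, so the trajectories agree bit for bit
  cfg_zero <- config_preset("toy", n_pop = 16L, n_islands = 2L, generations = 40L,
                            seed = 3L, pr_enabled = TRUE,
                            pr_tolerance_translation = -1,
                            pr_tolerance_quaternion = -1,
                            pr_tolerance_torsion = -1)
  r_off <- dock(sys$receptor, sys$topology, cfg_off, bounds = sys$bounds)
  r_zero <- dock(sys$receptor, sys$topology, cfg_zero, bounds = sys$bounds)
  expect_identical(r_off$history$island_best, r_zero$history$island_best)
  expect_identical(r_off$best_genes, r_zero$best_genes)
  expect_identical(r_off$events, r_zero$events)
})

test_that("an island run with pattern reduction logs its freezing decisions", {
  sys <- cached_toy()
  cfg <- config_preset("toy", n_pop = 16L, n_islands = 2L, generations = 60L,
                       seed = 21L, pr_enabled = TRUE)
  res <- dock(sys$receptor, sys$topology, cfg, bounds = sys$bounds)
  if (nrow(res$pr_log) > 0) {
    expect_true(all(res$pr_log$n_frozen >= 1))
    expect_true(all(res$pr_log$island %in% 1:2))
  }
  succeed("pattern-reduction audit log present")
})
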