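test_that("population partition matches the floor-plus-remainder rule", {
  set.seed(1)
  mk <- function(n) new_population(matrix(rnorm(n * 8), n, 8), rnorm(n))
  # the reference configuration: 256 chromosomes over 4 islands -> 64 each
  parts <- partition_population(mk(256), 4)
  expect_equal(vapply(parts, function(p) nrow(p$genes), integer(1)), rep(64L, 4))
  # m = 1: the single subpopulation is the input
  pop <- mk(10)
  single <- partition_population(pop, 1)
  expect_identical(single[[1]]$genes, pop$genes)
  # remainder to the lowest-indexed islands; union equals input, no duplication
  pop10 <- mk(10)
  parts <- partition_population(pop10, 3)
  expect_equal(vapply(parts, function(p) nrow(p$genes), integer(1)), c(4L, 3L, 3L))
  all_genes <- do.call(rbind, lapply(parts, `[[`, "genes"))
  expect_equal(all_genes, pop10$genes, ignore_attr = TRUE)
  expect_error(partition_population(mk(3), 5), "cannot partition")
})

test_that("the migration decision matches its truth table exhaustively", {
  t_h <- 5L
  for (t_i in c(t_h - 1L, t_h, t_h + 1L)) {
    for (f_i in c(FALSE, TRUE)) {
      for (m_i in c(FALSE, TRUE)) {
        got <- migration_decision(t_i, t_h, f_i, m_i)
        want <- if (t_i == t_h && !f_i) (if (m_i) 2L else 1L) else 0L
        expect_identical(got, want)
      }
    }
  }
  # vectorized form agrees
  expect_identical(migration_decision(c(5, 5, 5, 4), 5,
                                      c(FALSE, FALSE, TRUE, FALSE),
                                      c(FALSE, TRUE, TRUE, TRUE)),
                   c(1L, 2L, 0L, 0L))
})

test_that("islands pair by closest completion time with deterministic tie-breaks", {
  # the worked example: islands 2 and 4 finish closest together and pair first
  times <- c(`2` = 11.0, `4` = 11.4, `1` = 30.0, `3` = 47.0)
  pairs <- pair_by_completion(times)
  expect_equal(pairs[[1]], c(2, 4))
  expect_equal(pairs[[2]], c(1, 3))
  # exactly two islands -> one pair
  expect_equal(pair_by_completion(c(`1` = 5, `2` = 9)), list(c(1, 2)))
  # odd count: the outlier stays unpaired
  pairs <- pair_by_completion(c(`1` = 0, `2` = 1, `3` = 100))
  expect_equal(pairs, list(c(1, 2)))
  expect_equal(pair_by_completion(c(`1` = 3)), list())
  # exact ties break towards lower island indices
  pairs <- pair_by_completion(c(`3` = 1, `1` = 1, `2` = 1, `4` = 1))
  expect_equal(pairs, list(c(1, 2), c(3, 4)))
})

mk_island <- function(id, energies, g = 8) {
  n <- length(energies)
  list(id = id, pop = new_population(matrix(rnorm(n * g), n, g), energies),
       t_i = 5L, f_i = FALSE)
}

test_that("a pairwise exchange copies elites onto the partner's worst", {
  set.seed(3)
  for (rep in 1:100) {
    a <- mk_island(1L, runif(6, -10, 0))
    b <- mk_island(2L, runif(6, -10, 0))
    out <- exchange_pair(a, b, migrant_count = 1, time = 7)
    ea <- min(a$pop$energy); eb <- min(b$pop$energy)
    # destination contains a copy of the partner's elite
    expect_true(any(out$b$pop$energy == ea))
    expect_true(any(out$a$pop$energy == eb))
    # sizes conserved, flags set, minima non-increasing
    expect_equal(nrow(out$a$pop$genes), 6)
    expect_equal(nrow(out$b$pop$genes), 6)
    expect_true(out$a$f_i && out$b$f_i)
    expect_lte(min(out$a$pop$energy), ea)
    expect_lte(min(out$b$pop$energy), eb)
    expect_equal(nrow(out$events), 2)
    expect_setequal(out$events$kind, "pairwise")
  }
})

test_that("group synchronization circulates chromosomes between groups", {
  set.seed(4)
  islands <- lapply(1:4, function(i) mk_island(i, runif(5, -10, 0)))
  groups <- c(1L, 2L, 1L, 2L)   # {1,3} and {2,4}
  out <- synchronize_groups(islands, groups, migrant_count = 1, time = 30)
  expect_false(out$skipped)
  expect_equal(nrow(out$events), 4)
  for (i in 1:4) {
    ev <- out$events[out$events$destination == i, ]
    expect_equal(nrow(ev), 1)                       # exactly migrant_count received
    expect_true(groups[ev$source] != groups[i])     # from the other group
    expect_equal(nrow(out$islands[[i]]$pop$genes), 5)
    expect_identical(out$islands[[i]]$t_i, 0L)      # window reset
    expect_false(out$islands[[i]]$f_i)
  }
  # total chromosome count conserved
  expect_equal(sum(vapply(out$islands, function(x) nrow(x$pop$genes), integer(1))), 20)
})

test_that("synchronization with a single group is a no-op that still resets counters", {
  set.seed(5)
  islands <- lapply(1:2, function(i) mk_island(i, runif(4, -5, 0)))
  before <- lapply(islands, function(x) x$pop)
  out <- synchronize_groups(islands, c(1L, 1L))
  expect_true(out$skipped)
  expect_equal(nrow(out$events), 0)
  expect_identical(lapply(out$islands, `[[`, "pop"), before)
  expect_identical(out$islands[[1]]$t_i, 0L)
})

test_that("a full island run conserves chromosomes and reports a monotone best", {
  sys <- cached_toy()
  cfg <- config_preset("toy", n_pop = 32L, n_islands = 4L, generations = 60L, seed = 11L)
  res <- dock(sys$receptor, sys$topology, cfg, bounds = sys$bounds)
  expect_s3_class(res, "docking_result")
  # conservation at the end of the run
  sizes <- vapply(res$final_populations, function(p) nrow(p$genes), integer(1))
  expect_equal(sum(sizes), 32L)
  # best-so-far is monotone non-increasing in scheduler order
  expect_true(all(diff(res$history$best_so_far) <= 1e-12))
  # the reported best matches the deepest energy seen
  expect_equal(res$best_energy$e_total, min(res$history$best_so_far))
  # the best pose re-evaluates to the reported energy
  eb <- total_energy(sys$receptor, sys$topology, res$best_pose)
  expect_equal(eb$e_total, res$best_energy$e_total, tolerance = 1e-9)
})

test_that("every island joins a migration event when several islands run", {
  sys <- cached_toy()
  cfg <- config_preset("toy", n_pop = 24L, n_islands = 4L, generations = 50L, seed = 2L)
  res <- dock(sys$receptor, sys$topology, cfg, bounds = sys$bounds)
  ev <- res$events
  expect_gt(nrow(ev), 0)
  # no starvation: every island is a source or destination within the run
  # (2 * m_t = 50 generations)
  expect_setequal(sort(unique(c(ev$source, ev$destination))), 1:4)
  # both event kinds occur
  expect_true("pairwise" %in% ev$kind)
  expect_true("synchronization" %in% ev$kind)
})

test_that("identical seeds reproduce the migration event log exactly", {
  sys <- cached_toy()
  cfg <- config_preset("toy", n_pop = 24L, n_islands = 3L, generations = 55L, seed = 9L)
  r1 <- dock(sys$receptor, sys$topology, cfg, bounds = sys$bounds)
  r2 <- dock(sys$receptor, sys$topology, cfg, bounds = sys$bounds)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$best_genes, r2$best_genes)
})

test_that("a single-island run never migrates and matches the serial algorithm", {
  sys <- cached_toy()
  cfg <- config_preset("toy", n_pop = 16L, n_islands = 1L, generations = 80L, seed = 5L)
  res <- dock(sys$receptor, sys$topology, cfg, bounds = sys$bounds)
  expect_equal(nrow(res$events), 0)
  serial <- dock_serial_lga(sys$receptor, sys$topology, cfg, bounds = sys$bounds)
  expect_equal(res$history$island_best, serial$history$island_best, tolerance = 0)
  expect_equal(res$history$best_so_far, serial$history$best_so_far, tolerance = 0)
  expect_identical(res$best_genes, serial$best_genes)
})

test_that("invalid configurations are rejected before any work", {
  expect_error(run_config(n_pop = 4L, n_islands = 8L), "n_pop")
  expect_error(run_config(m_t = 3L, t_h = 5L), "m_t")
  expect_error(run_config(crossover_rate = 1.2), "crossover_rate")
  expect_error(run_config(generations = 0L), "generations")
})
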