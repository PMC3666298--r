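# surrogate objective: separable quadratic on a free gene vector
sphere_fn <- function(G) rowSums(G^2)

sphere_spec <- function(g, scales = 1) {
  isledock:::plain_gene_spec(g, lower = -10, upper = 10, scales = scales)
}

random_sphere_pop <- function(n, g) {
  G <- matrix(runif(n * g, -5, 5), n, g)
  evaluate_population(new_population(G), sphere_fn)
}

toy_energy_env <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sys <- cached_toy()
      ctx <- make_energy_context(sys$receptor, sys$topology)
      cache <<- list(
        sys = sys, ctx = ctx,
        spec = gene_spec(length(sys$topology$branches), sys$bounds),
        energy_fn = function(G) isledock:::cpp_energy_batch(ctx, G)
      )
    }
    cache
  }
})

random_toy_pop <- function(n) {
  te <- toy_energy_env()
  G <- isledock:::init_genes(n, te$spec, length(te$sys$topology$branches), te$sys$bounds)
  evaluate_population(new_population(G), te$energy_fn)
}

test_that("a GA generation preserves population size", {
  set.seed(1)
  te <- toy_energy_env()
  for (n in c(1, 2, 7, 16)) {
    pop <- random_toy_pop(n)
    out <- ga_generation(pop, te$spec, optimizer_params(), te$energy_fn)
    expect_equal(nrow(out$pop$genes), n)
    expect_length(out$pop$energy, n)
  }
  expect_error(ga_generation(new_population(matrix(0, 0, 8)), te$spec,
                             optimizer_params(), te$energy_fn), "empty")
})

test_that("with zero variation rates and elitism the best individual survives unchanged", {
  set.seed(2)
  te <- toy_energy_env()
  pop <- random_toy_pop(12)
  params <- optimizer_params(crossover_rate = 0, mutation_rate = 0)
  best_before <- pop$genes[which.min(pop$energy), ]
  out <- ga_generation(pop, te$spec, params, te$energy_fn)
  expect_equal(min(out$pop$energy), min(pop$energy))
  expect_equal(out$pop$genes[which.min(out$pop$energy), ], best_before)
})

test_that("the GA improves the median best energy on a toy system", {
  te <- toy_energy_env()
  run_best <- function(seed, gens) {
    set.seed(seed)
    pop <- random_toy_pop(20)
    first <- min(pop$energy)
    for (g in seq_len(gens)) {
      pop <- ga_generation(pop, te$spec, optimizer_params(), te$energy_fn)$pop
    }
    c(first = first, last = min(pop$energy))
  }
  res <- vapply(1:20, run_best, numeric(2), gens = 50)
  expect_lt(median(res["last", ]), median(res["first", ]))
})

test_that("elitism keeps the subpopulation minimum non-increasing", {
  set.seed(3)
  te <- toy_energy_env()
  pop <- random_toy_pop(10)
  best <- min(pop$energy)
  for (g in 1:30) {
    pop <- ga_generation(pop, te$spec, optimizer_params(), te$energy_fn)$pop
    expect_lte(min(pop$energy), best + 1e-12)
    best <- min(pop$energy)
  }
})

test_that("Solis-Wets with a zero budget is the identity", {
  set.seed(4)
  g <- 7
  x <- runif(g)
  params <- optimizer_params(sw_max_iter = 0)
  out <- solis_wets(x, sphere_fn(matrix(x, 1)), sphere_fn, sphere_spec(g), params)
  expect_identical(out$genes, x)
  expect_equal(out$n_evals, 0L)
})

test_that("Solis-Wets minimizes the separable quadratic from distance 1", {
  set.seed(5)
  g <- 7
  x <- rnorm(g); x <- x / sqrt(sum(x^2))   # start at distance 1 from the optimum
  params <- optimizer_params(sw_max_iter = 300)
  out <- solis_wets(x, sphere_fn(matrix(x, 1)), sphere_fn, sphere_spec(g, scales = 0.3),
                    params)
  expect_lte(out$energy, 1e-3)
})

test_that("Solis-Wets never returns a worse energy and writes the genotype back", {
  set.seed(6)
  te <- toy_energy_env()
  params <- optimizer_params(sw_max_iter = 40)
  for (rep in 1:100) {
    pop <- random_toy_pop(1)
    out <- solis_wets(pop$genes[1, ], pop$energy[1], te$energy_fn, te$spec, params)
    expect_lte(out$energy, pop$energy[1])
    # Lamarckian contract: stored genotype re-evaluates to the stored energy
    expect_equal(as.numeric(te$energy_fn(matrix(out$genes, 1))), out$energy,
                 tolerance = 1e-12)
  }
})

test_that("compiled and R Solis-Wets produce identical trajectories", {
  te <- toy_energy_env()
  params <- optimizer_params(sw_max_iter = 150)
  set.seed(77)
  pop <- random_toy_pop(1)
  set.seed(123)
  r_out <- solis_wets(pop$genes[1, ], pop$energy[1], te$energy_fn, te$spec, params)
  set.seed(123)
  c_out <- isledock:::cpp_solis_wets(te$ctx, pop$genes[1, ], pop$energy[1],
                                     te$spec$scales, te$spec$lower, te$spec$upper,
                                     rep(FALSE, te$spec$n_genes),
                                     params$sw_rho0, params$sw_lb, params$sw_succ,
                                     params$sw_fail, params$sw_max_iter)
  expect_equal(c_out$genes, r_out$genes, tolerance = 1e-12)
  expect_equal(c_out$energy, r_out$energy, tolerance = 1e-12)
  expect_equal(c_out$n_evals, r_out$n_evals)
})

test_that("local search applies to the expected fraction of individuals", {
  te <- toy_energy_env()
  set.seed(8)
  pop <- random_toy_pop(20)
  params0 <- optimizer_params(local_search_rate = 0)
  out0 <- apply_local_search(pop, te$spec, params0, te$energy_fn)
  expect_identical(out0$pop$genes, pop$genes)

  params1 <- optimizer_params(local_search_rate = 1, sw_max_iter = 10)
  out1 <- apply_local_search(pop, te$spec, params1, te$energy_fn)
  expect_true(all(out1$pop$energy <= pop$energy))

  # binomial count check at rate 0.3 over many sweeps
  rate <- 0.3
  n <- 20; trials <- 600
  params <- optimizer_params(local_search_rate = rate, sw_max_iter = 0)
  hits <- replicate(trials, {
    out <- apply_local_search(pop, te$spec, params, te$energy_fn)
    out$units[["ls_calls"]]
  })
  se <- sqrt(n * rate * (1 - rate) / trials)
  expect_lt(abs(mean(hits) - n * rate), 3 * se)
})

test_that("differential evolution is greedy and minimizes the sphere", {
  set.seed(9)
  g <- 10
  spec <- sphere_spec(g)
  pop <- random_sphere_pop(32, g)
  params <- optimizer_params()
  best <- min(pop$energy)
  for (gen in 1:500) {
    pop <- de_generation(pop, spec, params, sphere_fn)$pop
    expect_lte(min(pop$energy), best + 1e-12)
    best <- min(pop$energy)
  }
  expect_lte(best, 1e-2)
})

test_that("differential evolution with F = 0 and CR = 0 leaves the population unchanged", {
  set.seed(10)
  g <- 8
  pop <- random_sphere_pop(8, g)
  params <- optimizer_params(de_f = 0, de_cr = 0)
  out <- de_generation(pop, sphere_spec(g), params, sphere_fn)
  expect_equal(out$pop$genes, pop$genes)
  expect_equal(out$pop$energy, pop$energy)
  expect_error(de_generation(random_sphere_pop(3, g), sphere_spec(g), params, sphere_fn),
               "at least 4")
})

test_that("PSO with zero coefficients and zero velocity is stationary", {
  set.seed(11)
  g <- 8
  pop <- random_sphere_pop(10, g)
  swarm <- make_swarm(pop)
  params <- optimizer_params(pso_w = 0, pso_c1 = 0, pso_c2 = 0)
  out <- pso_generation(swarm, sphere_spec(g), params, sphere_fn)
  expect_equal(out$swarm$genes, pop$genes)
})

test_that("the PSO global best is monotone and minimizes the sphere", {
  set.seed(12)
  g <- 10
  spec <- sphere_spec(g)
  swarm <- make_swarm(random_sphere_pop(32, g))
  params <- optimizer_params()
  gbest <- swarm$gbest_energy
  for (gen in 1:500) {
    swarm <- pso_generation(swarm, spec, params, sphere_fn)$swarm
    expect_lte(swarm$gbest_energy, gbest + 1e-12)
    gbest <- swarm$gbest_energy
  }
  expect_lte(gbest, 1e-2)
})

test_that("identical seeds give identical optimizer trajectories", {
  te <- toy_energy_env()
  run <- function(kind) {
    set.seed(31)
    pop <- random_toy_pop(12)
    for (g in 1:10) {
      pop <- switch(kind,
        ga = ga_generation(pop, te$spec, optimizer_params(), te$energy_fn)$pop,
        de = de_generation(pop, te$spec, optimizer_params(), te$energy_fn)$pop)
    }
    pop
  }
  expect_identical(run("ga"), run("ga"))
  expect_identical(run("de"), run("de"))
})
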