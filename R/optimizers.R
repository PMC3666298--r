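#' Optimizer parameters
#'
#' Settings shared by the per-island optimizers. The genetic algorithm uses
#' fitness-proportional selection on `(worst - E)` shifted scores, two-point
#' crossover on the flattened gene vector, per-gene additive Cauchy mutation
#' (heavy tails help escape local minima), and keeps `elitism` elite
#' individuals unmodified. Solis-Wets is a derivative-free adaptive random
#' local search: the step multiplier doubles after `sw_succ` consecutive
#' successes and halves after `sw_fail` consecutive failures, and the search
#' stops after `sw_max_iter` iterations or once the multiplier drops below
#' `sw_lb`. Improvements are written back into the genotype (Lamarckian
#' inheritance).
#'
#' @param crossover_rate,mutation_rate,local_search_rate Probabilities in
#'   `[0, 1]`.
#' @param elitism Number of elite individuals copied unchanged each generation.
#' @param sw_rho0,sw_lb Initial and minimum Solis-Wets step multiplier
#'   (`sw_rho0 > sw_lb > 0`).
#' @param sw_succ,sw_fail Run lengths that double / halve the step.
#' @param sw_max_iter Iteration budget of one local search.
#' @param de_f,de_cr Differential-evolution scale factor and crossover rate
#'   (rand/1/bin).
#' @param pso_w,pso_c1,pso_c2 Particle-swarm inertia weight and acceleration
#'   coefficients.
#' @return An `optimizer_params` list.
#' @export
optimizer_params <- function(crossover_rate = 0.9, mutation_rate = 0.08,
                             local_search_rate = 0.06, elitism = 1L,
                             sw_rho0 = 1.0, sw_lb = 0.01, sw_succ = 4L,
                             sw_fail = 4L, sw_max_iter = 300L,
                             de_f = 0.8, de_cr = 0.9,
                             pso_w = 0.729, pso_c1 = 1.49445, pso_c2 = 1.49445) {
  rates <- c(crossover_rate = crossover_rate, mutation_rate = mutation_rate,
             local_search_rate = local_search_rate, de_cr = de_cr)
  for (nm in names(rates)) {
    if (rates[[nm]] < 0 || rates[[nm]] > 1) {
      stop(sprintf("%s must be in [0, 1]", nm), call. = FALSE)
    }
  }
  if (!(sw_rho0 > sw_lb && sw_lb > 0)) {
    stop("Solis-Wets steps must satisfy sw_rho0 > sw_lb > 0", call. = FALSE)
  }
  structure(list(crossover_rate = crossover_rate, mutation_rate = mutation_rate,
                 local_search_rate = local_search_rate, elitism = as.integer(elitism),
                 sw_rho0 = sw_rho0, sw_lb = sw_lb, sw_succ = as.integer(sw_succ),
                 sw_fail = as.integer(sw_fail), sw_max_iter = as.integer(sw_max_iter),
                 de_f = de_f, de_cr = de_cr,
                 pso_w = pso_w, pso_c1 = pso_c1, pso_c2 = pso_c2),
            class = "optimizer_params")
}

#' Populations of candidate solutions
#'
#' A population stores the flattened gene vectors as a matrix (one row per
#' individual, "chromosome") plus the corresponding energies. When the energy
#' vector is set it equals the objective at the stored genotype.
#'
#' @param genes Numeric matrix, one row per individual.
#' @param energy Numeric vector of objective values, or `NULL` if unevaluated.
#' @return A `population` object.
#' @export
new_population <- function(genes, energy = NULL) {
  stopifnot(is.matrix(genes))
  if (!is.null(energy)) stopifnot(length(energy) == nrow(genes))
  structure(list(genes = genes, energy = energy), class = "population")
}

#' @rdname new_population
#' @param pop A `population`.
#' @param energy_fn Objective: a function taking a gene matrix and returning a
#'   numeric vector of energies (lower is better).
#' @export
evaluate_population <- function(pop, energy_fn) {
  pop$energy <- as.numeric(energy_fn(pop$genes))
  pop
}

best_index <- function(energy) which.min(energy)   # ties: lowest index
worst_index <- function(energy) which.max(energy)

mask_frozen <- function(mask, n_genes) {
  if (is.null(mask)) rep(FALSE, n_genes) else mask$frozen
}

#' One genetic-algorithm generation
#'
#' Fitness-proportional selection on `(worst - E)`, two-point crossover at
#' `crossover_rate`, per-gene Cauchy mutation at `mutation_rate` (frozen loci
#' skipped), gene repair (box clamp, quaternion renormalization, torsion
#' wrapping), evaluation of the offspring, and elitist replacement of the worst
#' offspring by the best parents. Population size is preserved.
#'
#' @param pop Evaluated `population`.
#' @param spec A [gene_spec()].
#' @param params An [optimizer_params()].
#' @param energy_fn Objective function over gene matrices.
#' @param mask Optional `frozen_mask` from [detect_frozen_loci()].
#' @return A list: `pop` (next generation), `units` (named operation counts for
#'   the cost model).
#' @export
ga_generation <- function(pop, spec, params, energy_fn, mask = NULL) {
  n <- nrow(pop$genes)
  if (n == 0) stop("empty subpopulation", call. = FALSE)
  if (is.null(pop$energy)) stop("population must be evaluated before ga_generation", call. = FALSE)
  g <- spec$n_genes
  frozen <- mask_frozen(mask, g)

  # selection: proportional on shifted scores
  w <- max(pop$energy) - pop$energy
  if (sum(w) <= 0) w <- rep(1, n)
  parents <- sample.int(n, n, replace = TRUE, prob = w)
  G <- pop$genes[parents, , drop = FALSE]

  # two-point crossover on consecutive pairs
  n_cross <- 0L
  if (n >= 2 && g >= 3) {
    for (i in seq(1, n - 1, by = 2)) {
      if (stats::runif(1) < params$crossover_rate) {
        cp <- sort(sample.int(g - 1, 2))
        seg <- (cp[1] + 1):cp[2]
        tmp <- G[i, seg]
        G[i, seg] <- G[i + 1, seg]
        G[i + 1, seg] <- tmp
        n_cross <- n_cross + 1L
      }
    }
  }

  # Cauchy mutation, frozen loci excluded
  mut <- matrix(stats::runif(n * g) < params$mutation_rate, n, g)
  if (any(frozen)) mut[, frozen] <- FALSE
  n_mut <- sum(mut)
  if (n_mut > 0) {
    scl <- matrix(spec$scales, n, g, byrow = TRUE)
    G[mut] <- G[mut] + stats::rcauchy(n_mut) * scl[mut]
  }

  G <- repair_genes(G, spec)
  E <- as.numeric(energy_fn(G))

  # elitism: best parents replace worst offspring, unmodified
  k <- min(params$elitism, n)
  if (k > 0) {
    elite <- order(pop$energy)[seq_len(k)]
    slots <- order(E, decreasing = TRUE)[seq_len(k)]
    G[slots, ] <- pop$genes[elite, , drop = FALSE]
    E[slots] <- pop$energy[elite]
  }

  list(pop = new_population(G, E),
       units = c(selection = n, crossover = n_cross, mutation = n_mut, evaluation = n))
}

#' Solis-Wets local search
#'
#' Adaptive random local search on the flattened gene vector. Each iteration
#' draws a Gaussian step `rho * scales * N(0, 1)` (frozen loci zeroed), tries
#' the step and its reverse, and accepts whichever improves the energy.
#' `sw_succ` consecutive successes double `rho`; `sw_fail` consecutive failures
#' halve it; the search stops at `sw_max_iter` iterations or when `rho` falls
#' below `sw_lb`. The improved genotype replaces the input genotype
#' (Lamarckian write-back), so the returned energy never exceeds the input
#' energy.
#'
#' @param genes Numeric gene vector.
#' @param energy Objective value at `genes`.
#' @param energy_fn Objective function over gene matrices.
#' @param spec A [gene_spec()].
#' @param params An [optimizer_params()].
#' @param mask Optional `frozen_mask`.
#' @return A list: `genes`, `energy`, `n_evals`.
#' @export
solis_wets <- function(genes, energy, energy_fn, spec, params, mask = NULL) {
  g <- length(genes)
  frozen <- mask_frozen(mask, g)
  rho <- params$sw_rho0
  n_succ <- 0L; n_fail <- 0L; n_evals <- 0L
  base <- spec$scales
  for (iter in seq_len(params$sw_max_iter)) {
    if (rho < params$sw_lb) break
    d <- stats::rnorm(g) * base * rho
    d[frozen] <- 0
    cand <- repair_genes(matrix(genes + d, 1), spec)
    e1 <- as.numeric(energy_fn(cand))
    n_evals <- n_evals + 1L
    improved <- FALSE
    if (e1 < energy) {
      genes <- cand[1, ]; energy <- e1; improved <- TRUE
    } else {
      cand2 <- repair_genes(matrix(genes - d, 1), spec)
      e2 <- as.numeric(energy_fn(cand2))
      n_evals <- n_evals + 1L
      if (e2 < energy) {
        genes <- cand2[1, ]; energy <- e2; improved <- TRUE
      }
    }
    if (improved) {
      n_succ <- n_succ + 1L; n_fail <- 0L
      if (n_succ >= params$sw_succ) { rho <- rho * 2; n_succ <- 0L }
    } else {
      n_fail <- n_fail + 1L; n_succ <- 0L
      if (n_fail >= params$sw_fail) { rho <- rho / 2; n_fail <- 0L }
    }
  }
  list(genes = genes, energy = energy, n_evals = n_evals)
}

#' Lamarckian local-search sweep
#'
#' Each individual is independently selected with probability
#' `local_search_rate` and refined with [solis_wets()]; improvements are
#' written back into the population genotypes.
#'
#' @inheritParams ga_generation
#' @param context Optional [make_energy_context()]; when supplied, the search
#'   runs in the compiled kernel (drawing the same random numbers as the R
#'   implementation, so trajectories are identical).
#' @return A list: `pop`, `units` (`local_search` = number of local-search
#'   energy evaluations).
#' @export
apply_local_search <- function(pop, spec, params, energy_fn, mask = NULL,
                               context = NULL) {
  n <- nrow(pop$genes)
  chosen <- which(stats::runif(n) < params$local_search_rate)
  evals <- 0L
  frozen <- mask_frozen(mask, spec$n_genes)
  for (i in chosen) {
    res <- if (!is.null(context)) {
      cpp_solis_wets(context, pop$genes[i, ], pop$energy[i], spec$scales,
                     spec$lower, spec$upper, frozen, params$sw_rho0,
                     params$sw_lb, params$sw_succ, params$sw_fail,
                     params$sw_max_iter)
    } else {
      solis_wets(pop$genes[i, ], pop$energy[i], energy_fn, spec, params, mask)
    }
    pop$genes[i, ] <- res$genes
    pop$energy[i] <- res$energy
    evals <- evals + res$n_evals
  }
  list(pop = pop, units = c(local_search = evals, ls_calls = length(chosen)))
}

#' One differential-evolution generation (rand/1/bin)
#'
#' For each target, a mutant `x_r1 + F (x_r2 - x_r3)` is built from three
#' distinct other individuals and recombined gene-wise at rate `de_cr`; the
#' trial replaces the target only if it is no worse (greedy replacement), so
#' the best energy never worsens.
#'
#' @inheritParams ga_generation
#' @return A list: `pop`, `units`.
#' @export
de_generation <- function(pop, spec, params, energy_fn, mask = NULL) {
  n <- nrow(pop$genes)
  if (n < 4) stop("differential evolution needs a subpopulation of at least 4", call. = FALSE)
  g <- spec$n_genes
  frozen <- mask_frozen(mask, g)
  G <- pop$genes
  trials <- G
  for (i in seq_len(n)) {
    r <- sample(setdiff(seq_len(n), i), 3)
    v <- G[r[1], ] + params$de_f * (G[r[2], ] - G[r[3], ])
    cross <- stats::runif(g) < params$de_cr
    cross[frozen] <- FALSE
    trials[i, cross] <- v[cross]
  }
  trials <- repair_genes(trials, spec)
  Et <- as.numeric(energy_fn(trials))
  replace <- Et <= pop$energy
  G[replace, ] <- trials[replace, , drop = FALSE]
  E <- ifelse(replace, Et, pop$energy)
  list(pop = new_population(G, E),
       units = c(mutation = n, evaluation = n))
}

#' Particle swarm over the gene vector
#'
#' `make_swarm()` wraps an evaluated population with zero velocities and
#' personal/global bests. `pso_generation()` applies the standard
#' inertia-weight velocity and position update, repairs the genes, and updates
#' the bests; the global best is monotone non-increasing.
#'
#' @param pop Evaluated `population`.
#' @return `make_swarm()`: a `swarm` object.
#' @export
make_swarm <- function(pop) {
  stopifnot(!is.null(pop$energy))
  b <- best_index(pop$energy)
  structure(list(genes = pop$genes, velocity = 0 * pop$genes, energy = pop$energy,
                 pbest_genes = pop$genes, pbest_energy = pop$energy,
                 gbest_genes = pop$genes[b, ], gbest_energy = pop$energy[b]),
            class = "swarm")
}

#' @rdname make_swarm
#' @param swarm A `swarm`.
#' @inheritParams ga_generation
#' @return `pso_generation()`: a list with the updated `swarm` and `units`.
#' @export
pso_generation <- function(swarm, spec, params, energy_fn, mask = NULL) {
  n <- nrow(swarm$genes)
  if (n == 0) stop("empty swarm", call. = FALSE)
  g <- spec$n_genes
  frozen <- mask_frozen(mask, g)
  R1 <- matrix(stats::runif(n * g), n, g)
  R2 <- matrix(stats::runif(n * g), n, g)
  gb <- matrix(swarm$gbest_genes, n, g, byrow = TRUE)
  V <- params$pso_w * swarm$velocity +
    params$pso_c1 * R1 * (swarm$pbest_genes - swarm$genes) +
    params$pso_c2 * R2 * (gb - swarm$genes)
  if (any(frozen)) V[, frozen] <- 0
  X <- repair_genes(swarm$genes + V, spec)
  E <- as.numeric(energy_fn(X))
  swarm$velocity <- V
  swarm$genes <- X
  swarm$energy <- E
  upd <- E < swarm$pbest_energy
  swarm$pbest_genes[upd, ] <- X[upd, , drop = FALSE]
  swarm$pbest_energy[upd] <- E[upd]
  b <- best_index(swarm$pbest_energy)
  if (swarm$pbest_energy[b] < swarm$gbest_energy) {
    swarm$gbest_energy <- swarm$pbest_energy[b]
    swarm$gbest_genes <- swarm$pbest_genes[b, ]
  }
  list(swarm = swarm, units = c(evaluation = n))
}
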