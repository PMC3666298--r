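#' Partition a population across islands
#'
#' Splits a population of `N` individuals into `m` subpopulations of size
#' `floor(N / m)`, the remainder going to the lowest-indexed islands. The union
#' of the subpopulations equals the input, with no duplication.
#'
#' @param pop A `population`.
#' @param m Number of islands.
#' @return A list of `m` populations.
#' @export
partition_population <- function(pop, m) {
  n <- nrow(pop$genes)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (m > n) stop(sprintf("cannot partition %d individuals across %d islands", n, m),
                  call. = FALSE)
  sizes <- rep(n %/% m, m) + (seq_len(m) <= n %% m)
  stops <- cumsum(sizes)
  starts <- stops - sizes + 1
  lapply(seq_len(m), function(i) {
    idx <- starts[i]:stops[i]
    new_population(pop$genes[idx, , drop = FALSE],
                   if (is.null(pop$energy)) NULL else pop$energy[idx])
  })
}

#' Asynchronous migration decision
#'
#' The per-island migration policy. An island becomes migration-eligible
#' exactly when its window iteration counter reaches the threshold and it has
#' not migrated in this window: the function returns `1` (post the elite for
#' emigration and wait) when `t_i == t_h`, `f_i` is false and the master signal
#' `m_i` is false, `2` (participate in the master-directed exchange now) when
#' additionally `m_i` is true, and `0` otherwise. Pure and vectorized.
#'
#' @param t_i Iterations completed since the last window reset.
#' @param t_h Migration threshold (>= 1).
#' @param f_i Has this island already migrated this window?
#' @param m_i Master signal: is a partner island ready to exchange?
#' @return Integer code(s) in `{0, 1, 2}`.
#' @export
migration_decision <- function(t_i, t_h, f_i, m_i) {
  stopifnot(all(t_i >= 0), all(t_h >= 1))
  k <- max(length(t_i), length(f_i), length(m_i))
  t_i <- rep_len(t_i, k); f_i <- rep_len(f_i, k); m_i <- rep_len(m_i, k)
  out <- integer(k)
  eligible <- t_i == t_h & !f_i
  out[eligible & m_i] <- 2L
  out[eligible & !m_i] <- 1L
  out
}

#' Pair islands by closest completion time
#'
#' Greedy matching: repeatedly pair the two unpaired islands whose completion
#' times are closest, ties broken by lower island index. With an odd count the
#' leftover island stays unpaired this round.
#'
#' @param completion_times Numeric vector of completion times.
#' @param ids Island ids (defaults to names or positions of
#'   `completion_times`).
#' @return A list of length-2 integer vectors (island id pairs); empty if fewer
#'   than two islands.
#' @export
pair_by_completion <- function(completion_times, ids = NULL) {
  if (is.null(ids)) {
    ids <- if (!is.null(names(completion_times))) {
      as.integer(names(completion_times))
    } else {
      seq_along(completion_times)
    }
  }
  k <- length(ids)
  if (k < 2) return(list())
  ord <- order(ids)
  ids <- ids[ord]; tt <- completion_times[ord]
  cmb <- utils::combn(k, 2)
  d <- abs(tt[cmb[1, ]] - tt[cmb[2, ]])
  rank <- order(d, ids[cmb[1, ]], ids[cmb[2, ]])
  used <- logical(k)
  pairs <- list()
  for (p in rank) {
    a <- cmb[1, p]; b <- cmb[2, p]
    if (!used[a] && !used[b]) {
      used[a] <- used[b] <- TRUE
      pairs[[length(pairs) + 1]] <- c(ids[a], ids[b])
    }
  }
  pairs
}

empty_events <- function() {
  tibble::tibble(time = numeric(0), kind = character(0), source = integer(0),
                 destination = integer(0), migrant_energy = numeric(0))
}

#' Pairwise elite exchange between two islands
#'
#' Each island sends a copy of its `migrant_count` lowest-energy individuals;
#' each incoming migrant replaces the destination's current worst individual.
#' Both migration-done flags are set; subpopulation sizes are unchanged, and
#' the minimum energy of each island cannot increase.
#'
#' @param a,b Island states (lists with `id`, `pop`, `f_i`).
#' @param migrant_count Migrants per direction.
#' @param time Logical time recorded on the events.
#' @return A list: updated `a`, `b`, and an `events` tibble.
#' @export
exchange_pair <- function(a, b, migrant_count = 1, time = NA_real_) {
  migrant_count <- min(migrant_count, nrow(a$pop$genes), nrow(b$pop$genes))
  elite_a <- order(a$pop$energy)[seq_len(migrant_count)]
  elite_b <- order(b$pop$energy)[seq_len(migrant_count)]
  ga <- a$pop$genes[elite_a, , drop = FALSE]; ea <- a$pop$energy[elite_a]
  gb <- b$pop$genes[elite_b, , drop = FALSE]; eb <- b$pop$energy[elite_b]
  events <- list()
  for (k in seq_len(migrant_count)) {
    wb <- worst_index(b$pop$energy)
    b$pop$genes[wb, ] <- ga[k, ]; b$pop$energy[wb] <- ea[k]
    wa <- worst_index(a$pop$energy)
    a$pop$genes[wa, ] <- gb[k, ]; a$pop$energy[wa] <- eb[k]
    events[[length(events) + 1]] <- tibble::tibble(
      time = time, kind = "pairwise", source = a$id, destination = b$id,
      migrant_energy = ea[k])
    events[[length(events) + 1]] <- tibble::tibble(
      time = time, kind = "pairwise", source = b$id, destination = a$id,
      migrant_energy = eb[k])
  }
  a$f_i <- TRUE; b$f_i <- TRUE
  list(a = a, b = b, events = dplyr::bind_rows(events))
}

#' Cross-group synchronization
#'
#' Once every island has completed the synchronization interval, islands are
#' grouped by the connected components of this window's pairwise-exchange
#' graph, and every island receives `migrant_count` chromosomes picked
#' uniformly at random from the subpopulations of the other groups (replacing
#' its worst individuals), so information circulates between groups. Donor
#' subpopulations are snapshot before any replacement. All window counters and
#' migration-done flags are reset. With a single group the exchange is skipped
#' (counters still reset). Uses R's current random stream.
#'
#' @param islands List of island states.
#' @param groups Integer group id per island (connected components of the
#'   window's exchange graph).
#' @param migrant_count Chromosomes received per island.
#' @param time Logical time recorded on the events.
#' @return A list: `islands`, `events`, `skipped`.
#' @export
synchronize_groups <- function(islands, groups, migrant_count = 1, time = NA_real_) {
  m <- length(islands)
  reset <- function(isls) {
    lapply(isls, function(x) { x$t_i <- 0L; x$f_i <- FALSE; x })
  }
  if (m < 2 || length(unique(groups)) < 2) {
    return(list(islands = reset(islands), events = empty_events(), skipped = TRUE))
  }
  donors <- lapply(islands, function(x) x$pop)   # snapshot: simultaneous semantics
  events <- list()
  for (i in seq_len(m)) {
    others <- which(groups != groups[i])
    for (k in seq_len(migrant_count)) {
      src <- others[sample.int(length(others), 1)]
      row <- sample.int(nrow(donors[[src]]$genes), 1)
      w <- worst_index(islands[[i]]$pop$energy)
      islands[[i]]$pop$genes[w, ] <- donors[[src]]$genes[row, ]
      islands[[i]]$pop$energy[w] <- donors[[src]]$energy[row]
      events[[length(events) + 1]] <- tibble::tibble(
        time = time, kind = "synchronization",
        source = islands[[src]]$id, destination = islands[[i]]$id,
        migrant_energy = donors[[src]]$energy[row])
    }
  }
  list(islands = reset(islands), events = dplyr::bind_rows(events), skipped = FALSE)
}

# ---- island evolution step --------------------------------------------------

add_units <- function(total, add) {
  for (nm in names(add)) {
    total[nm] <- (if (nm %in% names(total)) total[nm] else 0) + add[[nm]]
  }
  total
}

# one generation of the island's optimizer under the CURRENT RNG stream;
# returns the updated island state and the operation counts
evolve_island_once <- function(isl, cfg, opt, spec, energy_fn, context = NULL) {
  units <- c(selection = 0, crossover = 0, mutation = 0, evaluation = 0,
             local_search = 0)
  mask <- NULL
  if (cfg$optimizer == "lga") {
    if (cfg$pr_enabled && nrow(isl$pop$genes) >= 2) {
      ps <- pr_step(isl$prs, isl$pop, spec, isl$total + 1L)
      isl$prs <- ps$state
      mask <- ps$mask
      if (any(mask$frozen)) {
        ap <- apply_pattern_reduction(isl$pop, mask, energy_fn)
        isl$pop <- ap$pop
        units <- add_units(units, ap$units)
        isl$pr_log[[length(isl$pr_log) + 1]] <-
          tibble::tibble(generation = isl$total + 1L, island = isl$id,
                         n_frozen = sum(mask$frozen),
                         loci = paste(which(mask$frozen), collapse = ","))
      }
    }
    gg <- ga_generation(isl$pop, spec, opt, energy_fn, mask)
    isl$pop <- gg$pop
    units <- add_units(units, gg$units)
    ls <- apply_local_search(isl$pop, spec, opt, energy_fn, mask, context)
    isl$pop <- ls$pop
    units <- add_units(units, ls$units["local_search"])
  } else if (cfg$optimizer == "de") {
    dg <- de_generation(isl$pop, spec, opt, energy_fn)
    isl$pop <- dg$pop
    units <- add_units(units, dg$units)
    ls <- apply_local_search(isl$pop, spec, opt, energy_fn, context = context)
    isl$pop <- ls$pop
    units <- add_units(units, ls$units["local_search"])
  } else {                                   # pso
    pg <- pso_generation(isl$swarm, spec, opt, energy_fn)
    isl$swarm <- pg$swarm
    units <- add_units(units, pg$units)
    popv <- new_population(isl$swarm$genes, isl$swarm$energy)
    ls <- apply_local_search(popv, spec, opt, energy_fn, context = context)
    units <- add_units(units, ls$units["local_search"])
    isl$swarm <- swarm_absorb(isl$swarm, ls$pop)
    isl$pop <- new_population(isl$swarm$genes, isl$swarm$energy)
  }
  if (cfg$optimizer == "pso") {
    isl$pop <- new_population(isl$swarm$genes, isl$swarm$energy)
  }
  isl$total <- isl$total + 1L
  isl$t_i <- isl$t_i + 1L
  list(isl = isl, units = units)
}

# write externally modified genes/energies back into a swarm (after local
# search or migration): positions replace, improved energies update the
# personal bests, changed rows lose their velocity
swarm_absorb <- function(swarm, pop) {
  changed <- rowSums(swarm$genes != pop$genes) > 0
  swarm$genes <- pop$genes
  swarm$energy <- pop$energy
  swarm$velocity[changed, ] <- 0
  upd <- swarm$energy < swarm$pbest_energy
  swarm$pbest_genes[upd, ] <- swarm$genes[upd, , drop = FALSE]
  swarm$pbest_energy[upd] <- swarm$energy[upd]
  b <- best_index(swarm$pbest_energy)
  if (swarm$pbest_energy[b] < swarm$gbest_energy) {
    swarm$gbest_energy <- swarm$pbest_energy[b]
    swarm$gbest_genes <- swarm$pbest_genes[b, ]
  }
  swarm
}

connected_components <- function(m, edges) {
  parent <- seq_len(m)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (e in edges) {
    ra <- find(e[1]); rb <- find(e[2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  vapply(seq_len(m), find, integer(1))
}

init_genes <- function(n, spec, n_torsions, bounds) {
  t(vapply(seq_len(n), function(i) pose_to_genes(random_pose(bounds, n_torsions)),
           numeric(spec$n_genes)))
}

unit_cost_vector <- function(cfg) {
  c(selection = cfg$cost_selection, crossover = cfg$cost_crossover,
    mutation = cfg$cost_mutation, evaluation = cfg$cost_evaluation,
    local_search = cfg$cost_local_search)
}

default_bounds <- function(receptor, margin = 5) {
  xyz <- as.matrix(receptor$atoms[, c("x", "y", "z")])
  search_bounds(apply(xyz, 2, min) - margin, apply(xyz, 2, max) + margin)
}

new_island <- function(id, pop, cfg, seed) {
  structure(list(
    id = id, pop = pop, swarm = if (cfg$optimizer == "pso") make_swarm(pop) else NULL,
    t_i = 0L, f_i = FALSE, total = 0L, time = 0,
    stream = stream_new(derive_seed(seed, id)),
    prs = pr_state(redetect = cfg$pr_redetect, release = cfg$pr_release,
                   top_fraction = cfg$pr_top_fraction,
                   tolerance = NULL),
    pr_log = list()
  ), class = "island_state")
}

island_pr_tolerance <- function(cfg, spec) {
  default_pr_tolerance(spec, cfg$pr_tolerance_translation,
                       cfg$pr_tolerance_quaternion, cfg$pr_tolerance_torsion)
}

# ---- main entry points ------------------------------------------------------

#' Dock a flexible ligand into a rigid receptor
#'
#' Runs the asynchronous island-model search: the initial population of
#' `n_pop` random poses is partitioned across `n_islands` islands, each island
#' evolves its subpopulation independently (genetic generation, optional
#' pattern reduction, Lamarckian Solis-Wets local search — or a DE/PSO
#' baseline) on a deterministic discrete-event scheduler with heterogeneous,
#' jittered iteration costs. After every island iteration the migration policy
#' ([migration_decision()]) is evaluated; eligible islands are paired by
#' closest completion time ([pair_by_completion()]) and exchange elite
#' chromosomes ([exchange_pair()]); once every island has run `m_t` iterations
#' the groups formed by this window's exchanges are synchronized
#' ([synchronize_groups()]) and the window restarts. The run terminates after
#' `generations` iterations per island.
#'
#' @param receptor A `receptor`.
#' @param topology A `ligand_topology`.
#' @param config A [run_config()].
#' @param bounds A [search_bounds()]; defaults to the receptor bounding box
#'   plus a 5 Angstrom margin.
#' @param ff A [force_field_params()].
#' @return A `docking_result`: `best_pose`, `best_energy` (breakdown),
#'   `history` (per-generation tibble), `events` (migration log tibble),
#'   `op_units` (operation counts per island and category), `pr_log`,
#'   `final_populations`, `config`, `simulated_time`.
#' @export
#' @examples
#' sys <- make_toy_system(seed = 1, n_atoms = 3, n_torsions = 0)
#' cfg <- config_preset("toy", n_pop = 16L, n_islands = 2L, generations = 10L)
#' res <- dock(sys$receptor, sys$topology, cfg, bounds = sys$bounds)
#' res$best_energy
dock <- function(receptor, topology, config = config_preset("toy"), bounds = NULL,
                 ff = force_field_params()) {
  config <- validate_run_config(config)
  m <- config$n_islands
  if (is.null(bounds)) bounds <- default_bounds(receptor)
  nt <- length(topology$branches)
  spec <- gene_spec(nt, bounds)
  ctx <- make_energy_context(receptor, topology, ff)
  energy_fn <- function(G) cpp_energy_batch(ctx, G)
  opt <- as_optimizer_params(config)
  ucost <- unit_cost_vector(config)
  speed <- if (m == 1) 1 else 1 + config$cost_heterogeneity * (seq_len(m) - 1) / (m - 1)

  with_preserved_rng({
    init_stream <- stream_new(derive_seed(config$seed, 0))
    G0 <- stream_eval(init_stream, function() init_genes(config$n_pop, spec, nt, bounds))$value
    E0 <- as.numeric(energy_fn(G0))
    subpops <- partition_population(new_population(G0, E0), m)
    islands <- lapply(seq_len(m), function(i) {
      isl <- new_island(i, subpops[[i]], config, config$seed)
      isl$prs$tolerance <- island_pr_tolerance(config, spec)
      isl
    })
    sched_stream <- stream_new(derive_seed(config$seed, 10007))

    best_i <- which.min(E0)
    best_genes <- G0[best_i, ]
    best_energy <- E0[best_i]

    units_mat <- matrix(0, m, 6,
                        dimnames = list(NULL, c("selection", "crossover", "mutation",
                                                "evaluation", "local_search",
                                                "send_and_receive")))
    history <- vector("list", m * config$generations)
    events <- list()
    ready <- integer(0)       # island ids awaiting a migration partner
    ready_time <- rep(NA_real_, m)
    edges <- list()           # this window's exchange graph
    step <- 0L

    do_sync <- function() {
      groups <- connected_components(m, edges)
      sr <- stream_eval(sched_stream, function() {
        synchronize_groups(islands, groups, config$migrant_count,
                           time = max(vapply(islands, `[[`, numeric(1), "time")))
      })
      sched_stream <<- sr$stream
      out <- sr$value
      islands <<- out$islands
      if (!out$skipped) {
        events[[length(events) + 1]] <<- out$events
        n_recv <- config$migrant_count
        for (i in seq_len(m)) {
          units_mat[i, "send_and_receive"] <<- units_mat[i, "send_and_receive"] + n_recv
          islands[[i]]$time <<- islands[[i]]$time +
            n_recv * config$cost_send_receive * speed[i]
        }
      }
      # swarm bookkeeping after migrant replacement
      if (config$optimizer == "pso") {
        for (i in seq_len(m)) {
          islands[[i]]$swarm <<- swarm_absorb(islands[[i]]$swarm, islands[[i]]$pop)
        }
      }
      ready <<- integer(0)
      ready_time <<- rep(NA_real_, m)
      edges <<- list()
    }

    repeat {
      totals <- vapply(islands, `[[`, integer(1), "total")
      active <- which(totals < config$generations)
      if (length(active) == 0) break
      t_is <- vapply(islands, `[[`, integer(1), "t_i")
      runnable <- active[t_is[active] < config$m_t]
      if (length(runnable) == 0) {
        do_sync()
        next
      }
      times <- vapply(islands, `[[`, numeric(1), "time")
      i <- runnable[order(times[runnable], runnable)[1]]

      sr <- stream_eval(islands[[i]]$stream, function() {
        evolve_island_once(islands[[i]], config, opt, spec, energy_fn, ctx)
      })
      islands[[i]] <- sr$value$isl
      islands[[i]]$stream <- sr$stream
      u <- sr$value$units
      for (nm in names(u)) units_mat[i, nm] <- units_mat[i, nm] + u[[nm]]

      jr <- stream_eval(sched_stream, function() {
        stats::runif(1, 1 - config$cost_jitter, 1 + config$cost_jitter)
      })
      sched_stream <- jr$stream
      cost <- sum(u * ucost[names(u)]) * speed[i] * jr$value
      islands[[i]]$time <- islands[[i]]$time + cost

      ib <- min(islands[[i]]$pop$energy)
      if (ib < best_energy) {
        best_energy <- ib
        best_genes <- islands[[i]]$pop$genes[best_index(islands[[i]]$pop$energy), ]
      }
      step <- step + 1L
      history[[step]] <- c(step = step, island = i,
                           generation = islands[[i]]$total,
                           island_best = ib, best_so_far = best_energy,
                           time = islands[[i]]$time)

      # migration policy
      decision <- migration_decision(islands[[i]]$t_i, config$t_h,
                                     islands[[i]]$f_i, length(ready) > 0)
      if (decision > 0) {
        ready <- c(ready, i)
        ready_time[i] <- islands[[i]]$time
        if (length(ready) >= 2) {
          pairs <- pair_by_completion(ready_time[ready], ids = ready)
          for (pr in pairs) {
            a <- pr[1]; b <- pr[2]
            ex <- exchange_pair(islands[[a]], islands[[b]], config$migrant_count,
                                time = max(islands[[a]]$time, islands[[b]]$time))
            islands[[a]] <- ex$a
            islands[[b]] <- ex$b
            events[[length(events) + 1]] <- ex$events
            edges[[length(edges) + 1]] <- c(a, b)
            for (isl_id in c(a, b)) {
              units_mat[isl_id, "send_and_receive"] <-
                units_mat[isl_id, "send_and_receive"] + config$migrant_count
              islands[[isl_id]]$time <- islands[[isl_id]]$time +
                config$migrant_count * config$cost_send_receive * speed[isl_id]
            }
            if (config$optimizer == "pso") {
              islands[[a]]$swarm <- swarm_absorb(islands[[a]]$swarm, islands[[a]]$pop)
              islands[[b]]$swarm <- swarm_absorb(islands[[b]]$swarm, islands[[b]]$pop)
            }
            ready <- setdiff(ready, c(a, b))
          }
        }
      }
    }

    finish_docking_result(best_genes, best_energy, history[seq_len(step)], events,
                          units_mat, config$n_pop, islands, config, bounds,
                          receptor, topology, ff, ctx)
  })
}

finish_docking_result <- function(best_genes, best_energy, history, events,
                                  units_mat, n_init, islands, config, bounds,
                                  receptor, topology, ff, ctx) {
  hist <- tibble::as_tibble(do.call(rbind, history))
  ev <- if (length(events) > 0) dplyr::bind_rows(events) else empty_events()
  op_units <- dplyr::bind_rows(
    tibble::tibble(island = NA_integer_, category = "initialization",
                   units = as.numeric(n_init)),
    do.call(dplyr::bind_rows, lapply(seq_along(islands), function(i) {
      tibble::tibble(island = i, category = colnames(units_mat),
                     units = units_mat[i, ])
    }))
  )
  pr_log <- dplyr::bind_rows(unlist(lapply(islands, `[[`, "pr_log"),
                                    recursive = FALSE))
  breakdown <- new_energy_breakdown(cpp_energy_breakdown(ctx, best_genes))
  structure(list(
    best_pose = genes_to_pose(best_genes),
    best_genes = best_genes,
    best_energy = breakdown,
    history = hist,
    events = ev,
    op_units = op_units,
    pr_log = pr_log,
    final_populations = lapply(islands, `[[`, "pop"),
    config = config,
    bounds = bounds,
    simulated_time = max(vapply(islands, `[[`, numeric(1), "time"))
  ), class = "docking_result")
}

#' Serial Lamarckian genetic algorithm
#'
#' The single-population reference: the same initialization, genetic
#' generation, pattern reduction and Lamarckian local search as [dock()], with
#' no scheduler and no migration machinery. With `n_islands = 1`, [dock()]
#' follows the identical random-number streams, so the two trajectories agree
#' generation by generation.
#'
#' @inheritParams dock
#' @return A `docking_result` (with an empty event log).
#' @export
dock_serial_lga <- function(receptor, topology, config = config_preset("toy", n_islands = 1L),
                            bounds = NULL, ff = force_field_params()) {
  config <- validate_run_config(config)
  if (is.null(bounds)) bounds <- default_bounds(receptor)
  nt <- length(topology$branches)
  spec <- gene_spec(nt, bounds)
  ctx <- make_energy_context(receptor, topology, ff)
  energy_fn <- function(G) cpp_energy_batch(ctx, G)
  opt <- as_optimizer_params(config)

  with_preserved_rng({
    init_stream <- stream_new(derive_seed(config$seed, 0))
    G0 <- stream_eval(init_stream, function() init_genes(config$n_pop, spec, nt, bounds))$value
    E0 <- as.numeric(energy_fn(G0))
    isl <- new_island(1L, new_population(G0, E0), config, config$seed)
    isl$prs$tolerance <- island_pr_tolerance(config, spec)

    best_i <- which.min(E0)
    best_genes <- G0[best_i, ]
    best_energy <- E0[best_i]
    units_mat <- matrix(0, 1, 6,
                        dimnames = list(NULL, c("selection", "crossover", "mutation",
                                                "evaluation", "local_search",
                                                "send_and_receive")))
    history <- vector("list", config$generations)
    for (gen in seq_len(config$generations)) {
      sr <- stream_eval(isl$stream, function() {
        evolve_island_once(isl, config, opt, spec, energy_fn, ctx)
      })
      isl <- sr$value$isl
      isl$stream <- sr$stream
      u <- sr$value$units
      for (nm in names(u)) units_mat[1, nm] <- units_mat[1, nm] + u[[nm]]
      ib <- min(isl$pop$energy)
      if (ib < best_energy) {
        best_energy <- ib
        best_genes <- isl$pop$genes[best_index(isl$pop$energy), ]
      }
      history[[gen]] <- c(step = gen, island = 1, generation = gen,
                          island_best = ib, best_so_far = best_energy, time = 0)
    }
    finish_docking_result(best_genes, best_energy, history, list(), units_mat,
                          config$n_pop, list(isl), config, bounds,
                          receptor, topology, ff, ctx)
  })
}

#' @export
print.docking_result <- function(x, ...) {
  cat(sprintf("<docking_result> %s, %d island(s), %d generations/island\n",
              x$config$optimizer, x$config$n_islands, x$config$generations))
  cat(sprintf("  best energy %.4f kcal/mol, %d migration event(s), simulated time %.1f\n",
              x$best_energy$e_total, nrow(x$events), x$simulated_time))
  invisible(x)
}
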