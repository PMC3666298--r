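#' Generate a toy docking system with a planted optimum
#'
#' Builds a small flexible ligand (a zigzag chain with 0-3 rotatable bonds) and
#' a pocket of receptor atoms placed on a spherical cap complementary to the
#' ligand at a randomly drawn reference pose: each pocket atom sits at the
#' pairwise equilibrium distance (hydrogen-bond distance for donor-acceptor
#' pairs) from a ligand atom, with an opposite partial charge, so the planted
#' pose is a deep minimum of the energy function. Generation is deterministic
#' in `seed` and verifies, by rejection sampling, that the reference-pose
#' energy is below the minimum of 1000 random-pose energies.
#'
#' These systems emulate the geometry and energetics of a binding pocket at
#' desk scale; they do not reproduce real protein chemistry (no full bond
#' graph, no protonation states, no structural water).
#'
#' @param seed Integer seed; the same seed reproduces the system exactly.
#' @param n_pocket Number of receptor pocket atoms.
#' @param n_atoms Ligand atoms (2-8).
#' @param n_torsions Rotatable bonds (0-3, at most `n_atoms - 2`).
#' @param box_margin Margin of the docking box around the system, Angstrom.
#' @param max_tries Rejection-sampling retries before giving up.
#' @param ff A [force_field_params()].
#' @return A `toy_system`: `receptor`, `topology`, `reference_pose`,
#'   `reference_coords`, `reference_energy`, `bounds`, `seed`.
#' @export
#' @examples
#' sys <- make_toy_system(seed = 7)
#' sys$reference_energy
make_toy_system <- function(seed, n_pocket = 12L, n_atoms = 4L, n_torsions = 1L,
                            box_margin = 2.5, max_tries = 40L,
                            ff = force_field_params()) {
  if (n_atoms < 2 || n_atoms > 8) stop("n_atoms must be in 2..8", call. = FALSE)
  if (n_torsions < 0 || n_torsions > 3 || (n_torsions > 0 && n_torsions > n_atoms - 3)) {
    stop("n_torsions must be in 0..3 and at most n_atoms - 3", call. = FALSE)
  }
  for (attempt in seq_len(max_tries)) {
    sys <- with_seed(derive_seed(seed, 31L * attempt), {
      build_toy_system(seed, n_pocket, n_atoms, n_torsions, box_margin, ff)
    })
    if (!is.null(sys)) return(sys)
  }
  stop("could not generate a toy system whose planted pose beats 1000 random poses; ",
       "try a different seed or a larger pocket", call. = FALSE)
}

build_toy_system <- function(seed, n_pocket, n_atoms, n_torsions, box_margin, ff) {
  params <- ff$atom_params

  # zigzag ligand chain, 1.5 A bonds
  lig_xyz <- matrix(0, n_atoms, 3)
  for (i in seq_len(n_atoms - 1)) {
    th <- 0.55 * (-1)^i
    lig_xyz[i + 1, ] <- lig_xyz[i, ] + 1.5 * c(cos(th), sin(th), 0.15 * (-1)^i)
  }
  # strongly but aperiodically charged centres: the complementary pocket
  # charges carry a smooth long-range electrostatic funnel into the planted
  # pose, and the irregular sign/type pattern avoids degenerate register-shifted
  # or flipped matches
  lig_types <- sample(c("C", "OA", "N"), n_atoms, replace = TRUE)
  signs <- sample(c(1, -1), n_atoms, replace = TRUE)
  if (length(unique(signs)) == 1) signs[sample.int(n_atoms, 1)] <- -signs[1]
  lig_charges <- stats::runif(n_atoms, 0.3, 0.6) * signs

  atoms <- tibble::tibble(
    serial = seq_len(n_atoms),
    name = paste0(lig_types, seq_len(n_atoms)),
    type = lig_types,
    x = lig_xyz[, 1], y = lig_xyz[, 2], z = lig_xyz[, 3],
    charge = lig_charges
  )
  atoms <- join_atom_params(atoms, params)

  # rotatable bonds at the tail of the chain; each bond's moved set keeps at
  # least one atom beyond the axis so every torsion actually moves atoms
  root <- seq_len(n_atoms - n_torsions - if (n_torsions > 0) 1L else 0L)
  branches <- lapply(seq_len(n_torsions), function(j) {
    child <- n_atoms - n_torsions - 1L + j
    list(parent = child - 1L, child = child, moved = child:n_atoms)
  })
  topology <- new_ligand_topology(atoms, root, branches, n_torsions)

  reference_pose <- pose(stats::runif(3, -1, 1), quat_random(),
                         if (n_torsions > 0) stats::runif(n_torsions, -pi, pi) else numeric(0))
  ref_coords <- apply_pose(topology, reference_pose)

  # pocket atoms on a bowl (spherical cap) around the posed ligand, each at the
  # pairwise equilibrium distance from its target atom: concave enough that the
  # planted pose collects many favourable contacts, open enough that a downhill
  # approach path into the pocket exists
  cap_axis <- stats::rnorm(3)
  cap_axis <- cap_axis / sqrt(sum(cap_axis^2))
  pocket <- matrix(NA_real_, n_pocket, 3)
  pocket_type <- character(n_pocket)
  pocket_charge <- numeric(n_pocket)
  type_row <- function(ty) params[match(ty, params$type), ]
  placed <- 0L
  guard <- 0L
  while (placed < n_pocket && guard < 2000L) {
    guard <- guard + 1L
    target <- (placed %% n_atoms) + 1L
    t_row <- topology$atoms[target, ]
    # acceptors get hydrogen-bond donors: deep, narrow 12-10 wells anchor the
    # planted pose specifically
    ty <- if (t_row$hbond == "acceptor") "HD" else sample(c("C", "N", "OA"), 1)
    p_row <- type_row(ty)
    r_place <- if (ty == "HD" && t_row$hbond == "acceptor") t_row$hb_rij
               else (p_row$rii / 2 + t_row$vdw_radius)
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    if (sum(dir * cap_axis) < -0.1) next
    cand <- as.numeric(ref_coords[target, ]) + dir * r_place
    d_lig <- sqrt(rowSums(sweep(ref_coords, 2, cand)^2))
    # allow contacts down to 0.85 of the pairwise equilibrium distance: still
    # on the attractive side of the 12-6 well, so the planted pose stays deep
    min_lig <- 0.85 * (p_row$rii / 2 + topology$atoms$vdw_radius)
    ok <- all(d_lig >= pmin(min_lig, r_place) - 1e-9)
    if (ok && placed > 0) {
      d_poc <- sqrt(rowSums(sweep(pocket[seq_len(placed), , drop = FALSE], 2, cand)^2))
      ok <- all(d_poc >= 2.4)
    }
    if (ok) {
      placed <- placed + 1L
      pocket[placed, ] <- cand
      pocket_type[placed] <- ty
      pocket_charge[placed] <- -t_row$charge * stats::runif(1, 0.8, 1.2)
    }
  }
  if (placed < n_pocket) return(NULL)

  rec_atoms <- tibble::tibble(
    serial = seq_len(n_pocket),
    name = paste0(pocket_type, seq_len(n_pocket)),
    type = pocket_type,
    x = pocket[, 1], y = pocket[, 2], z = pocket[, 3],
    charge = pocket_charge
  )
  receptor <- new_receptor(join_atom_params(rec_atoms, params))

  all_xyz <- rbind(pocket, ref_coords)
  bounds <- search_bounds(apply(all_xyz, 2, min) - box_margin,
                          apply(all_xyz, 2, max) + box_margin)

  # refine the planted pose into its exact local minimum so the reference is a
  # true stationary point of the energy
  ctx <- make_energy_context(receptor, topology, ff)
  spec <- gene_spec(n_torsions, bounds)
  energy_fn <- function(G) cpp_energy_batch(ctx, G)
  sw_par <- optimizer_params(sw_max_iter = 500L, sw_lb = 1e-4)
  frozen <- rep(FALSE, spec$n_genes)
  refine <- function(genes, e0) {
    cpp_solis_wets(ctx, genes, e0, spec$scales, spec$lower, spec$upper, frozen,
                   sw_par$sw_rho0, sw_par$sw_lb, sw_par$sw_succ, sw_par$sw_fail,
                   sw_par$sw_max_iter)
  }
  g_ref <- pose_to_genes(reference_pose)
  refined <- refine(g_ref, as.numeric(energy_fn(matrix(g_ref, 1))))
  if (rmsd(cpp_pose_coords(ctx, refined$genes), ref_coords) > 1.0) return(NULL)
  reference_pose <- genes_to_pose(refined$genes)
  ref_coords <- cpp_pose_coords(ctx, refined$genes)
  e_ref <- refined$energy

  # certification: the reference must be genuinely deep, beat the minimum of
  # 1000 random poses, and dominate the landscape: locally refining the best
  # of the random poses must not uncover a competing basin (a decoy) away from
  # the planted pose
  if (e_ref > -8) return(NULL)
  G <- init_genes(8000L, spec, n_torsions, bounds)
  e_rand <- cpp_energy_batch(ctx, G)
  if (!(e_ref < min(e_rand[seq_len(1000)]))) return(NULL)
  for (i in order(e_rand)[1:200]) {
    dec <- refine(G[i, ], e_rand[i])
    if (dec$energy < e_ref + 3 &&
        rmsd(cpp_pose_coords(ctx, dec$genes), ref_coords) > 2.0) {
      return(NULL)
    }
  }

  structure(list(receptor = receptor, topology = topology,
                 reference_pose = reference_pose,
                 reference_coords = ref_coords,
                 reference_energy = e_ref,
                 bounds = bounds, seed = seed),
            class = "toy_system")
}

#' The standard benchmark system
#'
#' The fixed toy system (generator seed 1, default dimensions: 12 pocket atoms,
#' 4 ligand atoms, 1 rotatable bond) used by the pose-recovery benchmark and
#' the comparison grids. Memoised per session.
#'
#' @return A `toy_system`.
#' @export
standard_toy_system <- function() {
  if (is.null(.toy_cache$standard)) {
    .toy_cache$standard <- make_toy_system(seed = 1L)
  }
  .toy_cache$standard
}

.toy_cache <- new.env(parent = emptyenv())

#' Docking success rate
#'
#' Fraction of independent runs whose final best pose lies within an RMSD
#' cutoff of the planted reference pose (community convention: 2.0 Angstrom).
#'
#' @param final_poses A list of `pose` objects or of `docking_result`s.
#' @param system A `toy_system`.
#' @param cutoff RMSD cutoff, Angstrom (> 0).
#' @return Fraction in `[0, 1]`, with the per-run RMSDs attached as attribute
#'   `"rmsd"`.
#' @export
success_rate <- function(final_poses, system, cutoff = 2.0) {
  if (length(final_poses) == 0) stop("empty pose list", call. = FALSE)
  if (cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  rmsds <- vapply(final_poses, function(p) {
    if (inherits(p, "docking_result")) p <- p$best_pose
    rmsd(apply_pose(system$topology, p), system$reference_coords)
  }, numeric(1))
  out <- mean(rmsds <= cutoff)
  attr(out, "rmsd") <- rmsds
  out
}

#' Timing profile of a run
#'
#' Attributes every logged operation unit to one of the seven cost categories
#' (initialization, selection, crossover, mutation, evaluation, local search,
#' send and receive), prices them with a cost model, and normalizes to
#' fractions of the accounted run cost. The cost model defaults to the one the
#' run was scheduled with; passing a different model reprices the same
#' operation counts.
#'
#' @param result A `docking_result` (or its `op_units` tibble).
#' @param cost_model Named numeric vector of per-unit costs for the seven
#'   categories; defaults to the run configuration's `cost_*` values.
#' @return A `timing_profile`: list with `fractions` (named, summing to 1) and
#'   `total_cost`.
#' @export
timing_profile <- function(result, cost_model = NULL) {
  categories <- c("initialization", "selection", "crossover", "mutation",
                  "evaluation", "local_search", "send_and_receive")
  if (inherits(result, "docking_result")) {
    op <- result$op_units
    if (is.null(cost_model)) {
      cfg <- result$config
      cost_model <- c(initialization = cfg$cost_initialization,
                      selection = cfg$cost_selection,
                      crossover = cfg$cost_crossover,
                      mutation = cfg$cost_mutation,
                      evaluation = cfg$cost_evaluation,
                      local_search = cfg$cost_local_search,
                      send_and_receive = cfg$cost_send_receive)
    }
  } else {
    op <- result
    if (is.null(cost_model)) stop("a cost model is required when passing raw operation counts",
                                  call. = FALSE)
  }
  unknown <- setdiff(unique(op$category), categories)
  if (length(unknown) > 0) {
    stop("unknown cost categories in the operation log: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  totals <- vapply(categories, function(cat) {
    sum(op$units[op$category == cat]) * cost_model[[cat]]
  }, numeric(1))
  total <- sum(totals)
  structure(list(fractions = if (total > 0) totals / total else totals,
                 total_cost = total),
            class = "timing_profile")
}

#' @export
print.timing_profile <- function(x, ...) {
  cat("<timing_profile> total cost", format(x$total_cost, digits = 6), "\n")
  for (nm in names(x$fractions)) {
    cat(sprintf("  %-17s %6.2f%%\n", nm, 100 * x$fractions[[nm]]))
  }
  invisible(x)
}

#' @export
print.toy_system <- function(x, ...) {
  cat(sprintf("<toy_system> seed %d: %d pocket atoms, %d ligand atoms, %d torsion(s), planted energy %.3f kcal/mol\n",
              x$seed, nrow(x$receptor$atoms), nrow(x$topology$atoms),
              length(x$topology$branches), x$reference_energy))
  invisible(x)
}

#' Island-count comparison grid
#'
#' Runs repeated seeded docking runs for every optimizer / island-count cell on
#' one toy system and tabulates the success rate, the mean simulated completion
#' time and the cost-category fractions.
#'
#' @param system A `toy_system`.
#' @param optimizers Character subset of `c("lga", "de", "pso")`.
#' @param islands Integer vector of island counts.
#' @param n_seeds Independent runs per cell.
#' @param base_config A [run_config()] supplying everything but optimizer,
#'   island count and seed.
#' @param cutoff Success RMSD cutoff, Angstrom.
#' @return A tibble with one row per cell.
#' @export
benchmark_grid <- function(system, optimizers = "lga", islands = c(1L, 2L, 4L),
                           n_seeds = 5L, base_config = config_preset("toy"),
                           cutoff = 2.0) {
  rows <- list()
  for (optim in optimizers) {
    for (m in islands) {
      runs <- lapply(seq_len(n_seeds), function(s) {
        cfg <- base_config
        cfg$optimizer <- optim
        cfg$n_islands <- as.integer(m)
        cfg$seed <- derive_seed(base_config$seed, 1000L * s + m)
        cfg <- validate_run_config(cfg)
        dock(system$receptor, system$topology, cfg, bounds = system$bounds)
      })
      sr <- success_rate(runs, system, cutoff)
      fr <- rowMeans(vapply(runs, function(r) timing_profile(r)$fractions,
                            numeric(7)))
      rows[[length(rows) + 1]] <- tibble::tibble(
        optimizer = optim, islands = as.integer(m),
        chromosomes = base_config$n_pop %/% as.integer(m),
        success_rate = as.numeric(sr),
        average_time = mean(vapply(runs, `[[`, numeric(1), "simulated_time")),
        initialization = fr[["initialization"]], selection = fr[["selection"]],
        crossover = fr[["crossover"]], mutation = fr[["mutation"]],
        evaluation = fr[["evaluation"]], local_search = fr[["local_search"]],
        send_and_receive = fr[["send_and_receive"]]
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Write a benchmark grid as a delimited report
#'
#' One column per island count, category rows labelled with the standard
#' vocabulary (Initialization, Selection, Crossover, Mutation, Evaluation,
#' Local search, Send and receive, Success rate, Average time), one block per
#' optimizer.
#'
#' @param grid Output of [benchmark_grid()].
#' @param path Output file.
#' @export
write_benchmark_report <- function(grid, path) {
  labels <- c(initialization = "Initialization", selection = "Selection",
              crossover = "Crossover", mutation = "Mutation",
              evaluation = "Evaluation", local_search = "Local search",
              send_and_receive = "Send and receive")
  con <- file(path, "w")
  on.exit(close(con))
  for (optim in unique(grid$optimizer)) {
    sub <- grid[grid$optimizer == optim, ]
    writeLines(optim, con)
    writeLines(paste(c("Islands", sub$islands), collapse = "\t"), con)
    writeLines(paste(c("Chromosomes", sub$chromosomes), collapse = "\t"), con)
    for (nm in names(labels)) {
      writeLines(paste(c(labels[[nm]], sprintf("%.2f%%", 100 * sub[[nm]])),
                       collapse = "\t"), con)
    }
    writeLines(paste(c("Success rate", sprintf("%.2f%%", 100 * sub$success_rate)),
                     collapse = "\t"), con)
    writeLines(paste(c("Average time", sprintf("%.2f", sub$average_time)),
                     collapse = "\t"), con)
    writeLines("", con)
  }
  invisible(path)
}
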