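# Shared fixtures: tiny PDBQT texts built in code, a small cached toy system,
# and an R-level brute-force energy oracle coded independently of the
# cutoff/pair-table evaluation path.

pdbqt_atom_line <- function(serial, name, x, y, z, charge, type,
                            record = "ATOM", resname = "LIG") {
  sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f%10.3f %-2s",
          record, serial, name, resname, "A", 1L, x, y, z, 1.00, 0.00, charge, type)
}

receptor_fixture_text <- function() {
  paste(c(
    pdbqt_atom_line(1, "C1", 0, 0, 0, 0.10, "C", record = "ATOM", resname = "REC"),
    pdbqt_atom_line(2, "O1", 3.5, 0, 0, -0.30, "OA", record = "ATOM", resname = "REC"),
    pdbqt_atom_line(3, "N1", 0, 3.5, 0, -0.20, "N", record = "HETATM", resname = "REC")
  ), collapse = "\n")
}

# 4-atom ligand, one rotatable bond (2-3) moving atoms 3 and 4
ligand_fixture_text <- function() {
  paste(c(
    "REMARK test ligand",
    "ROOT",
    pdbqt_atom_line(1, "C1", 0.000, 0.000, 0.000, 0.20, "C"),
    pdbqt_atom_line(2, "O1", 1.400, 0.000, 0.000, -0.35, "OA"),
    "ENDROOT",
    "BRANCH   2   3",
    pdbqt_atom_line(3, "C2", 2.100, 1.200, 0.000, 0.15, "C"),
    pdbqt_atom_line(4, "N1", 3.500, 1.200, 0.500, -0.25, "N"),
    "ENDBRANCH   2   3",
    "TORSDOF 1"
  ), collapse = "\n")
}

ligand_fixture <- function() parse_ligand_pdbqt(ligand_fixture_text())
receptor_fixture <- function() parse_receptor_pdbqt(receptor_fixture_text())

# small cached toy system so the expensive generator runs once per test session
cached_toy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_toy_system(seed = 1L)
    cache
  }
})

# random receptor/ligand configuration of n_rec + n_lig atoms for oracle checks
random_system <- function(n_rec = 14, n_lig = 6, n_torsions = 1, spread = 6) {
  params <- default_atom_params()
  types <- c("C", "OA", "N", "HD", "A", "S")
  mk_atoms <- function(n, offset = 0) {
    tb <- tibble::tibble(
      serial = seq_len(n),
      name = paste0("X", seq_len(n)),
      type = sample(types, n, replace = TRUE),
      x = runif(n, -spread, spread) + offset,
      y = runif(n, -spread, spread),
      z = runif(n, -spread, spread),
      charge = runif(n, -0.5, 0.5)
    )
    isledock:::join_atom_params(tb, params)
  }
  rec <- isledock:::new_receptor(mk_atoms(n_rec))
  lat <- mk_atoms(n_lig)
  # chain-like geometry so the torsion tree is meaningful
  lat$x <- seq(0, by = 1.5, length.out = n_lig)
  lat$y <- rep(c(0, 0.8), length.out = n_lig)
  lat$z <- 0
  root <- seq_len(n_lig - n_torsions - 1)
  branches <- lapply(seq_len(n_torsions), function(j) {
    child <- n_lig - n_torsions - 1L + j
    list(parent = child - 1L, child = child, moved = child:n_lig)
  })
  topo <- new_ligand_topology(lat, root, branches, n_torsions)
  list(receptor = rec, topology = topo)
}

# brute-force O(n^2) total energy: double loop over every pair using the scalar
# term functions, with no cutoff and no precomputed tables
oracle_total_energy <- function(receptor, topology, pose, ff = force_field_params()) {
  L <- apply_pose(topology, pose)
  R <- as.matrix(receptor$atoms[, c("x", "y", "z")])
  ra <- receptor$atoms; la <- topology$atoms
  pair_energy <- function(a, b, r) {
    hb <- hbond_pair(a, b)
    e <- if (isTRUE(hb$hbond)) {
      hbond_energy(r, hb, cutoff = Inf)
    } else {
      vdw_energy(r, vdw_pair(a, b), cutoff = Inf)
    }
    e + electrostatic_energy(r, a$charge, b$charge, ff$dielectric, ff$coulomb) +
      desolvation_energy(r, a, b, ff$desolvation_weight, ff$desolvation_sigma,
                         cutoff = Inf)
  }
  total <- 0
  for (i in seq_len(nrow(ra))) {
    for (j in seq_len(nrow(la))) {
      r <- sqrt(sum((R[i, ] - L[j, ])^2))
      total <- total + pair_energy(ra[i, ], la[j, ], r)
    }
  }
  ip <- isledock:::intra_pair_indices(topology)
  for (k in seq_along(ip$i)) {
    i <- ip$i[k]; j <- ip$j[k]
    r <- sqrt(sum((L[i, ] - L[j, ])^2))
    total <- total + pair_energy(la[i, ], la[j, ], r)
  }
  total
}

# force field with no cutoff, for oracle comparisons
ff_nocut <- function() force_field_params(cutoff = Inf)
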