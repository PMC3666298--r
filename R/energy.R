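#' Force-field parameters for the empirical energy function
#'
#' The total interaction energy is the sum of five pairwise terms:
#' `E_total = E_v + E_h + E_e + E_i + E_d`, where `E_v` is a 12-6 van der Waals
#' term, `E_h` a 12-10 hydrogen-bond term (used instead of the 12-6 term for
#' donor-acceptor pairs), `E_e` a Coulomb term with a sigmoidal
#' distance-dependent dielectric, `E_d` a volume-weighted Gaussian desolvation
#' term, and `E_i` the ligand intramolecular energy (the same pairwise forms
#' summed over ligand atom pairs in different rigid groups). All terms are
#' evaluated on explicit atom pairs with a hard nonbonded cutoff; there is no
#' grid precomputation. The functional forms are AD4-like; bit-compatibility
#' with any particular docking engine is not a goal. No torsional-entropy
#' constant is added: it shifts every pose equally and cannot change the argmin.
#'
#' @param atom_params Atom parameter table, see [default_atom_params()].
#' @param coulomb Coulomb conversion constant, kcal Angstrom / (mol e^2).
#' @param desolvation_weight Weight of the desolvation term.
#' @param desolvation_sigma Gaussian width of the desolvation term, Angstrom.
#' @param cutoff Nonbonded cutoff, Angstrom (`Inf` disables it).
#' @param dielectric Parameters of the sigmoidal dielectric
#'   `eps(r) = A + B / (1 + k * exp(-lambda * B * r))` with `B = eps0 - A`.
#' @return A `force_field_params` list.
#' @export
force_field_params <- function(atom_params = default_atom_params(),
                               coulomb = 332.06,
                               desolvation_weight = 0.1465,
                               desolvation_sigma = 3.5,
                               cutoff = 8,
                               dielectric = list(eps0 = 78.4, A = -8.5525,
                                                 lambda = 0.003627, k = 7.7839)) {
  if (cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  structure(list(atom_params = atom_params, coulomb = coulomb,
                 desolvation_weight = desolvation_weight,
                 desolvation_sigma = desolvation_sigma,
                 cutoff = cutoff, dielectric = dielectric),
            class = "force_field_params")
}

check_r_positive <- function(r) {
  if (any(r <= 0)) stop("interatomic distance must be > 0", call. = FALSE)
}

#' Pairwise energy terms
#'
#' Scalar (vectorized over `r`) forms of the four pairwise terms. `pair` is a
#' list with `r_eq` and `epsilon` (and `hbond` for [hbond_energy()]), typically
#' from [vdw_pair()] / [hbond_pair()].
#'
#' @param r Interatomic distance(s), Angstrom; must be > 0.
#' @param pair Pair parameters.
#' @param cutoff Nonbonded cutoff, Angstrom.
#' @return Energy in kcal/mol.
#' @name energy_terms
NULL

#' @rdname energy_terms
#' @export
vdw_energy <- function(r, pair, cutoff = 8) {
  check_r_positive(r)
  A <- pair$epsilon * pair$r_eq^12
  B <- 2 * pair$epsilon * pair$r_eq^6
  out <- A / r^12 - B / r^6
  out[r > cutoff] <- 0
  out
}

#' @rdname energy_terms
#' @export
hbond_energy <- function(r, pair, cutoff = 8) {
  check_r_positive(r)
  if (!isTRUE(pair$hbond)) return(rep(0, length(r)))
  C <- 5 * pair$epsilon * pair$r_eq^12
  D <- 6 * pair$epsilon * pair$r_eq^10
  out <- C / r^12 - D / r^10
  out[r > cutoff] <- 0
  out
}

#' Sigmoidal distance-dependent dielectric
#'
#' @param r Distance(s), Angstrom.
#' @param params Dielectric parameters (see [force_field_params()]).
#' @return Dimensionless relative permittivity.
#' @export
sigmoidal_dielectric <- function(r, params = force_field_params()$dielectric) {
  B <- params$eps0 - params$A
  params$A + B / (1 + params$k * exp(-params$lambda * B * r))
}

#' @rdname energy_terms
#' @param q1,q2 Partial charges, elementary charge units.
#' @param diel Dielectric parameters.
#' @param coulomb Coulomb constant.
#' @export
electrostatic_energy <- function(r, q1, q2,
                                 diel = force_field_params()$dielectric,
                                 coulomb = 332.06) {
  check_r_positive(r)
  coulomb * q1 * q2 / (sigmoidal_dielectric(r, diel) * r)
}

#' @rdname energy_terms
#' @param atom_a,atom_b Atom rows (lists with `solvation_parameter` and
#'   `solvation_volume`).
#' @param weight Desolvation weight.
#' @param sigma Gaussian width, Angstrom.
#' @export
desolvation_energy <- function(r, atom_a, atom_b, weight = 0.1465,
                               sigma = 3.5, cutoff = 8) {
  check_r_positive(r)
  sv <- atom_a$solvation_parameter * atom_b$solvation_volume +
    atom_b$solvation_parameter * atom_a$solvation_volume
  out <- weight * sv * exp(-r^2 / (2 * sigma^2))
  out[r > cutoff] <- 0
  out
}

#' Combined pair parameters
#'
#' `vdw_pair()` combines per-type parameters with the arithmetic mean of the
#' like-pair equilibrium distances and the geometric mean of the well depths.
#' `hbond_pair()` returns the 12-10 parameters when one atom is a donor
#' hydrogen and the other an acceptor (taken from the acceptor's columns);
#' otherwise `hbond = FALSE`.
#'
#' @param a,b Atom rows (lists with `vdw_radius`, `well_depth`, `hbond`,
#'   `hb_rij`, `hb_eps`).
#' @return A list with `r_eq`, `epsilon` (and `hbond` flag for `hbond_pair`).
#' @export
vdw_pair <- function(a, b) {
  list(r_eq = a$vdw_radius + b$vdw_radius,
       epsilon = sqrt(a$well_depth * b$well_depth))
}

#' @rdname vdw_pair
#' @export
hbond_pair <- function(a, b) {
  if (a$hbond == "donor" && b$hbond == "acceptor") {
    list(r_eq = b$hb_rij, epsilon = b$hb_eps, hbond = TRUE)
  } else if (b$hbond == "donor" && a$hbond == "acceptor") {
    list(r_eq = a$hb_rij, epsilon = a$hb_eps, hbond = TRUE)
  } else {
    list(r_eq = NA_real_, epsilon = NA_real_, hbond = FALSE)
  }
}

# ---- precomputed pairwise tables -------------------------------------------

# For a set of pairs (ai rows, bi rows of atom tibbles) return per-pair
# coefficient vectors. Hydrogen-bonding pairs use the 12-10 term instead of
# the 12-6 term, so exactly one of (A, B) and (C, D) is nonzero per pair.
pair_coefficients <- function(atoms_a, ai, atoms_b, bi, ff) {
  ra <- atoms_a$vdw_radius[ai]; rb <- atoms_b$vdw_radius[bi]
  ea <- atoms_a$well_depth[ai]; eb <- atoms_b$well_depth[bi]
  r_eq <- ra + rb
  eps <- sqrt(ea * eb)
  A <- eps * r_eq^12
  B <- 2 * eps * r_eq^6

  hb_ab <- atoms_a$hbond[ai] == "donor" & atoms_b$hbond[bi] == "acceptor"
  hb_ba <- atoms_b$hbond[bi] == "donor" & atoms_a$hbond[ai] == "acceptor"
  hb <- hb_ab | hb_ba
  r_hb <- ifelse(hb_ab, atoms_b$hb_rij[bi], atoms_a$hb_rij[ai])
  e_hb <- ifelse(hb_ab, atoms_b$hb_eps[bi], atoms_a$hb_eps[ai])
  C <- ifelse(hb, 5 * e_hb * r_hb^12, 0)
  D <- ifelse(hb, 6 * e_hb * r_hb^10, 0)
  A[hb] <- 0; B[hb] <- 0

  qq <- ff$coulomb * atoms_a$charge[ai] * atoms_b$charge[bi]
  dsol <- ff$desolvation_weight *
    (atoms_a$solvation_parameter[ai] * atoms_b$solvation_volume[bi] +
       atoms_b$solvation_parameter[bi] * atoms_a$solvation_volume[ai])
  list(A = A, B = B, C = C, D = D, qq = qq, dsol = dsol)
}

# ligand intramolecular pair list: atoms in different rigid groups whose
# bond-path separation is at least 3 (1-4 interactions and beyond). PDBQT
# carries no bond records, so covalent bonds are inferred from the input
# geometry (heavy-atom distance <= 1.9 A, a standard perception threshold);
# the rotatable bonds declared by the torsion tree are always included.
# Same-group pairs are rigid, hence constant, and are skipped.
intra_pair_indices <- function(topology, bond_cutoff = 1.9) {
  n <- nrow(topology$atoms)
  if (n < 2 || length(topology$branches) == 0) {
    return(list(i = integer(0), j = integer(0)))
  }
  xyz <- as.matrix(topology$atoms[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  adj <- d > 0 & d <= bond_cutoff
  for (b in topology$branches) {
    adj[b$parent, b$child] <- TRUE
    adj[b$child, b$parent] <- TRUE
  }
  sep <- bond_separation(adj)
  g <- rigid_groups(topology)
  cmb <- utils::combn(n, 2)
  keep <- g[cmb[1, ]] != g[cmb[2, ]] &
    sep[cbind(cmb[1, ], cmb[2, ])] >= 3
  list(i = cmb[1, keep], j = cmb[2, keep])
}

# all-pairs shortest bond-path lengths (BFS per atom; unreachable = Inf)
bond_separation <- function(adj) {
  n <- nrow(adj)
  sep <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(adj[v, ] & dist > dist[v] + 1)
        dist[nb] <- dist[v] + 1
        nxt <- c(nxt, nb)
      }
      frontier <- unique(nxt)
    }
    sep[s, ] <- dist
  }
  sep
}

#' Precompute an energy-evaluation context
#'
#' Builds the per-pair coefficient tables (intermolecular receptor-ligand pairs
#' and ligand intramolecular pairs) and the torsion-tree arrays consumed by the
#' compiled evaluation kernel. Build it once per receptor/ligand/parameter
#' combination and reuse it for every pose.
#'
#' @param receptor A `receptor`.
#' @param topology A `ligand_topology`.
#' @param params A [force_field_params()].
#' @return An `energy_context` list.
#' @export
make_energy_context <- function(receptor, topology, params = force_field_params()) {
  ra <- receptor$atoms; la <- topology$atoms
  k <- nrow(ra); n <- nrow(la)
  ri <- rep(seq_len(k), times = n)
  li <- rep(seq_len(n), each = k)
  inter <- pair_coefficients(ra, ri, la, li, params)
  ip <- intra_pair_indices(topology)
  intra <- pair_coefficients(la, ip$i, la, ip$j, params)
  diel <- params$dielectric
  structure(list(
    rec_coords = unname(as.matrix(ra[, c("x", "y", "z")])),
    lig_coords = unname(as.matrix(la[, c("x", "y", "z")])),
    branch_parent = vapply(topology$branches, `[[`, numeric(1), "parent"),
    branch_child = vapply(topology$branches, `[[`, numeric(1), "child"),
    branch_moved = lapply(topology$branches, `[[`, "moved"),
    inter_ri = ri, inter_li = li,
    inter_A = inter$A, inter_B = inter$B, inter_C = inter$C, inter_D = inter$D,
    inter_qq = inter$qq, inter_dsol = inter$dsol,
    intra_i = ip$i, intra_j = ip$j,
    intra_A = intra$A, intra_B = intra$B, intra_C = intra$C, intra_D = intra$D,
    intra_qq = intra$qq, intra_dsol = intra$dsol,
    cutoff = params$cutoff,
    sigma = params$desolvation_sigma,
    diel_A = diel$A, diel_B = diel$eps0 - diel$A,
    diel_lambda = diel$lambda, diel_k = diel$k,
    n_torsions = length(topology$branches)
  ), class = "energy_context")
}

# fast path used by the optimizers: vector of totals for a gene matrix
context_energy <- function(ctx, genes_matrix) {
  cpp_energy_batch(ctx, genes_matrix)
}

new_energy_breakdown <- function(v) {
  structure(list(e_v = v[1], e_h = v[2], e_e = v[3], e_i = v[4], e_d = v[5],
                 e_total = v[6]),
            class = "energy_breakdown")
}

#' Total interaction energy of a pose
#'
#' Sums the intermolecular terms (`E_v`, `E_h`, `E_e`, `E_d`) over all
#' receptor-ligand atom pairs within the cutoff and the intramolecular term
#' `E_i` over ligand atom pairs in different rigid groups. The receptor is
#' rigid, so its internal energy is a constant and is not included.
#'
#' @param receptor A `receptor`.
#' @param topology A `ligand_topology`.
#' @param pose A `pose`.
#' @param params A [force_field_params()].
#' @param context Optional precomputed [make_energy_context()] (must match
#'   `receptor`/`topology`/`params`); avoids rebuilding the pair tables.
#' @return An `energy_breakdown` with fields `e_v`, `e_h`, `e_e`, `e_i`, `e_d`
#'   and their sum `e_total` (kcal/mol).
#' @export
total_energy <- function(receptor, topology, pose, params = force_field_params(),
                         context = NULL) {
  if (is.null(context)) context <- make_energy_context(receptor, topology, params)
  if (length(pose$torsions) != context$n_torsions) {
    stop(sprintf("pose has %d torsion(s) but the ligand has %d rotatable bond(s)",
                 length(pose$torsions), context$n_torsions), call. = FALSE)
  }
  new_energy_breakdown(cpp_energy_breakdown(context, pose_to_genes(pose)))
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(
    "<energy_breakdown> total %.4f kcal/mol (vdw %.4f, hbond %.4f, elec %.4f, internal %.4f, desolv %.4f)\n",
    x$e_total, x$e_v, x$e_h, x$e_e, x$e_i, x$e_d))
  invisible(x)
}
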