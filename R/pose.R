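#' Candidate-solution encoding
#'
#' A pose is the candidate solution of the docking search: the ligand centroid
#' translation (3 coordinates, Angstrom), a rigid-body orientation stored as a
#' unit quaternion (4 scalars, normalized on construction), and one torsion
#' angle per rotatable bond (radians, wrapped to (-pi, pi]).
#'
#' @param translation Numeric 3-vector, Angstrom.
#' @param orientation Numeric 4-vector quaternion `(w, x, y, z)`; normalized.
#' @param torsions Numeric vector of torsion angles, radians.
#' @return A `pose` object.
#' @export
#' @examples
#' p <- pose(c(1, 2, 3), c(1, 0, 0, 0), pi / 2)
pose <- function(translation, orientation = c(1, 0, 0, 0), torsions = numeric(0)) {
  stopifnot(length(translation) == 3, length(orientation) == 4)
  if (any(!is.finite(c(translation, orientation, torsions)))) {
    stop("pose parameters must be finite", call. = FALSE)
  }
  structure(list(
    translation = as.numeric(translation),
    orientation = quat_normalize(as.numeric(orientation)),
    torsions = wrap_angle(as.numeric(torsions))
  ), class = "pose")
}

#' Search bounds for the translation box and torsions
#'
#' @param lower,upper Numeric 3-vectors: the docking box corners, Angstrom.
#' @return A `search_bounds` object.
#' @export
search_bounds <- function(lower, upper) {
  stopifnot(length(lower) == 3, length(upper) == 3)
  if (any(lower >= upper)) stop("search box: lower must be < upper on every axis", call. = FALSE)
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper)),
            class = "search_bounds")
}

#' Map a pose to ligand coordinates
#'
#' Torsions are applied innermost-first along the torsion tree (each rotates
#' its moved atom set about the parent-to-child bond axis), then the whole
#' ligand is rotated rigidly about its centroid by the orientation quaternion,
#' then the centroid is translated to the pose translation.
#'
#' @param topology A `ligand_topology`.
#' @param pose A `pose`; its torsion count must match the branch count.
#' @return An n_atoms x 3 coordinate matrix.
#' @export
apply_pose <- function(topology, pose) {
  nb <- length(topology$branches)
  if (length(pose$torsions) != nb) {
    stop(sprintf("pose has %d torsion(s) but topology has %d rotatable bond(s)",
                 length(pose$torsions), nb), call. = FALSE)
  }
  X <- as.matrix(topology$atoms[, c("x", "y", "z")])
  dimnames(X) <- NULL
  # branches are stored parents-first; reverse order applies leaves first
  for (j in rev(seq_len(nb))) {
    ang <- pose$torsions[j]
    if (ang != 0) {
      b <- topology$branches[[j]]
      p <- X[b$parent, ]
      ax <- X[b$child, ] - p
      R <- rotation_matrix_axis(ax, ang)
      idx <- b$moved
      X[idx, ] <- sweep(sweep(X[idx, , drop = FALSE], 2, p) %*% t(R), 2, p, `+`)
    }
  }
  ctr <- colMeans(X)
  Rq <- quat_to_matrix(pose$orientation)
  sweep(sweep(X, 2, ctr) %*% t(Rq), 2, pose$translation, `+`)
}

#' Root-mean-square deviation between two coordinate sets
#'
#' Plain per-atom RMSD in the docking convention: no re-superposition and no
#' symmetry correction.
#'
#' @param coords_a,coords_b n x 3 coordinate matrices with matched atom order.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) == 0) stop("rmsd: need at least one atom", call. = FALSE)
  if (!all(dim(coords_a) == dim(coords_b))) {
    stop("rmsd: coordinate sets differ in size", call. = FALSE)
  }
  sqrt(mean(rowSums((coords_a - coords_b)^2)))
}

#' Draw a random pose
#'
#' Translation uniform in the box, orientation uniform on the rotation group
#' (normalized 4-Gaussian), torsions uniform in (-pi, pi]. Uses R's current
#' random number stream.
#'
#' @param bounds A `search_bounds`.
#' @param n_torsions Number of rotatable bonds.
#' @return A `pose`.
#' @export
random_pose <- function(bounds, n_torsions = 0) {
  tr <- stats::runif(3, bounds$lower, bounds$upper)
  q <- quat_random()
  tors <- if (n_torsions > 0) stats::runif(n_torsions, -pi, pi) else numeric(0)
  pose(tr, q, tors)
}

# ---- flattened gene vector ------------------------------------------------
# Variation operators act on the flattened vector
#   [t_x, t_y, t_z, q_w, q_x, q_y, q_z, tor_1, ..., tor_n]

#' Gene-vector layout for the optimizers
#'
#' Describes the flattened encoding all optimizers share: which loci are the
#' translation (clamped to the docking box), the quaternion (renormalized after
#' every variation), and the torsions (wrapped to (-pi, pi]), plus the per-locus
#' perturbation scales used by mutation and Solis-Wets.
#'
#' @param n_torsions Number of rotatable bonds.
#' @param bounds A `search_bounds`, or `NULL` for an unbounded surrogate space.
#' @param scale_translation,scale_quaternion,scale_torsion Perturbation scales
#'   (Angstrom; quaternion components pre-normalization; radians).
#' @return A `gene_spec` list.
#' @export
gene_spec <- function(n_torsions, bounds,
                      scale_translation = 2.0,
                      scale_quaternion = 0.2,
                      scale_torsion = 15 * pi / 180) {
  g <- 7L + n_torsions
  lower <- rep(-Inf, g); upper <- rep(Inf, g)
  lower[1:3] <- bounds$lower; upper[1:3] <- bounds$upper
  structure(list(
    n_genes = g,
    idx_box = 1:3,
    idx_quat = 4:7,
    idx_tors = if (n_torsions > 0) 7L + seq_len(n_torsions) else integer(0),
    scales = c(rep(scale_translation, 3), rep(scale_quaternion, 4),
               rep(scale_torsion, n_torsions)),
    lower = lower, upper = upper
  ), class = "gene_spec")
}

# free-form spec for surrogate objective functions (no quaternion block)
plain_gene_spec <- function(n_genes, lower = -Inf, upper = Inf, scales = 1) {
  structure(list(
    n_genes = as.integer(n_genes),
    idx_box = seq_len(n_genes),
    idx_quat = integer(0),
    idx_tors = integer(0),
    scales = rep_len(scales, n_genes),
    lower = rep_len(lower, n_genes),
    upper = rep_len(upper, n_genes)
  ), class = "gene_spec")
}

pose_to_genes <- function(pose) {
  c(pose$translation, pose$orientation, pose$torsions)
}

genes_to_pose <- function(genes) {
  n_tors <- length(genes) - 7L
  pose(genes[1:3], genes[4:7],
       if (n_tors > 0) genes[7L + seq_len(n_tors)] else numeric(0))
}

# clamp box loci, renormalize the quaternion, wrap torsions; G is a matrix
repair_genes <- function(G, spec) {
  for (j in spec$idx_box) {
    if (is.finite(spec$lower[j])) G[, j] <- pmax(G[, j], spec$lower[j])
    if (is.finite(spec$upper[j])) G[, j] <- pmin(G[, j], spec$upper[j])
  }
  if (length(spec$idx_quat) == 4) {
    Q <- G[, spec$idx_quat, drop = FALSE]
    nrm <- sqrt(rowSums(Q^2))
    bad <- nrm < 1e-12
    if (any(bad)) {
      Q[bad, ] <- matrix(c(1, 0, 0, 0), sum(bad), 4, byrow = TRUE)
      nrm[bad] <- 1
    }
    G[, spec$idx_quat] <- Q / nrm
  }
  if (length(spec$idx_tors) > 0) {
    G[, spec$idx_tors] <- wrap_angle(G[, spec$idx_tors, drop = FALSE])
  }
  G
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("<pose> t = (%.3f, %.3f, %.3f), q = (%.3f, %.3f, %.3f, %.3f), %d torsion(s)\n",
              x$translation[1], x$translation[2], x$translation[3],
              x$orientation[1], x$orientation[2], x$orientation[3], x$orientation[4],
              length(x$torsions)))
  invisible(x)
}
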