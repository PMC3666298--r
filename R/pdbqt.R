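#' @title PDBQT input and output (documented subset)
#'
#' @description
#' The package reads and writes a documented subset of the PDBQT format:
#' `ATOM`/`HETATM` records with partial charges (columns 67-76) and docking
#' atom types (columns 78-79), plus the ligand torsion-tree records `ROOT`,
#' `ENDROOT`, `BRANCH`, `ENDBRANCH` and `TORSDOF`. `REMARK`, `MODEL` and `USER`
#' lines are ignored on input; parsing of a multi-model file stops at the first
#' `ENDMDL`. Coordinates are in Angstrom, right-handed axes, no origin shift.
#' Atom indices are 1-based internally; serial numbers are preserved for
#' output.
#'
#' @name pdbqt
NULL

parse_atom_record <- function(line, lineno, params) {
  if (nchar(line) < 79) {
    stop(sprintf("line %d: ATOM/HETATM record too short for the documented PDBQT column layout (need >= 79 columns, got %d)",
                 lineno, nchar(line)), call. = FALSE)
  }
  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) {
      stop(sprintf("line %d: malformed %s field '%s'", lineno, what, trimws(s)), call. = FALSE)
    }
    v
  }
  list(
    serial = as.integer(num(substr(line, 7, 11), "serial")),
    name = trimws(substr(line, 13, 16)),
    x = num(substr(line, 31, 38), "x"),
    y = num(substr(line, 39, 46), "y"),
    z = num(substr(line, 47, 54), "z"),
    charge = num(substr(line, 67, 76), "charge"),
    type = trimws(substr(line, 78, 79))
  )
}

atoms_to_tibble <- function(records, params) {
  atoms <- tibble::tibble(
    serial = vapply(records, `[[`, integer(1), "serial"),
    name = vapply(records, `[[`, character(1), "name"),
    type = vapply(records, `[[`, character(1), "type"),
    x = vapply(records, `[[`, numeric(1), "x"),
    y = vapply(records, `[[`, numeric(1), "y"),
    z = vapply(records, `[[`, numeric(1), "z"),
    charge = vapply(records, `[[`, numeric(1), "charge")
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite atom coordinates", call. = FALSE)
  }
  join_atom_params(atoms, params)
}

#' Parse a rigid receptor from PDBQT text
#'
#' @param text A single string (possibly multi-line) or a character vector of
#'   lines in the documented PDBQT subset.
#' @param params Atom parameter table, see [default_atom_params()].
#' @return A `receptor` object: a list with an `atoms` tibble.
#' @export
#' @examples
#' rec <- parse_receptor_pdbqt(paste0(
#'   "ATOM      1  C   REC A   1       0.000   0.000   0.000  1.00  0.00",
#'   "     0.100 C "))
#' nrow(rec$atoms)
parse_receptor_pdbqt <- function(text, params = default_atom_params()) {
  lines <- split_pdbqt_lines(text)
  rec_lines <- which(grepl("^(ATOM|HETATM)", lines))
  if (length(rec_lines) == 0) {
    stop("no ATOM/HETATM records found in receptor input", call. = FALSE)
  }
  records <- lapply(rec_lines, function(i) parse_atom_record(lines[i], i, params))
  new_receptor(atoms_to_tibble(records, params))
}

new_receptor <- function(atoms) {
  stopifnot(nrow(atoms) >= 1)
  structure(list(atoms = atoms), class = "receptor")
}

split_pdbqt_lines <- function(text) {
  if (length(text) == 1 && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  text
}

#' Parse a flexible ligand (atoms plus torsion tree) from PDBQT text
#'
#' Reconstructs the rooted torsion tree from `ROOT`/`BRANCH` nesting. The
#' number of branches equals the number of rotatable bonds. If a `TORSDOF`
#' record is present and disagrees with the branch count a warning is issued
#' but parsing succeeds.
#'
#' @inheritParams parse_receptor_pdbqt
#' @return A `ligand_topology` object: `atoms` tibble, `root` (atom indices of
#'   the rigid root), `branches` (list of `parent`/`child`/`moved` index sets,
#'   in order of appearance, parents before children), and `torsdof`.
#' @export
parse_ligand_pdbqt <- function(text, params = default_atom_params()) {
  lines <- split_pdbqt_lines(text)
  records <- list()
  root <- integer(0)
  branches <- list()        # finalized in encounter (preorder) order
  open <- integer(0)        # indices into `branches` of currently open blocks
  in_root <- FALSE
  seen_root <- FALSE
  torsdof <- NA_integer_
  serials <- integer(0)

  for (i in seq_along(lines)) {
    line <- lines[i]
    key <- trimws(substr(line, 1, 9))
    if (grepl("^(ATOM|HETATM)", line)) {
      rec <- parse_atom_record(line, i, params)
      records[[length(records) + 1]] <- rec
      serials <- c(serials, rec$serial)
      idx <- length(records)
      if (length(open) > 0) {
        for (b in open) branches[[b]]$moved <- c(branches[[b]]$moved, idx)
      } else if (in_root || !seen_root) {
        # atoms before any ROOT keyword are treated as root atoms
        root <- c(root, idx)
      } else {
        root <- c(root, idx)
      }
    } else if (grepl("^ROOT", line)) {
      in_root <- TRUE; seen_root <- TRUE
    } else if (grepl("^ENDROOT", line)) {
      in_root <- FALSE
    } else if (grepl("^BRANCH", line)) {
      toks <- strsplit(trimws(line), "\\s+")[[1]]
      if (length(toks) < 3) stop(sprintf("line %d: malformed BRANCH record", i), call. = FALSE)
      branches[[length(branches) + 1]] <- list(
        parent_serial = as.integer(toks[2]),
        child_serial = as.integer(toks[3]),
        moved = integer(0)
      )
      open <- c(open, length(branches))
    } else if (grepl("^ENDBRANCH", line)) {
      if (length(open) == 0) {
        stop(sprintf("line %d: ENDBRANCH without matching BRANCH", i), call. = FALSE)
      }
      open <- open[-length(open)]
    } else if (grepl("^TORSDOF", line)) {
      toks <- strsplit(trimws(line), "\\s+")[[1]]
      torsdof <- as.integer(toks[2])
    } else if (grepl("^ENDMDL", line)) {
      break
    }
    # REMARK, MODEL, USER, blank lines: ignored
  }

  if (length(open) > 0) {
    stop("unbalanced BRANCH nesting: ", length(open), " BRANCH block(s) not closed",
         call. = FALSE)
  }
  if (length(records) == 0) stop("no ATOM/HETATM records found in ligand input", call. = FALSE)

  atoms <- atoms_to_tibble(records, params)
  branches <- lapply(branches, function(b) {
    p <- match(b$parent_serial, serials)
    ch <- match(b$child_serial, serials)
    if (is.na(p) || is.na(ch)) {
      stop(sprintf("BRANCH %d %d references an atom serial absent from the file",
                   b$parent_serial, b$child_serial), call. = FALSE)
    }
    list(parent = p, child = ch, moved = b$moved)
  })

  if (!is.na(torsdof) && torsdof != length(branches)) {
    warning(sprintf("TORSDOF (%d) differs from the number of BRANCH blocks (%d); using the branch count",
                    torsdof, length(branches)), call. = FALSE)
  }
  new_ligand_topology(atoms, root, branches, torsdof)
}

#' Construct a ligand topology
#'
#' Validates the torsion tree: branches must form a tree rooted at the root
#' atoms (moved sets nested or disjoint), every non-root atom must belong to at
#' least one branch, each branch's child atom lies in its moved set and its
#' parent atom does not.
#'
#' @param atoms Atom tibble (as produced by the parser or [join_atom_params()]).
#' @param root Integer indices of the rigid root atoms.
#' @param branches List of `list(parent, child, moved)` with 1-based atom
#'   indices, parents listed before their sub-branches.
#' @param torsdof Declared torsion count (`TORSDOF`), or `NA`.
#' @return A `ligand_topology` object.
#' @export
new_ligand_topology <- function(atoms, root, branches, torsdof = NA_integer_) {
  n <- nrow(atoms)
  stopifnot(n >= 1)
  covered <- root
  for (j in seq_along(branches)) {
    b <- branches[[j]]
    if (!(b$child %in% b$moved)) {
      stop(sprintf("branch %d: child atom %d not in its moved set", j, b$child), call. = FALSE)
    }
    if (b$parent %in% b$moved) {
      stop(sprintf("branch %d: parent atom %d must stay on the root side of the bond",
                   j, b$parent), call. = FALSE)
    }
    covered <- union(covered, b$moved)
  }
  if (!setequal(covered, seq_len(n))) {
    stop("torsion tree does not cover all atoms: atoms ",
         paste(setdiff(seq_len(n), covered), collapse = ", "), " unassigned", call. = FALSE)
  }
  # nesting check: any two moved sets are nested or disjoint
  if (length(branches) > 1) {
    for (a in seq_along(branches)) {
      for (b in seq_along(branches)) {
        if (a < b) {
          ma <- branches[[a]]$moved; mb <- branches[[b]]$moved
          inter <- length(intersect(ma, mb))
          if (inter > 0 && inter != length(ma) && inter != length(mb)) {
            stop(sprintf("branches %d and %d overlap without nesting: not a tree", a, b),
                 call. = FALSE)
          }
        }
      }
    }
  }
  structure(list(atoms = atoms, root = sort(unique(root)), branches = branches,
                 torsdof = torsdof),
            class = "ligand_topology")
}

#' Rigid-group assignment
#'
#' Every atom belongs to exactly one rigid group: 0 for the root, otherwise the
#' index of the innermost branch whose moved set contains it.
#'
#' @param topology A `ligand_topology`.
#' @return Integer vector, one group id per atom.
#' @export
rigid_groups <- function(topology) {
  g <- integer(nrow(topology$atoms))   # 0 = root
  # branches are stored parents-first, so later (inner) assignments win
  for (j in seq_along(topology$branches)) {
    g[topology$branches[[j]]$moved] <- j
  }
  g
}

#' Write one or more coordinate sets as multi-model ligand PDBQT
#'
#' The torsion-tree skeleton (ROOT/BRANCH nesting) is reconstructed from the
#' topology so that re-parsing the output recovers the atom count, charges (3
#' decimals) and torsion tree.
#'
#' @param topology A `ligand_topology`.
#' @param coordinate_sets A list of n_atoms x 3 coordinate matrices.
#' @return A single string of PDBQT text.
#' @export
write_poses_pdbqt <- function(topology, coordinate_sets) {
  if (length(coordinate_sets) == 0) {
    stop("empty coordinate-set list: nothing to write", call. = FALSE)
  }
  n <- nrow(topology$atoms)
  for (k in seq_along(coordinate_sets)) {
    cs <- coordinate_sets[[k]]
    if (!is.matrix(cs) || nrow(cs) != n || ncol(cs) != 3) {
      stop(sprintf("coordinate set %d: expected a %d x 3 matrix", k, n), call. = FALSE)
    }
  }

  groups <- rigid_groups(topology)
  # parent branch of branch j: innermost branch containing j's parent atom
  parent_of <- vapply(topology$branches, function(b) groups[b$parent], numeric(1))
  children <- lapply(0:length(topology$branches), function(g) which(parent_of == g))

  atom_line <- function(i, xyz) {
    a <- topology$atoms[i, ]
    sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f%10.3f %-2s",
            "ATOM", a$serial, a$name, "LIG", "A", 1L,
            xyz[1], xyz[2], xyz[3], 1.00, 0.00, a$charge, a$type)
  }

  emit_branch <- function(j, xyzs) {
    b <- topology$branches[[j]]
    own <- which(groups == j)
    c(sprintf("BRANCH %3d %3d", topology$atoms$serial[b$parent], topology$atoms$serial[b$child]),
      vapply(own, function(i) atom_line(i, xyzs[i, ]), character(1)),
      unlist(lapply(children[[j + 1]], emit_branch, xyzs = xyzs)),
      sprintf("ENDBRANCH %3d %3d", topology$atoms$serial[b$parent], topology$atoms$serial[b$child]))
  }

  out <- character(0)
  for (k in seq_along(coordinate_sets)) {
    xyzs <- coordinate_sets[[k]]
    out <- c(out,
             sprintf("MODEL %8d", k),
             "ROOT",
             vapply(topology$root, function(i) atom_line(i, xyzs[i, ]), character(1)),
             "ENDROOT",
             unlist(lapply(children[[1]], emit_branch, xyzs = xyzs)),
             sprintf("TORSDOF %d", length(topology$branches)),
             "ENDMDL")
  }
  paste(out, collapse = "\n")
}

#' @export
print.receptor <- function(x, ...) {
  cat(sprintf("<receptor> %d atoms, %d atom types\n",
              nrow(x$atoms), length(unique(x$atoms$type))))
  invisible(x)
}

#' @export
print.ligand_topology <- function(x, ...) {
  cat(sprintf("<ligand_topology> %d atoms, %d rotatable bond(s), root of %d atom(s)\n",
              nrow(x$atoms), length(x$branches), length(x$root)))
  invisible(x)
}
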