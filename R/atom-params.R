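#' Atom parameter table
#'
#' Per-type van der Waals, solvation and hydrogen-bond parameters used by the
#' empirical energy function. Values are AD4-like defaults shipped as a plain
#' tab-separated file (`system.file("extdata", "atom_params.tsv", package =
#' "isledock")`); pass a modified copy to the parsers or to
#' [force_field_params()] to override them.
#'
#' Columns: `type` (docking atom type), `rii` (sum of van der Waals radii for a
#' like pair, Angstrom), `eps` (well depth, kcal/mol), `vol` (solvation volume,
#' cubic Angstrom), `solpar` (solvation parameter, kcal/(mol A^3)), `hbond`
#' (`none`, `donor` or `acceptor`), `hb_rij` / `hb_eps` (12-10 equilibrium
#' distance and well depth, used when the atom is the acceptor of a
#' donor-acceptor pair).
#'
#' @param path Optional path to an alternative parameter file with the same
#'   columns.
#' @return A tibble with one row per atom type.
#' @export
#' @examples
#' head(default_atom_params())
default_atom_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "atom_params.tsv", package = "isledock")
  }
  # na.strings = "": the nitrogen-acceptor type is spelled "NA"
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  required <- c("type", "rii", "eps", "vol", "solpar", "hbond", "hb_rij", "hb_eps")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("atom parameter table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(tab$rii <= 0)) stop("atom parameter table: rii must be > 0")
  if (any(tab$eps < 0)) stop("atom parameter table: eps must be >= 0")
  tibble::as_tibble(tab)
}

# join parameter columns onto a raw atom table; unknown types are an error
join_atom_params <- function(atoms, params = default_atom_params()) {
  idx <- match(atoms$type, params$type)
  if (anyNA(idx)) {
    bad <- sort(unique(atoms$type[is.na(idx)]))
    stop("unknown atom type(s) not in parameter table: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  atoms$vdw_radius <- params$rii[idx] / 2
  atoms$well_depth <- params$eps[idx]
  atoms$solvation_volume <- params$vol[idx]
  atoms$solvation_parameter <- params$solpar[idx]
  atoms$hbond <- params$hbond[idx]
  atoms$hb_rij <- params$hb_rij[idx]
  atoms$hb_eps <- params$hb_eps[idx]
  atoms
}
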