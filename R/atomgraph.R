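#' Atom-type vocabulary
#'
#' The model initialises every atom from its type alone, so the vocabulary is
#' element-based: a fixed set of heavy elements plus one reserved code per
#' (virtual-token kind, entity role) combination.  Hydrogens are dropped on
#' input and are not part of the vocabulary.
#'
#' @return Character vector of vocabulary symbols; the integer code of a
#'   symbol is its position in this vector.
#' @export
atom_vocab <- function() {
  c(
    "C", "N", "O", "S", "P", "F", "Cl", "Br", "I",
    "[CLS:pocket]", "[CLS:molecule]", "[ENCODE:pocket]", "[ENCODE:molecule]"
  )
}

#' @rdname atom_vocab
#' @param symbols character vector of atom-type symbols.
#' @export
atom_type_codes <- function(symbols) {
  codes <- match(symbols, atom_vocab())
  if (anyNA(codes)) {
    bad <- unique(symbols[is.na(codes)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  codes
}

bond_type_levels <- function() c("single", "double", "triple", "aromatic")

virtual_symbol <- function(token_kind, entity_role) {
  paste0("[", token_kind, ":", entity_role, "]")
}

#' Construct a typed 3D atom graph
#'
#' `AtomGraph` is the package's central container: a pocket or a molecule as a
#' set of typed atoms with Cartesian coordinates in Angstrom, chemical bonds
#' (molecules only; pockets carry none), and optional virtual tokens placed at
#' the entity centroid.
#'
#' @param entity_role `"pocket"` or `"molecule"`.
#' @param atom_types character vector of vocabulary symbols (see
#'   [atom_vocab()]), one per atom.
#' @param coords numeric n x 3 matrix of coordinates in Angstrom.
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices) and
#'   `type` (one of single/double/triple/aromatic), or `NULL` for no bonds.
#' @param virtual_flags logical vector, `TRUE` for virtual tokens.
#' @param source_id opaque identifier carried through untouched.
#' @param residue_ids optional per-atom residue identifiers (pockets only),
#'   used by the pocket-size filter.
#' @return An object of class `atom_graph`.
#' @export
atom_graph <- function(entity_role, atom_types, coords, bonds = NULL,
                       virtual_flags = NULL, source_id = "",
                       residue_ids = NULL) {
  entity_role <- match.arg(entity_role, c("pocket", "molecule"))
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- length(atom_types)
  if (is.null(virtual_flags)) virtual_flags <- rep(FALSE, n)
  stopifnot(nrow(coords) == n, ncol(coords) == 3,
            length(virtual_flags) == n)
  if (!all(is.finite(coords))) stop("non-finite coordinates in atom graph")
  if (sum(!virtual_flags) < 1) stop("atom graph needs at least one real atom")
  atom_type_codes(atom_types)  # validates symbols
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0) {
    bonds <- data.frame(i = integer(0), j = integer(0),
                        type = character(0), stringsAsFactors = FALSE)
  } else {
    bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
    stopifnot(all(c("i", "j", "type") %in% names(bonds)))
    bonds$i <- as.integer(bonds$i); bonds$j <- as.integer(bonds$j)
    if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n))
      stop("bond endpoint index out of range")
    if (any(bonds$i == bonds$j)) stop("self-bond (i == j) not allowed")
    if (!all(bonds$type %in% bond_type_levels()))
      stop("unknown bond type: ",
           paste(setdiff(bonds$type, bond_type_levels()), collapse = ", "))
    if (any(virtual_flags[bonds$i] | virtual_flags[bonds$j]))
      stop("virtual atoms must not carry chemical bonds")
  }
  if (!is.null(residue_ids)) stopifnot(length(residue_ids) == n)
  structure(
    list(entity_role = entity_role,
         atom_types = as.character(atom_types),
         coords = coords,
         bonds = bonds,
         virtual_flags = as.logical(virtual_flags),
         source_id = source_id,
         residue_ids = residue_ids),
    class = "atom_graph")
}

#' @export
print.atom_graph <- function(x, ...) {
  cat(sprintf("<atom_graph %s '%s': %d atoms (%d virtual), %d bonds>\n",
              x$entity_role, x$source_id, length(x$atom_types),
              sum(x$virtual_flags), nrow(x$bonds)))
  invisible(x)
}

n_atoms <- function(g) length(g$atom_types)
n_real_atoms <- function(g) sum(!g$virtual_flags)
real_coords <- function(g) g$coords[!g$virtual_flags, , drop = FALSE]

#' Insert a virtual token atom at the entity centroid
#'
#' Appends one virtual atom whose coordinates are the unweighted centroid of
#' the real atoms, with a reserved vocabulary code keyed by
#' (`token_kind`, entity role).  Virtual atoms never receive bond records;
#' their connection to all atoms exists only through the fully connected pair
#' representation inside the encoder.
#'
#' @param graph an [atom_graph()].
#' @param token_kind `"CLS"` (summary token) or `"ENCODE"` (cross-context
#'   token for the pocket-grounded pass).
#' @return The graph with one additional virtual atom.
#' @export
insert_virtual_atom <- function(graph, token_kind = c("CLS", "ENCODE")) {
  token_kind <- match.arg(token_kind)
  sym <- virtual_symbol(token_kind, graph$entity_role)
  if (sym %in% graph$atom_types[graph$virtual_flags])
    stop("graph already carries a virtual ", token_kind, " token")
  centroid <- colMeans(real_coords(graph))
  graph$atom_types <- c(graph$atom_types, sym)
  graph$coords <- rbind(graph$coords, matrix(centroid, 1, 3))
  graph$virtual_flags <- c(graph$virtual_flags, TRUE)
  if (!is.null(graph$residue_ids)) graph$residue_ids <- c(graph$residue_ids, NA)
  graph
}

#' Pair a pocket and a molecule into a training complex
#'
#' @param pocket,molecule [atom_graph()] objects with the matching roles.
#' @param match_label 1 for a true (bound) pair, 0 for a mismatched pair.
#' @param true_ligand_coords optional n_mol x 3 matrix of the ground-truth
#'   ligand pose (one row per real molecule atom), in the pocket's frame.
#' @param pair_id opaque identifier.
#' @return An object of class `complex_pair`.
#' @export
complex_pair <- function(pocket, molecule, match_label,
                         true_ligand_coords = NULL, pair_id = "") {
  stopifnot(inherits(pocket, "atom_graph"), pocket$entity_role == "pocket",
            inherits(molecule, "atom_graph"),
            molecule$entity_role == "molecule")
  if (!match_label %in% c(0L, 1L)) stop("match_label must be 0 or 1")
  if (!is.null(true_ligand_coords)) {
    true_ligand_coords <- as.matrix(true_ligand_coords)
    storage.mode(true_ligand_coords) <- "double"
    if (nrow(true_ligand_coords) != n_real_atoms(molecule))
      stop("true_ligand_coords must have one row per real molecule atom")
  }
  structure(
    list(pocket = pocket, molecule = molecule,
         match_label = as.integer(match_label),
         true_ligand_coords = true_ligand_coords, pair_id = pair_id),
    class = "complex_pair")
}

#' @export
print.complex_pair <- function(x, ...) {
  cat(sprintf("<complex_pair '%s': pocket %d atoms, molecule %d atoms, label %d%s>\n",
              x$pair_id, length(x$pocket$atom_types),
              length(x$molecule$atom_types), x$match_label,
              if (is.null(x$true_ligand_coords)) "" else ", true pose"))
  invisible(x)
}

#' Accept or reject a complex on the pocket-size rule
#'
#' A complex is usable when its binding pocket has at least `min_residues`
#' residues with at least one atom within `radius` of any ligand atom.  The
#' rule is residue-level: a residue qualifies as a whole or not at all.
#'
#' @param pair a [complex_pair()] whose pocket retains residue metadata.
#' @param min_residues minimum number of qualifying residues (default 5).
#' @param radius contact radius in Angstrom (default 5).
#' @return A list with `accept` (logical), `reason` (character, `""` when
#'   accepted) and `n_qualifying` (integer residue count).
#' @export
validate_complex <- function(pair, min_residues = 5, radius = 5) {
  stopifnot(inherits(pair, "complex_pair"))
  rid <- pair$pocket$residue_ids
  if (is.null(rid)) stop("pocket carries no residue metadata")
  keep <- !pair$pocket$virtual_flags
  pk <- pair$pocket$coords[keep, , drop = FALSE]
  rid <- rid[keep]
  lig <- real_coords(pair$molecule)
  dmin <- apply(pk, 1, function(a) {
    sqrt(min(rowSums(sweep(lig, 2, a)^2)))
  })
  qual <- unique(rid[dmin <= radius])
  n_q <- length(qual)
  if (n_q >= min_residues) {
    list(accept = TRUE, reason = "", n_qualifying = n_q)
  } else {
    list(accept = FALSE,
         reason = sprintf("insufficient pocket residues: %d within %g A (need >= %d)",
                          n_q, radius, min_residues),
         n_qualifying = n_q)
  }
}
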