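#' Extract a binding pocket from a PDB file
#'
#' Reads `ATOM` records with [bio3d::read.pdb()] and keeps every residue with
#' at least one heavy atom within `radius` of any ligand coordinate.
#' Inclusion is residue-level: a qualifying residue is kept whole.
#' Heteroatoms and waters are excluded, hydrogens are dropped, and alternate
#' locations are resolved to the highest-occupancy conformer.  Residue
#' identity is (chain, residue number, insertion code), so the result carries
#' the residue metadata needed by [validate_complex()].
#'
#' @param path path to a PDB file.
#' @param ligand_coords m x 3 matrix of ligand coordinates in Angstrom.
#' @param radius pocket radius in Angstrom (must be > 0).
#' @param source_id identifier for the resulting graph; defaults to the file
#'   name.
#' @return An [atom_graph()] with `entity_role = "pocket"`, empty bonds and
#'   per-atom `residue_ids`.
#' @export
read_pocket <- function(path, ligand_coords, radius = 5,
                        source_id = basename(path)) {
  stopifnot(radius > 0)
  ligand_coords <- as.matrix(ligand_coords)
  stopifnot(ncol(ligand_coords) == 3)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("PDB file has no ATOM records: ", path)
  if (anyNA(at$x) || anyNA(at$y) || anyNA(at$z))
    stop("ATOM record with missing coordinates in ", path)
  # element symbol: PDB element column, falling back to the atom-name prefix
  elem <- trimws(at$elesy)
  miss <- is.na(elem) | elem == ""
  elem[miss] <- sub("[0-9'].*$", "", trimws(at$elety[miss]))
  elem <- paste0(toupper(substr(elem, 1, 1)),
                 tolower(substr(elem, 2, 2)))
  heavy <- !(elem %in% c("H", "D"))
  at <- at[heavy, , drop = FALSE]; elem <- elem[heavy]
  # alternate locations: keep the highest-occupancy conformer per atom site
  alt <- at$alt; alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    site <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
    occ <- at$o; occ[is.na(occ)] <- 1
    ord <- order(site, -occ, alt)
    keep_first <- !duplicated(site[ord])
    sel <- sort(ord[keep_first])
    at <- at[sel, , drop = FALSE]; elem <- elem[sel]
  }
  ins <- at$insert; ins[is.na(ins)] <- ""
  rid <- paste(at$chain, at$resno, ins, sep = "|")
  xyz <- cbind(at$x, at$y, at$z)
  d2 <- vapply(seq_len(nrow(xyz)), function(k) {
    min(rowSums(sweep(ligand_coords, 2, xyz[k, ])^2))
  }, numeric(1))
  qual <- unique(rid[d2 <= radius^2])
  if (length(qual) == 0)
    stop("empty pocket: no residue within ", radius, " A of the ligand")
  sel <- rid %in% qual
  unknown <- setdiff(unique(elem[sel]),
                     grep("^\\[", atom_vocab(), value = TRUE, invert = TRUE))
  if (length(unknown) > 0)
    stop("unknown element symbol(s) in pocket: ",
         paste(unknown, collapse = ", "))
  atom_graph("pocket", elem[sel], xyz[sel, , drop = FALSE],
             source_id = source_id, residue_ids = rid[sel])
}
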