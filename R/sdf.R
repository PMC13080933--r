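# SDF V2000 reading/writing.  The reader is deliberately strict: fixed-width
# V2000 fields, line-numbered parse errors, and an explicit warning (not an
# error) for 2D-only records.  Hydrogens are dropped on input; bond indices
# are remapped accordingly.

parse_sdf_block <- function(lines, offset, source_id) {
  ln <- function(k) offset + k  # absolute line number for messages
  if (length(lines) < 4)
    stop("malformed SDF: truncated molecule block at line ", ln(1))
  counts <- lines[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds))
    stop("malformed SDF: unreadable counts line at line ", ln(4))
  if (length(lines) < 4 + natoms + nbonds)
    stop("malformed SDF: block shorter than counts line promises (line ",
         ln(4), ")")
  dim_flag <- trimws(substr(lines[2], 21, 22))
  coords <- matrix(NA_real_, natoms, 3)
  elems <- character(natoms)
  for (k in seq_len(natoms)) {
    row <- lines[4 + k]
    xyz <- suppressWarnings(as.numeric(c(substr(row, 1, 10),
                                         substr(row, 11, 20),
                                         substr(row, 21, 30))))
    if (anyNA(xyz))
      stop("malformed SDF: unreadable atom coordinates at line ", ln(4 + k))
    coords[k, ] <- xyz
    elems[k] <- trimws(substr(row, 32, 34))
    if (elems[k] == "")
      stop("malformed SDF: missing element symbol at line ", ln(4 + k))
  }
  bonds <- data.frame(i = integer(0), j = integer(0), type = character(0),
                      stringsAsFactors = FALSE)
  if (nbonds > 0) {
    bi <- bj <- integer(nbonds); bt <- integer(nbonds)
    for (k in seq_len(nbonds)) {
      row <- lines[4 + natoms + k]
      v <- suppressWarnings(as.integer(c(substr(row, 1, 3),
                                         substr(row, 4, 6),
                                         substr(row, 7, 9))))
      if (anyNA(v))
        stop("malformed SDF: unreadable bond record at line ",
             ln(4 + natoms + k))
      if (any(v[1:2] < 1) || any(v[1:2] > natoms))
        stop("malformed SDF: bond atom index out of range at line ",
             ln(4 + natoms + k))
      if (!v[3] %in% 1:4)
        stop("malformed SDF: unsupported bond type ", v[3], " at line ",
             ln(4 + natoms + k))
      bi[k] <- v[1]; bj[k] <- v[2]; bt[k] <- v[3]
    }
    bonds <- data.frame(i = bi, j = bj, type = bond_type_levels()[bt],
                        stringsAsFactors = FALSE)
  }
  if (identical(dim_flag, "2D") && all(abs(coords[, 3]) < 1e-12))
    warning("SDF block at line ", ln(1),
            " is flagged 2D with all-zero z coordinates")
  # drop hydrogens, remap bonds
  keep <- !(elems %in% c("H", "D", "T"))
  if (!any(keep)) stop("SDF block at line ", ln(1), " has no heavy atoms")
  idx_map <- cumsum(keep)
  bonds <- bonds[keep[bonds$i] & keep[bonds$j], , drop = FALSE]
  bonds$i <- idx_map[bonds$i]; bonds$j <- idx_map[bonds$j]
  elems <- elems[keep]; coords <- coords[keep, , drop = FALSE]
  unknown <- setdiff(unique(elems),
                     setdiff(atom_vocab(), grep("^\\[", atom_vocab(), value = TRUE)))
  if (length(unknown) > 0)
    stop("unknown element symbol(s) in SDF: ", paste(unknown, collapse = ", "))
  atom_graph("molecule", elems, coords, bonds, source_id = source_id)
}

#' Read molecules from an SDF (V2000) file
#'
#' Parses every molecule block of an SDF file into an [atom_graph()] with
#' `entity_role = "molecule"`.  Hydrogens are dropped; bonds are preserved
#' with their single/double/triple/aromatic codes; atom order follows the
#' file.  A block whose dimensional flag is `2D` and whose z column is all
#' zero triggers a warning.
#'
#' @param path path to an SDF V2000 file.
#' @return A list of `atom_graph` objects, one per molecule block, in file
#'   order.
#' @export
read_molecule <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # split on $$$$ delimiters; a single block without the delimiter is allowed
  delim <- grep("^\\$\\$\\$\\$", lines)
  starts <- c(1L, delim + 1L)
  ends <- c(delim - 1L, length(lines))
  out <- list()
  for (b in seq_along(starts)) {
    blk <- starts[b]:min(ends[b], length(lines))
    if (starts[b] > length(lines)) next
    block <- lines[blk]
    if (all(trimws(block) == "")) next
    mend <- grep("^M  END", block)
    upto <- if (length(mend) > 0) mend[1] else length(block)
    title <- trimws(block[1])
    sid <- if (nzchar(title)) title else sprintf("%s#%d", basename(path), b)
    out[[length(out) + 1L]] <-
      parse_sdf_block(block[seq_len(upto)], starts[b] - 1L, sid)
  }
  if (length(out) == 0) stop("no molecule blocks found in ", path)
  out
}

#' Write a molecule pose to an SDF (V2000) file
#'
#' Emits a single-molecule SDF with the supplied coordinates and the graph's
#' original atom types and bonds.  Virtual tokens are omitted.  Coordinates
#' are written at the format's 4-decimal precision.
#'
#' @param molecule an [atom_graph()] with `entity_role = "molecule"`.
#' @param coords n x 3 matrix with one row per real atom of `molecule`; if
#'   `NULL`, the graph's own coordinates are used.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pose <- function(molecule, coords = NULL, path) {
  stopifnot(inherits(molecule, "atom_graph"),
            molecule$entity_role == "molecule")
  keep <- !molecule$virtual_flags
  if (is.null(coords)) coords <- molecule$coords[keep, , drop = FALSE]
  coords <- as.matrix(coords)
  if (nrow(coords) != sum(keep) || ncol(coords) != 3)
    stop("coords must be ", sum(keep), " x 3 (one row per real atom)")
  elems <- molecule$atom_types[keep]
  bonds <- molecule$bonds  # bonds never touch virtual atoms; indices of real
  # atoms are unchanged because virtual tokens are appended last
  n <- sum(keep)
  lines <- c(
    molecule$source_id,
    "  pocketformer          3D",
    "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(bonds))
  )
  for (k in seq_len(n)) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              coords[k, 1], coords[k, 2], coords[k, 3],
                              elems[k]))
  }
  if (nrow(bonds) > 0) {
    bt <- match(bonds$type, bond_type_levels())
    for (k in seq_len(nrow(bonds))) {
      lines <- c(lines, sprintf("%3d%3d%3d  0", bonds$i[k], bonds$j[k], bt[k]))
    }
  }
  lines <- c(lines, "M  END", "$$$$")
  writeLines(lines, path)
  invisible(path)
}
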