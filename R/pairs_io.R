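# JSON-lines fixture format: one complex_pair per line with explicit fields.
# This is the canonical interchange emitted by the synthetic generator and
# consumed by training.

graph_to_list <- function(g) {
  list(entity_role = g$entity_role,
       atom_types = g$atom_types,
       coords = unname(apply(g$coords, 1, as.numeric, simplify = FALSE)),
       bonds = if (nrow(g$bonds) == 0) list() else
         unname(Map(function(i, j, t) list(i, j, t),
                    g$bonds$i, g$bonds$j, g$bonds$type)),
       virtual_flags = g$virtual_flags,
       source_id = g$source_id,
       residue_ids = g$residue_ids)
}

graph_from_list <- function(x) {
  coords <- do.call(rbind, lapply(x$coords, as.numeric))
  bonds <- if (length(x$bonds) == 0) NULL else
    data.frame(i = vapply(x$bonds, function(b) as.integer(b[[1]]), 1L),
               j = vapply(x$bonds, function(b) as.integer(b[[2]]), 1L),
               type = vapply(x$bonds, function(b) as.character(b[[3]]), ""),
               stringsAsFactors = FALSE)
  atom_graph(x$entity_role, unlist(x$atom_types), coords, bonds,
             virtual_flags = unlist(x$virtual_flags),
             source_id = x$source_id,
             residue_ids = if (is.null(x$residue_ids)) NULL else
               unlist(x$residue_ids))
}

#' Write / read complex pairs as JSON lines
#'
#' One [complex_pair()] per line; atom types as element strings, coordinates
#' as arrays, bonds as `(i, j, type)` triples.  Numbers are written at full
#' precision so that write/read round-trips are exact to JSON double
#' precision.
#'
#' @param pairs list of `complex_pair` objects.
#' @param path file path.
#' @return `write_pairs()` returns `path` invisibly; `read_pairs()` returns a
#'   list of `complex_pair` objects.
#' @export
write_pairs <- function(pairs, path) {
  lines <- vapply(pairs, function(p) {
    jsonlite::toJSON(
      list(pair_id = p$pair_id,
           match_label = p$match_label,
           pocket = graph_to_list(p$pocket),
           molecule = graph_to_list(p$molecule),
           true_ligand_coords = if (is.null(p$true_ligand_coords)) NULL else
             unname(apply(p$true_ligand_coords, 1, as.numeric,
                          simplify = FALSE))),
      auto_unbox = TRUE, digits = NA, null = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    x <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    complex_pair(graph_from_list(x$pocket), graph_from_list(x$molecule),
                 x$match_label,
                 true_ligand_coords = if (is.null(x$true_ligand_coords)) NULL
                 else do.call(rbind, lapply(x$true_ligand_coords, as.numeric)),
                 pair_id = x$pair_id)
  })
}

#' Pad a list of atom graphs into a batch
#'
#' Packs graphs into padded type/coordinate arrays with validity masks.  The
#' encoder consumes batches graph-wise through the masks, so padded positions
#' can never influence real-atom outputs.
#'
#' @param graphs list of [atom_graph()] objects.
#' @param max_atoms padding width; every graph must fit.
#' @return An object of class `graph_batch` with fields `type_codes`
#'   (B x max_atoms), `coords` (B x max_atoms x 3), `mask` (B x max_atoms
#'   logical), `n_atoms`, and the original `graphs`.
#' @export
batch_graphs <- function(graphs, max_atoms) {
  stopifnot(length(graphs) >= 1)
  ns <- vapply(graphs, n_atoms, 1L)
  over <- which(ns > max_atoms)
  if (length(over) > 0)
    stop(sprintf("graph '%s' has %d atoms, exceeding max_atoms = %d",
                 graphs[[over[1]]]$source_id, ns[over[1]], max_atoms))
  B <- length(graphs)
  types <- matrix(0L, B, max_atoms)
  coords <- array(0, c(B, max_atoms, 3))
  mask <- matrix(FALSE, B, max_atoms)
  for (b in seq_len(B)) {
    g <- graphs[[b]]
    types[b, seq_len(ns[b])] <- atom_type_codes(g$atom_types)
    coords[b, seq_len(ns[b]), ] <- g$coords
    mask[b, seq_len(ns[b])] <- TRUE
  }
  structure(list(type_codes = types, coords = coords, mask = mask,
                 n_atoms = ns, graphs = graphs),
            class = "graph_batch")
}
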