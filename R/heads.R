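# Public encoding API and the output heads.

#' Encode an atom graph (separate-encoder mode)
#'
#' Runs the dual-track encoder on a single pocket or molecule graph.  Virtual
#' tokens already inserted with [insert_virtual_atom()] take part as ordinary
#' tokens of the fully connected pair representation, sitting at the entity
#' centroid.
#'
#' @param model a [new_model()].
#' @param graph an [atom_graph()].
#' @param keep_cache keep intermediate activations for a backward pass.
#' @return An encoder output: `atom_reps` (n x d), `pair_initial` and
#'   `pair_final` (n x n x H), `cls_embedding` (named list, one d-vector per
#'   virtual token present), `coords_in`, and bookkeeping indices.
#' @export
encode_graph <- function(model, graph, keep_cache = FALSE) {
  types <- atom_type_codes(graph$atom_types)
  fwd <- encoder_fwd(model, types, graph$coords, graph$bonds, keep_cache)
  out <- list(atom_reps = fwd$atom_reps, pair_initial = fwd$q0,
              pair_final = fwd$qL, coords_in = fwd$coords_in,
              cache = fwd$cache,
              real_flags = !graph$virtual_flags,
              movable = rep(FALSE, length(types)))
  vir <- which(graph$virtual_flags)
  out$cls_embedding <- stats::setNames(
    lapply(vir, function(i) fwd$atom_reps[i, ]),
    graph$atom_types[vir])
  out
}

# Assemble the joint pocket+molecule atom set: pocket real atoms first, then
# the molecule (its virtual tokens included, recentred at the ligand
# centroid).  Molecule bonds are offset; no cross-entity bonds exist.
joint_inputs <- function(pocket, molecule, ligand_coords = NULL) {
  pk_keep <- !pocket$virtual_flags
  pk_types <- pocket$atom_types[pk_keep]
  pk_xyz <- pocket$coords[pk_keep, , drop = FALSE]
  np <- nrow(pk_xyz)
  ml_types <- molecule$atom_types
  ml_xyz <- molecule$coords
  ml_real <- !molecule$virtual_flags
  if (!is.null(ligand_coords)) {
    ligand_coords <- as.matrix(ligand_coords)
    stopifnot(nrow(ligand_coords) == sum(ml_real))
    ml_xyz[ml_real, ] <- ligand_coords
    if (any(!ml_real))  # virtual tokens follow the ligand centroid
      ml_xyz[!ml_real, ] <- matrix(colMeans(ligand_coords),
                                   sum(!ml_real), 3, byrow = TRUE)
  }
  bonds <- molecule$bonds
  if (nrow(bonds) > 0) {
    bonds$i <- bonds$i + np; bonds$j <- bonds$j + np
  }
  list(types = atom_type_codes(c(pk_types, ml_types)),
       coords = rbind(pk_xyz, ml_xyz),
       bonds = bonds,
       idx_pocket = seq_len(np),
       idx_mol = np + seq_along(ml_types),
       idx_mol_real = np + which(ml_real),
       idx_mol_virtual = np + which(!ml_real),
       mol_virtual_types = ml_types[!ml_real],
       real = c(rep(TRUE, np), ml_real))
}

#' Encode a pocket-molecule pair jointly
#'
#' Concatenates the pocket's real atoms with the molecule's atoms (including
#' the molecule's virtual tokens) into one fully connected set with a single
#' pair tensor, and runs the encoder.  Used by the matching, docking and
#' pose-ranking paths.
#'
#' @inheritParams encode_graph
#' @param pocket,molecule the two [atom_graph()]s.
#' @param ligand_coords optional override for the molecule's real-atom
#'   coordinates (an input pose), rows in molecule atom order.
#' @return As [encode_graph()], plus index vectors `idx_pocket`,
#'   `idx_mol_real`, `idx_mol_virtual` and the joint `real`/`movable` flags.
#' @export
encode_joint <- function(model, pocket, molecule, ligand_coords = NULL,
                         keep_cache = FALSE) {
  ji <- joint_inputs(pocket, molecule, ligand_coords)
  fwd <- encoder_fwd(model, ji$types, ji$coords, ji$bonds, keep_cache)
  movable <- rep(FALSE, length(ji$types))
  movable[ji$idx_mol_real] <- TRUE
  out <- list(atom_reps = fwd$atom_reps, pair_initial = fwd$q0,
              pair_final = fwd$qL, coords_in = fwd$coords_in,
              cache = fwd$cache, real_flags = ji$real, movable = movable,
              idx_pocket = ji$idx_pocket, idx_mol = ji$idx_mol,
              idx_mol_real = ji$idx_mol_real,
              idx_mol_virtual = ji$idx_mol_virtual)
  out$cls_embedding <- stats::setNames(
    lapply(ji$idx_mol_virtual, function(i) fwd$atom_reps[i, ]),
    ji$mol_virtual_types)
  out
}

#' Encode a padded batch
#'
#' Convenience wrapper running [encode_graph()] over every graph of a
#' [batch_graphs()] batch.  Graphs are processed through their masks, so
#' outputs for a graph are identical whether it is batched alone or with
#' others.
#'
#' @param model a [new_model()].
#' @param batch a `graph_batch`.
#' @return List of encoder outputs, one per graph.
#' @export
encode_batch <- function(model, batch) {
  stopifnot(inherits(batch, "graph_batch"))
  lapply(batch$graphs, function(g) encode_graph(model, g))
}

# ---- coordinate head -------------------------------------------------------

#' Equivariant coordinate head
#'
#' Predicts updated coordinates for the movable (real molecule) atoms:
#' `x_i + (1/n) * sum_j (x_i - x_j) c_ij` with `c_ij = ReLU((q^L - q^0) U) W`
#' a scalar per ordered pair, the sum running over all real atoms of the
#' joint context.  Because `c_ij` is built from rigid-transform-invariant
#' pair features and the update is a combination of difference vectors, the
#' head is SE(3)-equivariant by construction.
#'
#' @param model a [new_model()].
#' @param enc a joint encoder output from [encode_joint()].
#' @param keep_cache keep activations for the backward pass.
#' @return List with `coords` (n x 3 predicted coordinates; non-movable atoms
#'   unchanged) and `cache`.
#' @export
coordinate_head <- function(model, enc, keep_cache = FALSE) {
  p <- model$params
  n <- nrow(enc$atom_reps)
  H <- dim(enc$pair_final)[3]
  real <- which(enc$real_flags)
  mov <- which(enc$movable)
  if (length(real) == 0) stop("empty real-atom context")
  # c_ij enters the update only for movable i and real context j, so the MLP
  # is evaluated on that block alone
  D <- enc$pair_final[mov, real, , drop = FALSE] -
    enc$pair_initial[mov, real, , drop = FALSE]
  nm <- length(mov); nr <- length(real)
  Dflat <- matrix(D, nm * nr, H)
  Z <- Dflat %*% p$coord_U
  Z <- Z * (Z > 0)
  cmat <- matrix(Z %*% p$coord_W, nm, nr)
  X <- enc$coords_in
  Xr <- X[real, , drop = FALSE]
  S <- rowSums(cmat)
  M <- cmat %*% Xr
  out <- X
  out[mov, ] <- X[mov, , drop = FALSE] +
    (S * X[mov, , drop = FALSE] - M) / nr
  list(coords = out,
       cache = if (keep_cache) list(Dflat = Dflat, Z = Z, mov = mov,
                                    real = real, n = n, H = H) else NULL)
}

# dcoords: n x 3 upstream gradient (only movable rows used).  Returns head
# parameter grads and the dqL / dq0_direct arrays to feed encoder_bwd.
coordinate_head_bwd <- function(model, enc, head, dcoords) {
  p <- model$params; ch <- head$cache
  n <- ch$n; real <- ch$real; mov <- ch$mov
  nr <- length(real); nm <- length(mov)
  X <- enc$coords_in; Xr <- X[real, , drop = FALSE]
  dmov <- dcoords[mov, , drop = FALSE]
  a <- rowSums(dmov * X[mov, , drop = FALSE])       # dxhat_i . x_i
  dC <- (a - tcrossprod(dmov, Xr)) / nr             # nm x nr
  dc_flat <- matrix(dC, nm * nr, 1)
  dZ <- dc_flat %*% t(p$coord_W)
  dZ <- dZ * (ch$Z > 0)
  g <- list(coord_W = crossprod(ch$Z, dc_flat),
            coord_U = crossprod(ch$Dflat, dZ))
  dDblock <- array(dZ %*% t(p$coord_U), c(nm, nr, ch$H))
  dD <- array(0, c(n, n, ch$H))
  dD[mov, real, ] <- dDblock
  list(grads = g, dqL = dD, dq0 = -dD)
}

# ---- distance head ---------------------------------------------------------

#' Distance head
#'
#' Projects the symmetrised final pair features through a two-layer MLP and a
#' softplus positivity map into a symmetric, non-negative distance matrix
#' with a zero diagonal.  Intramolecular entries describe the ligand
#' conformation; pocket-molecule entries localise the ligand in the site.
#'
#' @param model a [new_model()].
#' @param enc a joint encoder output.
#' @return n x n predicted distance matrix (Angstrom).
#' @export
distance_head <- function(model, enc) {
  p <- model$params
  n <- nrow(enc$atom_reps)
  qsym <- (enc$pair_final + aperm(enc$pair_final, c(2, 1, 3))) / 2
  flat <- matrix(qsym, n * n, dim(qsym)[3])
  h1 <- pmax(flat %*% p$dist_W1 +
               matrix(p$dist_b1, n * n, length(p$dist_b1), byrow = TRUE), 0)
  z <- h1 %*% p$dist_W2 + p$dist_b2
  dm <- matrix(softplus(z), n, n)
  diag(dm) <- 0
  dm
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

# ---- docking score head ----------------------------------------------------

#' Docking score
#'
#' Affinity ranking score of a joint pass (arbitrary units, higher is
#' better), combining two pose-sensitive terms:
#'
#' * a learned interaction readout: a small MLP maps each (pocket atom i,
#'   ligand atom j) cross-pair feature `q^L_ij` to a scalar pair energy,
#'   averaged over the cross block;
#' * a self-consistency term: minus `exp(log lambda)` times the mean
#'   displacement magnitude the coordinate head would apply to the ligand.
#'   A refinement model moves a near-native pose very little and a wrong
#'   pose a lot, so the model's own proposed movement measures how far a
#'   pose sits from where the model places the ligand.
#'
#' @param model a [new_model()].
#' @param enc a joint encoder output from [encode_joint()].
#' @return Scalar score.
#' @export
docking_score <- function(model, enc) {
  docking_score_fwd(model, enc)$s
}

docking_score_fwd <- function(model, enc, keep_cache = FALSE) {
  p <- model$params
  if (is.null(enc$idx_pocket)) stop("docking score needs a joint encoding")
  np <- length(enc$idx_pocket); nm <- length(enc$idx_mol_real)
  H <- dim(enc$pair_final)[3]
  F <- matrix(enc$pair_final[enc$idx_pocket, enc$idx_mol_real, ,
                             drop = FALSE], np * nm, H)
  pre <- F %*% p$score_W1 + matrix(p$score_b1, np * nm,
                                   length(p$score_b1), byrow = TRUE)
  h1 <- pre * (pre > 0)
  m <- matrix(h1 %*% p$score_w2, np, nm)      # pair energies
  ch <- coordinate_head(model, enc, keep_cache = keep_cache)
  u <- ch$coords[enc$idx_mol_real, , drop = FALSE] -
    enc$coords_in[enc$idx_mol_real, , drop = FALSE]
  unorm <- sqrt(rowSums(u^2))
  disp <- mean(unorm)
  lambda <- exp(p$score_log_lambda)
  list(s = mean(m) + p$score_b2 - lambda * disp,
       F = F, pre = pre, h1 = h1, np = np, nm = nm, H = H,
       ch = ch, u = u, unorm = unorm, disp = disp, lambda = lambda)
}

docking_score_bwd <- function(model, enc, dscore, fwd = NULL) {
  p <- model$params
  if (is.null(fwd)) fwd <- docking_score_fwd(model, enc, keep_cache = TRUE)
  dmflat <- matrix(dscore / (fwd$np * fwd$nm), fwd$np * fwd$nm, 1)
  dh1 <- dmflat %*% t(p$score_w2)
  dpre <- dh1 * (fwd$pre > 0)
  g <- list(score_w2 = crossprod(fwd$h1, dmflat),
            score_b2 = dscore,
            score_W1 = crossprod(fwd$F, dpre),
            score_b1 = colSums(dpre),
            score_log_lambda = -dscore * fwd$lambda * fwd$disp)
  dqL <- array(0, dim(enc$pair_final))
  dqL[enc$idx_pocket, enc$idx_mol_real, ] <-
    array(tcrossprod(dpre, p$score_W1), c(fwd$np, fwd$nm, fwd$H))
  # displacement term: d s / d xhat_i = -lambda * u_i / (nm * |u_i|)
  du <- -dscore * fwd$lambda * fwd$u / (fwd$nm * pmax(fwd$unorm, 1e-8))
  dcoords <- matrix(0, nrow(enc$coords_in), 3)
  dcoords[enc$idx_mol_real, ] <- du
  cb <- coordinate_head_bwd(model, enc, fwd$ch, dcoords)
  g$coord_U <- cb$grads$coord_U
  g$coord_W <- cb$grads$coord_W
  dqL <- dqL + cb$dqL
  list(grads = g, dqL = dqL, dq0 = cb$dq0)
}
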