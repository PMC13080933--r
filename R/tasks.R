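# Task modes: virtual screening (separate-encoder similarity), target
# fishing (joint matching probability) and docking / pose ranking.

ensure_token <- function(graph, token_kind) {
  sym <- virtual_symbol(token_kind, graph$entity_role)
  if (sym %in% graph$atom_types) graph else
    insert_virtual_atom(graph, token_kind)
}

#' Screen a molecule library against a pocket
#'
#' Encodes the pocket once (CLS token inserted if absent) and scores every
#' molecule by projected-CLS similarity; no joint pass is involved, so a
#' library scales linearly in molecule encodes.
#'
#' @param model a [new_model()].
#' @param pocket a pocket [atom_graph()].
#' @param molecules list of molecule graphs.
#' @param labels optional activity labels carried into the table.
#' @return A [score_table()] ranked by similarity.
#' @export
screen_library <- function(model, pocket, molecules, labels = NULL) {
  if (length(molecules) == 0) stop("empty molecule library")
  pocket <- ensure_token(pocket, "CLS")
  encP <- encode_graph(model, pocket)
  vP <- encP$cls_embedding[[virtual_symbol("CLS", "pocket")]]
  scores <- vapply(molecules, function(m) {
    m <- ensure_token(m, "CLS")
    encM <- encode_graph(model, m)
    similarity(model, vP, encM$cls_embedding[[virtual_symbol("CLS", "molecule")]])
  }, numeric(1))
  ids <- vapply(seq_along(molecules), function(i) {
    sid <- molecules[[i]]$source_id
    if (nzchar(sid)) sid else sprintf("mol-%03d", i)
  }, character(1))
  score_table(ids, scores, labels)
}

#' Rank candidate pockets for a molecule (target fishing)
#'
#' Runs one pocket-grounded joint pass per candidate pocket with the ENCODE
#' token on the molecule; the score is the softmax probability of the
#' "matched" class.
#'
#' @param model a [new_model()].
#' @param molecule a molecule [atom_graph()].
#' @param pockets list of pocket graphs.
#' @param labels optional labels (1 = true target).
#' @return A [score_table()] ranked by matching probability.
#' @export
fish_targets <- function(model, molecule, pockets, labels = NULL) {
  if (length(pockets) == 0) stop("empty pocket list")
  molecule <- ensure_token(molecule, "ENCODE")
  tok <- virtual_symbol("ENCODE", "molecule")
  scores <- vapply(pockets, function(pk) {
    enc <- encode_joint(model, pk, molecule)
    lg <- match_logits(model, enc$cls_embedding[[tok]])
    e <- exp(lg - max(lg))
    (e / sum(e))[2]
  }, numeric(1))
  ids <- vapply(seq_along(pockets), function(i) {
    sid <- pockets[[i]]$source_id
    if (nzchar(sid)) sid else sprintf("pocket-%03d", i)
  }, character(1))
  score_table(ids, scores, labels)
}

#' Dock a molecule into a pocket
#'
#' Starting from the supplied (or the molecule's own) coordinates, performs
#' `recycles + 1` rounds of joint encoding followed by the equivariant
#' coordinate head applied to the ligand atoms, then reads the docking score
#' from the final joint pass.
#'
#' @param model a [new_model()].
#' @param pair a [complex_pair()]; its molecule's coordinates are the initial
#'   pose unless `init_coords` is given.
#' @param init_coords optional n_mol x 3 starting pose.
#' @param recycles number of re-encoding rounds (default from the model
#'   config).
#' @return A `pose_result`: `predicted_coords`, `docking_score`,
#'   `rmsd_to_truth` (when the pair carries a true pose) and `recycle_trace`.
#' @export
dock <- function(model, pair, init_coords = NULL, recycles = NULL) {
  if (is.null(recycles)) recycles <- model$config$recycles
  mol <- pair$molecule
  keep <- !mol$virtual_flags
  coords <- if (is.null(init_coords)) mol$coords[keep, , drop = FALSE] else
    as.matrix(init_coords)
  trace <- list()
  enc <- NULL
  for (r in seq_len(recycles + 1)) {
    enc <- encode_joint(model, pair$pocket, mol, ligand_coords = coords)
    ch <- coordinate_head(model, enc)
    coords <- ch$coords[enc$idx_mol_real, , drop = FALSE]
    trace[[r]] <- coords
  }
  enc_final <- encode_joint(model, pair$pocket, mol, ligand_coords = coords)
  res <- list(predicted_coords = coords,
              docking_score = docking_score(model, enc_final),
              rmsd_to_truth = if (is.null(pair$true_ligand_coords)) NULL else
                rmsd(coords, pair$true_ligand_coords),
              recycle_trace = trace)
  class(res) <- "pose_result"
  res
}

#' @export
print.pose_result <- function(x, ...) {
  cat(sprintf("<pose_result: score=%.4f%s, %d refinement round(s)>\n",
              x$docking_score,
              if (is.null(x$rmsd_to_truth)) "" else
                sprintf(", RMSD=%.3f A", x$rmsd_to_truth),
              length(x$recycle_trace)))
  invisible(x)
}

#' Score and rank candidate poses
#'
#' Rescoring semantics: each pose is scored by a joint pass with no
#' coordinate movement, then ranked descending.
#'
#' @param model a [new_model()].
#' @param pair a [complex_pair()].
#' @param poses list of n_mol x 3 pose matrices sharing the molecule's
#'   topology.
#' @param rmsds optional per-pose RMSD annotations carried into the table.
#' @return A [score_table()] (with an `rmsd` column when `rmsds` is given).
#' @export
rank_poses <- function(model, pair, poses, rmsds = NULL) {
  n_mol <- n_real_atoms(pair$molecule)
  scores <- vapply(seq_along(poses), function(k) {
    ps <- as.matrix(poses[[k]])
    if (nrow(ps) != n_mol || ncol(ps) != 3)
      stop("pose ", k, " does not match the molecule topology (",
           n_mol, " atoms)")
    enc <- encode_joint(model, pair$pocket, pair$molecule,
                        ligand_coords = ps)
    docking_score(model, enc)
  }, numeric(1))
  ids <- sprintf("pose-%03d", seq_along(poses))
  tab <- score_table(ids, scores)
  if (!is.null(rmsds)) {
    stopifnot(length(rmsds) == length(poses))
    tab$rmsd <- rmsds[match(tab$item_id, ids)]
  }
  tab
}

#' Fine-tune the docking score head on native-vs-decoy discrimination
#'
#' None of the four pre-training losses supervise the affinity-ranking
#' readout, so pose ranking is trained separately with a listwise objective:
#' per step one complex is drawn, its native pose is scored alongside decoy
#' poses at controlled RMSD, and the cross-entropy of the softmax over the
#' pose set against the native is minimised by AdamW through the score head
#' and the backbone.  Ranking is within-complex, so the loss compares scores
#' within one pose set rather than against a global threshold.
#'
#' @param model a [new_model()].
#' @param pairs list of matched [complex_pair()]s with true poses.
#' @param steps optimisation steps.
#' @param lr learning rate.
#' @param decoys_per_step decoy poses drawn per step alongside one native.
#' @param decoy_rmsd_range RMSD range (Angstrom) the decoys are drawn from.
#' @param grad_clip global gradient-norm ceiling.
#' @param seed integer seed.
#' @return The trained model, with a `history` attribute of per-step losses.
#' @export
fit_pose_ranker <- function(model, pairs, steps = 150, lr = 1e-3,
                            decoys_per_step = 8,
                            decoy_rmsd_range = c(2, 10), grad_clip = 1.0,
                            seed = 1L) {
  opt <- adamw_init(model$params)
  history <- numeric(steps)
  for (st in seq_len(steps)) {
    pair <- pairs[[with_seed(derive_seed(seed, 401L, st),
                             sample.int(length(pairs), 1))]]
    targets <- with_seed(derive_seed(seed, 402L, st),
                         stats::runif(decoys_per_step, decoy_rmsd_range[1],
                                      decoy_rmsd_range[2]))
    poses <- c(list(pair$true_ligand_coords),
               lapply(seq_len(decoys_per_step), function(k)
                 make_decoy_pose(pair, targets[k],
                                 seed = derive_seed(seed, 403L, st, k))))
    encs <- lapply(poses, function(ps)
      encode_joint(model, pair$pocket, pair$molecule,
                   ligand_coords = ps, keep_cache = TRUE))
    fwds <- lapply(encs, function(e)
      docking_score_fwd(model, e, keep_cache = TRUE))
    s <- vapply(fwds, function(f) f$s, numeric(1))
    p <- exp(s - max(s)); p <- p / sum(p)
    loss <- -log(max(p[1], 1e-300))     # native is element 1
    ds <- p; ds[1] <- ds[1] - 1
    acc <- grad_acc(model)
    for (k in seq_along(poses)) {
      sb <- docking_score_bwd(model, encs[[k]], ds[k], fwd = fwds[[k]])
      acc_add(acc, sb$grads)
      encoder_bwd(model, encs[[k]], NULL, dqL = sb$dqL, dq0_direct = sb$dq0,
                  acc = acc)
    }
    history[st] <- loss
    grads <- clip_grads(acc$g, grad_clip)
    upd <- adamw_step(model$params, grads, opt, lr = lr, weight_decay = 0.05)
    model$params <- upd$params; opt <- upd$state
  }
  attr(model, "history") <- history
  model
}
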