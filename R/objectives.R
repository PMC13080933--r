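# The three pre-training objectives: contrastive alignment (CLS tokens,
# separate passes), pocket-grounded matching (ENCODE token, joint passes,
# hard-negative mining) and the geometric docking losses (Huber on
# intramolecular distances + MSE on coordinates).  Each loss comes with the
# gradients needed to chain into the encoder backward pass.

project_normalize <- function(v, W, b) {
  z <- as.numeric(v %*% W) + b
  nz <- sqrt(sum(z^2))
  if (nz < 1e-12) stop("zero-norm projection")
  list(u = z / nz, z = z, norm = nz)
}

#' Pocket-molecule similarity
#'
#' Cosine-type similarity between the CLS embeddings of a pocket and a
#' molecule: both are linearly projected to the shared space and
#' L2-normalised, then combined by dot product, so the score lies in
#' [-1, 1].
#'
#' @param model a [new_model()].
#' @param v_cls_P,v_cls_M CLS embeddings (d-vectors) from the pocket and
#'   molecule passes.
#' @return Scalar similarity.
#' @export
similarity <- function(model, v_cls_P, v_cls_M) {
  p <- model$params
  uP <- project_normalize(matrix(v_cls_P, 1), p$gP, p$gP_b)$u
  uM <- project_normalize(matrix(v_cls_M, 1), p$gM, p$gM_b)$u
  sum(uP * uM)
}

# Projected, normalised batch; rows are items.  Returns U (N x k) + cache.
project_batch <- function(cls, W, b) {
  Z <- cls %*% W + matrix(b, nrow(cls), length(b), byrow = TRUE)
  norms <- sqrt(rowSums(Z^2))
  if (any(norms < 1e-12)) stop("zero-norm projection")
  list(U = Z / norms, Z = Z, norms = norms)
}

project_batch_bwd <- function(dU, pb) {
  dZ <- (dU - pb$U * rowSums(dU * pb$U)) / pb$norms
  dZ
}

#' Batch similarity matrix
#'
#' @param model a [new_model()].
#' @param cls_P,cls_M N x d matrices of CLS embeddings; row i of both is the
#'   matched pair.
#' @return N x N matrix `S[i, j] = s(P_i, M_j)`.
#' @export
similarity_matrix <- function(model, cls_P, cls_M) {
  p <- model$params
  pP <- project_batch(cls_P, p$gP, p$gP_b)
  pM <- project_batch(cls_M, p$gM, p$gM_b)
  tcrossprod(pP$U, pM$U)
}

#' Contrastive alignment loss
#'
#' InfoNCE in both directions at temperature tau: softmax over molecules per
#' pocket and over pockets per molecule, cross-entropy against the diagonal,
#' averaged and halved.
#'
#' @param model a [new_model()].
#' @param cls_P,cls_M N x d matrices of CLS embeddings (row i matched).
#' @param with_grads also return gradients (`d_cls_P`, `d_cls_M`, parameter
#'   grads for the projection heads and temperature).
#' @return List with `loss`, the similarity matrix `S`, and optionally
#'   gradients.
#' @export
contrastive_loss <- function(model, cls_P, cls_M, with_grads = FALSE) {
  p <- model$params
  N <- nrow(cls_P)
  if (N < 1) stop("empty batch")
  pP <- project_batch(cls_P, p$gP, p$gP_b)
  pM <- project_batch(cls_M, p$gM, p$gM_b)
  S <- tcrossprod(pP$U, pM$U)
  tau <- exp(p$log_tau)
  L <- S / tau
  P_p2m <- softmax_rows(L)
  P_m2p <- softmax_rows(t(L))
  loss <- 0.5 * (mean(-log(pmax(diag(P_p2m), 1e-300))) +
                   mean(-log(pmax(diag(P_m2p), 1e-300))))
  out <- list(loss = loss, S = S)
  if (with_grads) {
    Y <- diag(N)
    dL <- (P_p2m - Y) / (2 * N) + t(P_m2p - Y) / (2 * N)
    dS <- dL / tau
    d_log_tau <- -sum(dL * S) / tau
    dUP <- dS %*% pM$U
    dUM <- crossprod(dS, pP$U)
    dZP <- project_batch_bwd(dUP, pP)
    dZM <- project_batch_bwd(dUM, pM)
    out$grads <- list(gP = crossprod(cls_P, dZP), gP_b = colSums(dZP),
                      gM = crossprod(cls_M, dZM), gM_b = colSums(dZM),
                      log_tau = d_log_tau)
    out$d_cls_P <- tcrossprod(dZP, p$gP)
    out$d_cls_M <- tcrossprod(dZM, p$gM)
  }
  out
}

#' Hard-negative mining
#'
#' Selects, for each pocket, one non-matching molecule (and symmetrically one
#' non-matching pocket per molecule) that the contrastive stage scores as
#' deceptively similar.  `"sample"` draws with probability proportional to
#' the softmax of off-diagonal similarities; `"argmax"` takes the single
#' highest off-diagonal.
#'
#' @param sim_matrix N x N similarity matrix (diagonal = matched pairs).
#' @param seed integer seed for the sampling strategy.
#' @param strategy `"sample"` or `"argmax"`.
#' @return data.frame with columns `pocket`, `molecule`, `direction`
#'   (`"p2m"` rows share the pocket, `"m2p"` rows share the molecule);
#'   `pocket != molecule` always.  Empty for N < 2.
#' @export
mine_hard_negatives <- function(sim_matrix, seed = 1L,
                                strategy = c("sample", "argmax")) {
  strategy <- match.arg(strategy)
  N <- nrow(sim_matrix)
  if (N < 2)
    return(data.frame(pocket = integer(0), molecule = integer(0),
                      direction = character(0)))
  pick <- function(row_sims, self) {
    cand <- setdiff(seq_len(N), self)
    s <- row_sims[cand]
    if (strategy == "argmax") {
      cand[which.max(s)]
    } else {
      w <- exp(s - max(s))
      cand[sample.int(length(cand), 1, prob = w / sum(w))]
    }
  }
  with_seed(seed, {
    mol_for_pocket <- vapply(seq_len(N), function(i)
      pick(sim_matrix[i, ], i), 1L)
    pocket_for_mol <- vapply(seq_len(N), function(j)
      pick(sim_matrix[, j], j), 1L)
    rbind(
      data.frame(pocket = seq_len(N), molecule = mol_for_pocket,
                 direction = "p2m", stringsAsFactors = FALSE),
      data.frame(pocket = pocket_for_mol, molecule = seq_len(N),
                 direction = "m2p", stringsAsFactors = FALSE))
  })
}

#' Matching loss
#'
#' Binary cross-entropy of the matched/unmatched classifier applied to the
#' ENCODE-token embedding of joint passes.
#'
#' @param logits B x 2 matrix of class logits (column 2 = "matched").
#' @param labels length-B vector in {0, 1}.
#' @param with_grads also return `d_logits`.
#' @return List with `loss` (and `d_logits`).
#' @export
matching_loss <- function(logits, labels, with_grads = FALSE) {
  logits <- as.matrix(logits)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  B <- nrow(logits)
  P <- softmax_rows(logits)
  idx <- cbind(seq_len(B), labels + 1L)
  loss <- mean(-log(pmax(P[idx], 1e-300)))
  out <- list(loss = loss)
  if (with_grads) {
    Y <- matrix(0, B, 2); Y[idx] <- 1
    out$d_logits <- (P - Y) / B
  }
  out
}

match_logits <- function(model, enc_embedding) {
  p <- model$params
  as.numeric(matrix(enc_embedding, 1) %*% p$match_W) + p$match_b
}

#' Huber function
#'
#' Quadratic inside `[-delta, delta]`, linear outside, continuous and once
#' differentiable at the joint where both branches equal `delta^2 / 2`.
#'
#' @param a numeric deviations.
#' @param delta positive threshold.
#' @return Huber values (same shape as `a`).
#' @export
huber <- function(a, delta) {
  stopifnot(delta > 0)
  aa <- abs(a)
  ifelse(aa <= delta, 0.5 * a^2, delta * (aa - 0.5 * delta))
}

huber_grad <- function(a, delta) {
  ifelse(abs(a) <= delta, a, delta * sign(a))
}

#' Intramolecular docking loss
#'
#' Mean Huber penalty on the deviations between predicted and ground-truth
#' pairwise distances over all unordered real-atom pairs of the molecule;
#' keeps the predicted ligand conformation internally consistent.
#'
#' @param pred_coords,true_coords n x 3 matrices (Angstrom), same atom order.
#' @param delta Huber threshold (Angstrom).
#' @param with_grads also return `d_pred` (gradient w.r.t. `pred_coords`).
#' @return List with `loss` (and `d_pred`).
#' @export
intra_loss <- function(pred_coords, true_coords, delta = 1.0,
                       with_grads = FALSE) {
  pred_coords <- as.matrix(pred_coords); true_coords <- as.matrix(true_coords)
  stopifnot(all(dim(pred_coords) == dim(true_coords)))
  n <- nrow(pred_coords)
  if (n < 2) {
    warning("intra loss needs >= 2 atoms; returning 0")
    return(list(loss = 0,
                d_pred = if (with_grads) pred_coords * 0 else NULL))
  }
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  dp <- pred_coords[ij[, 1], , drop = FALSE] -
    pred_coords[ij[, 2], , drop = FALSE]
  dt <- true_coords[ij[, 1], , drop = FALSE] -
    true_coords[ij[, 2], , drop = FALSE]
  dist_p <- sqrt(rowSums(dp^2)); dist_t <- sqrt(rowSums(dt^2))
  dev <- dist_p - dist_t
  loss <- mean(huber(dev, delta))
  out <- list(loss = loss)
  if (with_grads) {
    m <- nrow(ij)
    gdev <- huber_grad(dev, delta) / m
    unit <- dp / pmax(dist_p, 1e-8)
    gpair <- unit * gdev
    d_pred <- matrix(0, n, 3)
    for (k in seq_len(m)) {
      d_pred[ij[k, 1], ] <- d_pred[ij[k, 1], ] + gpair[k, ]
      d_pred[ij[k, 2], ] <- d_pred[ij[k, 2], ] - gpair[k, ]
    }
    out$d_pred <- d_pred
  }
  out
}

#' Intermolecular docking loss
#'
#' Mean squared coordinate deviation per ligand atom (Angstrom^2) in the
#' shared pocket frame; anchors the predicted pose to the true binding
#' position.
#'
#' @inheritParams intra_loss
#' @return List with `loss` (and `d_pred`).
#' @export
inter_loss <- function(pred_coords, true_coords, with_grads = FALSE) {
  pred_coords <- as.matrix(pred_coords); true_coords <- as.matrix(true_coords)
  if (!all(dim(pred_coords) == dim(true_coords)))
    stop("coordinate shape mismatch")
  n <- nrow(pred_coords)
  diff <- pred_coords - true_coords
  loss <- sum(diff^2) / n
  out <- list(loss = loss)
  if (with_grads) out$d_pred <- 2 * diff / n
  out
}

#' Combine loss components
#'
#' @param l_pmc,l_pmm,l_intra,l_inter the four components (contrastive,
#'   matching, intra, inter).
#' @return A `loss_report`: the components plus their unit-weight sum.
#' @export
total_loss <- function(l_pmc = 0, l_pmm = 0, l_intra = 0, l_inter = 0) {
  comps <- c(l_pmc = l_pmc, l_pmm = l_pmm, l_intra = l_intra,
             l_inter = l_inter)
  bad <- names(comps)[!is.finite(comps)]
  if (length(bad) > 0)
    stop("non-finite loss component(s): ", paste(bad, collapse = ", "))
  structure(list(l_pmc = l_pmc, l_pmm = l_pmm, l_intra = l_intra,
                 l_inter = l_inter,
                 total = l_pmc + l_pmm + l_intra + l_inter),
            class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf("loss: total=%.6g (pmc=%.4g pmm=%.4g intra=%.4g inter=%.4g)\n",
              x$total, x$l_pmc, x$l_pmm, x$l_intra, x$l_inter))
  invisible(x)
}
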