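# Dual-track encoder: atom representations (n x d) and a pair tensor
# (n x n x H) updated jointly.  The pair tensor is initialised from RBF-coded
# squared distances plus bond embeddings, biases every attention head, and is
# incremented by each block's raw attention logits.  Forward and backward
# passes are hand-derived; see the gradient-check tests.

#' Gaussian RBF encoding of squared distances
#'
#' Maps squared Euclidean distances through a bank of Gaussian kernels
#' `exp(-gamma_g * d2)`, one channel per kernel, giving a smooth,
#' rigid-transform-invariant distance code in (0, 1].
#'
#' @param sq_dists n x n matrix of squared distances (Angstrom^2).
#' @param gammas vector of G positive kernel widths (1/Angstrom^2).
#' @return n x n x G array of features.
#' @export
rbf_encode <- function(sq_dists, gammas) {
  sq_dists <- as.matrix(sq_dists)
  if (any(sq_dists < 0)) stop("negative squared distance")
  n <- nrow(sq_dists)
  array(exp(-as.vector(sq_dists) %o% gammas), c(n, n, length(gammas)))
}

sq_dist_matrix <- function(coords) {
  s <- rowSums(coords^2)
  d2 <- outer(s, s, "+") - 2 * tcrossprod(coords)
  d2[d2 < 0] <- 0
  d2
}

#' Initial pair tensor
#'
#' `q0[i,j,] = Linear(RBF(|x_i - x_j|^2)) + BondEmbed(bond(i,j))`, fully
#' connected over every ordered atom pair (virtual tokens included, at their
#' centroid coordinates); the no-bond embedding is the zero vector.
#'
#' @param model a [new_model()].
#' @param coords n x 3 coordinates.
#' @param bonds bond data.frame (`i`, `j`, `type`) or `NULL`.
#' @return List with `q0` (n x n x H), plus the flattened RBF features kept
#'   for the backward pass.
#' @export
init_pair <- function(model, coords, bonds = NULL) {
  cfg <- model$config; p <- model$params
  n <- nrow(coords); H <- cfg$heads
  rbf_flat <- exp(-as.vector(sq_dist_matrix(coords)) %o% cfg$rbf_gammas)
  q0_flat <- rbf_flat %*% p$rbf_w +
    matrix(p$rbf_b, n * n, H, byrow = TRUE)
  q0 <- array(q0_flat, c(n, n, H))
  bond_code <- NULL
  if (!is.null(bonds) && nrow(bonds) > 0) {
    bt <- match(bonds$type, bond_type_levels())
    bond_code <- cbind(bonds$i, bonds$j, bt)
    for (k in seq_len(nrow(bond_code))) {
      i <- bond_code[k, 1]; j <- bond_code[k, 2]; t <- bond_code[k, 3]
      q0[i, j, ] <- q0[i, j, ] + p$bond_emb[t, ]
      q0[j, i, ] <- q0[j, i, ] + p$bond_emb[t, ]
    }
  }
  list(q0 = q0, rbf_flat = rbf_flat, bond_code = bond_code)
}

softmax_rows <- function(m) {
  # max-subtraction for stability; max.col is deterministic with "first"
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  e <- exp(m - mx)
  e / rowSums(e)
}

layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- xc * inv_sd
  list(y = sweep(xhat, 2, g, "*") + matrix(b, nrow(x), length(b), byrow = TRUE),
       xhat = xhat, inv_sd = inv_sd)
}

layernorm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat); db <- colSums(dy)
  dxhat <- sweep(dy, 2, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * cache$inv_sd
  list(dx = dx, dg = dg, db = db)
}

# One transformer block: pair-biased multi-head attention -> residual+norm
# -> feed-forward -> residual+norm, plus the pair-track update from this
# block's raw logits.  `mask` (optional logical) removes invalid atoms from
# the softmax columns.
attention_block_fwd <- function(p, pre, X, q, cfg, mask = NULL,
                                keep_cache = FALSE) {
  n <- nrow(X); d <- cfg$atom_dim; H <- cfg$heads; dh <- d / H
  scale <- 1 / sqrt(dh)
  Qm <- X %*% p[[paste0(pre, "Wq")]] +
    matrix(p[[paste0(pre, "bq")]], n, d, byrow = TRUE)
  Km <- X %*% p[[paste0(pre, "Wk")]] +
    matrix(p[[paste0(pre, "bk")]], n, d, byrow = TRUE)
  Vm <- X %*% p[[paste0(pre, "Wv")]] +
    matrix(p[[paste0(pre, "bv")]], n, d, byrow = TRUE)
  raw <- array(0, c(n, n, H)); A <- array(0, c(n, n, H))
  O <- matrix(0, n, d)
  for (h in seq_len(H)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    raw_h <- tcrossprod(Qm[, idx, drop = FALSE],
                        Km[, idx, drop = FALSE]) * scale
    logits <- raw_h + q[, , h]
    if (!is.null(mask)) logits[, !mask] <- -Inf
    if (any(is.nan(logits))) stop("NaN in attention logits")
    A_h <- softmax_rows(logits)
    O[, idx] <- A_h %*% Vm[, idx, drop = FALSE]
    raw[, , h] <- raw_h; A[, , h] <- A_h
  }
  attn_out <- O %*% p[[paste0(pre, "Wo")]] +
    matrix(p[[paste0(pre, "bo")]], n, d, byrow = TRUE)
  x1pre <- X + attn_out
  ln1 <- layernorm_fwd(x1pre, p[[paste0(pre, "ln1_g")]],
                       p[[paste0(pre, "ln1_b")]])
  X1 <- ln1$y
  pre_act <- X1 %*% p[[paste0(pre, "W1")]] +
    matrix(p[[paste0(pre, "b1")]], n, cfg$ffn_dim, byrow = TRUE)
  Hff <- pre_act * (pre_act > 0)
  ff <- Hff %*% p[[paste0(pre, "W2")]] +
    matrix(p[[paste0(pre, "b2")]], n, d, byrow = TRUE)
  x2pre <- X1 + ff
  ln2 <- layernorm_fwd(x2pre, p[[paste0(pre, "ln2_g")]],
                       p[[paste0(pre, "ln2_b")]])
  list(X = ln2$y, q = q + raw,
       cache = if (keep_cache)
         list(X = X, Qm = Qm, Km = Km, Vm = Vm, raw = raw, A = A, O = O,
              ln1 = ln1, X1 = X1, pre_act = pre_act, Hff = Hff,
              ln2 = ln2) else NULL)
}

#' Pair-biased attention block
#'
#' Applies one transformer block to atom representations: per-head attention
#' logits `(Q_i . K_j) / sqrt(d/H) + q_ij[h]`, softmax (masked columns get
#' -Inf), value aggregation, output projection, residual + layer norm, and a
#' feed-forward block with residual + layer norm.
#'
#' @param model a [new_model()].
#' @param atom_reps n x d atom representations.
#' @param pair n x n x H pair tensor biasing the attention.
#' @param layer which block's parameters to use (default 1).
#' @param mask optional logical vector of valid atoms.
#' @return Updated n x d atom representations.
#' @export
attention_layer <- function(model, atom_reps, pair, layer = 1, mask = NULL) {
  attention_block_fwd(model$params, sprintf("L%d.", layer), atom_reps, pair,
                      model$config, mask = mask)$X
}

#' Pair-track update from attention logits
#'
#' `q[i,j,h] + (Q_i^h . K_j^h) / sqrt(d/H)`: the raw (pre-softmax, pre-mask,
#' pre-bias) per-head logits are added to the incoming pair tensor.
#'
#' @param pair n x n x H pair tensor.
#' @param Q,K n x d query/key matrices from the same block.
#' @param heads number of heads H.
#' @return Updated n x n x H pair tensor.
#' @export
pair_update <- function(pair, Q, K, heads) {
  n <- nrow(Q); d <- ncol(Q); dh <- d / heads
  out <- pair
  for (h in seq_len(heads)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    out[, , h] <- out[, , h] +
      tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(dh)
  }
  out
}

# Forward through the L blocks for one (possibly joint) atom set.
# types: integer codes; coords: n x 3; bonds: data.frame or NULL.
encoder_fwd <- function(model, types, coords, bonds = NULL,
                        keep_cache = FALSE) {
  cfg <- model$config; p <- model$params
  n <- length(types)
  if (n > cfg$max_atoms) stop("input has ", n, " atoms, exceeds max_atoms = ",
                              cfg$max_atoms)
  ip <- init_pair(model, coords, bonds)
  q <- ip$q0
  X <- p$embed[types, , drop = FALSE]
  X0 <- X
  layer_caches <- if (keep_cache) vector("list", cfg$layers) else NULL
  for (l in seq_len(cfg$layers)) {
    blk <- attention_block_fwd(p, sprintf("L%d.", l), X, q, cfg,
                               keep_cache = keep_cache)
    if (keep_cache) layer_caches[[l]] <- blk$cache
    X <- blk$X
    q <- blk$q
  }
  list(atom_reps = X, q0 = ip$q0, qL = q, coords_in = coords,
       cache = if (keep_cache)
         list(types = types, X0 = X0, layers = layer_caches,
              rbf_flat = ip$rbf_flat, bond_code = ip$bond_code, n = n) else NULL)
}

# Backward: dX (n x d) gradient on final atom reps, dqL (n x n x H or NULL)
# on the final pair tensor, dq0_direct on the initial pair tensor (heads that
# consume q0 directly, e.g. the coordinate head's q^L - q^0 difference).
encoder_bwd <- function(model, fwd, dX, dqL = NULL, dq0_direct = NULL,
                        acc = NULL) {
  cfg <- model$config; p <- model$params
  cache <- fwd$cache
  if (is.null(cache)) stop("forward pass was run without keep_cache = TRUE")
  n <- cache$n; d <- cfg$atom_dim; H <- cfg$heads; dh <- d / H
  scale <- 1 / sqrt(dh)
  g <- list()
  gadd <- if (is.null(acc)) {
    function(nm, val) g[[nm]] <<- if (is.null(g[[nm]])) val else g[[nm]] + val
  } else {
    function(nm, val) acc$g[[nm]] <- acc$g[[nm]] + val
  }
  if (is.null(dX)) dX <- matrix(0, n, d)
  dq <- if (is.null(dqL)) array(0, c(n, n, H)) else dqL
  for (l in rev(seq_len(cfg$layers))) {
    pre <- sprintf("L%d.", l)
    lc <- cache$layers[[l]]
    # layernorm 2
    b2 <- layernorm_bwd(dX, lc$ln2, p[[paste0(pre, "ln2_g")]])
    gadd(paste0(pre, "ln2_g"), b2$dg); gadd(paste0(pre, "ln2_b"), b2$db)
    dx2pre <- b2$dx
    dX1 <- dx2pre
    dff <- dx2pre
    # ffn
    gadd(paste0(pre, "W2"), crossprod(lc$Hff, dff))
    gadd(paste0(pre, "b2"), colSums(dff))
    dHff <- tcrossprod(dff, p[[paste0(pre, "W2")]])
    dpre_act <- dHff * (lc$pre_act > 0)
    gadd(paste0(pre, "W1"), crossprod(lc$X1, dpre_act))
    gadd(paste0(pre, "b1"), colSums(dpre_act))
    dX1 <- dX1 + tcrossprod(dpre_act, p[[paste0(pre, "W1")]])
    # layernorm 1
    b1 <- layernorm_bwd(dX1, lc$ln1, p[[paste0(pre, "ln1_g")]])
    gadd(paste0(pre, "ln1_g"), b1$dg); gadd(paste0(pre, "ln1_b"), b1$db)
    dx1pre <- b1$dx
    dXin <- dx1pre          # residual into the block input
    dattn <- dx1pre
    # output projection
    gadd(paste0(pre, "Wo"), crossprod(lc$O, dattn))
    gadd(paste0(pre, "bo"), colSums(dattn))
    dO <- tcrossprod(dattn, p[[paste0(pre, "Wo")]])
    dQm <- matrix(0, n, d); dKm <- matrix(0, n, d); dVm <- matrix(0, n, d)
    dq_in <- array(0, c(n, n, H))
    for (h in seq_len(H)) {
      idx <- ((h - 1) * dh + 1):(h * dh)
      A_h <- lc$A[, , h]
      dO_h <- dO[, idx, drop = FALSE]
      dA_h <- tcrossprod(dO_h, lc$Vm[, idx, drop = FALSE])
      dVm[, idx] <- crossprod(A_h, dO_h)
      dlogits <- A_h * (dA_h - rowSums(dA_h * A_h))
      # pair tensor: bias path + pass-through of q_next = q + raw
      dq_in[, , h] <- dlogits + dq[, , h]
      draw <- dlogits + dq[, , h]      # raw feeds both logits and q_next
      dQm[, idx] <- draw %*% lc$Km[, idx, drop = FALSE] * scale
      dKm[, idx] <- crossprod(draw, lc$Qm[, idx, drop = FALSE]) * scale
    }
    gadd(paste0(pre, "Wq"), crossprod(lc$X, dQm))
    gadd(paste0(pre, "bq"), colSums(dQm))
    gadd(paste0(pre, "Wk"), crossprod(lc$X, dKm))
    gadd(paste0(pre, "bk"), colSums(dKm))
    gadd(paste0(pre, "Wv"), crossprod(lc$X, dVm))
    gadd(paste0(pre, "bv"), colSums(dVm))
    dXin <- dXin + tcrossprod(dQm, p[[paste0(pre, "Wq")]]) +
      tcrossprod(dKm, p[[paste0(pre, "Wk")]]) +
      tcrossprod(dVm, p[[paste0(pre, "Wv")]])
    dX <- dXin
    dq <- dq_in
  }
  if (!is.null(dq0_direct)) dq <- dq + dq0_direct
  # embedding
  dE <- matrix(0, nrow(p$embed), d)
  for (i in seq_len(n)) dE[cache$types[i], ] <- dE[cache$types[i], ] + dX[i, ]
  gadd("embed", dE)
  # pair initialisation
  dq_flat <- matrix(dq, n * n, H)
  gadd("rbf_w", crossprod(cache$rbf_flat, dq_flat))
  gadd("rbf_b", colSums(dq_flat))
  dbond <- matrix(0, 4, H)
  if (!is.null(cache$bond_code)) {
    for (k in seq_len(nrow(cache$bond_code))) {
      i <- cache$bond_code[k, 1]; j <- cache$bond_code[k, 2]
      t <- cache$bond_code[k, 3]
      dbond[t, ] <- dbond[t, ] + dq[i, j, ] + dq[j, i, ]
    }
  }
  gadd("bond_emb", dbond)
  if (is.null(acc)) g else invisible(NULL)
}

# mutable gradient accumulator shared across backward calls in one step
grad_acc <- function(model) {
  acc <- new.env(parent = emptyenv())
  acc$g <- zero_grads(model)
  acc
}

acc_add <- function(acc, g) {
  for (nm in names(g)) acc$g[[nm]] <- acc$g[[nm]] + g[[nm]]
  invisible(NULL)
}
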