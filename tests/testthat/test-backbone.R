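# Dual-track encoder: RBF coding, pair initialisation, attention +
# pair-update oracle equivalence, symmetry properties, heads, gradients.

test_that("rbf_encode matches the Gaussian kernel pointwise", {
  g <- c(0.5, 1, 2)
  sqd <- matrix(c(0, 1, 1, 4), 2, 2)
  f <- rbf_encode(sqd, g)
  expect_equal(f[1, 1, ], rep(1, 3))              # exp(0)
  expect_equal(f[1, 2, 2], exp(-1))
  expect_equal(f[2, 2, 3], exp(-8))
  expect_true(all(f > 0 & f <= 1))
  expect_error(rbf_encode(matrix(-1, 1, 1), g), "negative")
  # strictly decreasing in squared distance for every channel: points on a
  # line, distances from the first point strictly increase
  pos <- cumsum(with_seed(1, stats::runif(12, 0.2, 1)))
  sqd2 <- as.matrix(stats::dist(cbind(pos, 0, 0)))^2
  vals <- rbf_encode(sqd2, c(0.3, 2))
  expect_true(all(diff(vals[1, -1, 1]) < 0))
  expect_true(all(diff(vals[1, -1, 2]) < 0))
})

test_that("initial pair tensor = projected RBF plus bond embedding", {
  model <- tiny_model()
  coords <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(1.5, 1.5, 0))
  bonds <- data.frame(i = 1, j = 2, type = "double")
  q <- init_pair(model, coords, bonds)$q0
  # hand computation for the (1,3) unbonded pair
  d2 <- sum((coords[1, ] - coords[3, ])^2)
  hand <- as.numeric(exp(-d2 * model$config$rbf_gammas) %*%
                       model$params$rbf_w) + model$params$rbf_b
  expect_equal(q[1, 3, ], hand, tolerance = 1e-12)
  # bonded (1,2) differs from an equidistant unbonded pair by BondEmbed
  q_nb <- init_pair(model, coords, NULL)$q0
  expect_equal(q[1, 2, ] - q_nb[1, 2, ],
               as.numeric(model$params$bond_emb[2, ]))
  expect_equal(q[2, 1, ] - q_nb[2, 1, ],
               as.numeric(model$params$bond_emb[2, ]))
  # rigid transform leaves q0 unchanged
  tf <- random_rigid(4)
  q_tf <- init_pair(model, apply_rigid(coords, tf), bonds)$q0
  expect_lt(max(abs(q_tf - q)), 1e-6)
})

test_that("attention block and pair update match the nested-loop oracle", {
  model <- tiny_model(seed = 3)
  for (case in 1:3) {
    n <- 3 + case
    X <- with_seed(10 + case, matrix(stats::rnorm(n * 8), n, 8))
    q <- with_seed(20 + case, array(stats::rnorm(n * n * 2, sd = 0.3),
                                    c(n, n, 2)))
    fast <- attention_layer(model, X, q, layer = 1)
    oracle <- loop_attention_block(model, X, q, layer = 1)
    expect_lt(max(abs(fast - oracle$X)), 1e-6)
    # pair update: same raw logits, added to the incoming tensor
    p <- model$params
    Qm <- X %*% p$L1.Wq + matrix(p$L1.bq, n, 8, byrow = TRUE)
    Km <- X %*% p$L1.Wk + matrix(p$L1.bk, n, 8, byrow = TRUE)
    expect_lt(max(abs(pair_update(q, Qm, Km, 2) - oracle$q)), 1e-6)
  }
})

test_that("pair update with zero queries leaves the tensor unchanged", {
  q <- array(stats::rnorm(3 * 3 * 2), c(3, 3, 2))
  expect_equal(pair_update(q, matrix(0, 3, 8), matrix(1, 3, 8), 2), q)
})

test_that("attention with zero bias and identical keys is uniform; large
           negative bias removes a column", {
  model <- tiny_model(seed = 5)
  n <- 4
  # identical rows -> identical keys/queries -> uniform attention.  With
  # uniform weights every output row is identical.
  X <- matrix(1, n, 8)
  q0 <- array(0, c(n, n, 2))
  out_u <- attention_layer(model, X, q0, layer = 1)
  expect_lt(max(abs(sweep(out_u, 2, out_u[1, ]))), 1e-10)
  # -1e9 bias on column j: outputs equal those from a mask excluding j
  Xr <- with_seed(6, matrix(stats::rnorm(n * 8), n, 8))
  qb <- q0; qb[, 3, ] <- -1e9
  out_b <- attention_layer(model, Xr, qb, layer = 1)
  out_m <- attention_layer(model, Xr, q0, layer = 1,
                           mask = c(TRUE, TRUE, FALSE, TRUE))
  expect_lt(max(abs(out_b[-3, ] - out_m[-3, ])), 1e-9)
})

test_that("encoder is invariant and equivariant under rigid transforms", {
  model <- tiny_model(seed = 2)
  model$params$coord_W <- matrix(stats::rnorm(5, sd = 0.3), ncol = 1)
  spec <- small_spec(seed = 9)
  pair <- generate_complex(spec, 1)
  enc <- encode_joint(model, pair$pocket, pair$molecule)
  for (k in 1:5) {
    tf <- random_rigid(30 + k)
    enc_tf <- encode_joint(model, transform_graph(pair$pocket, tf),
                           transform_graph(pair$molecule, tf))
    expect_lt(max(abs(enc_tf$atom_reps - enc$atom_reps)), 1e-8)
    expect_lt(max(abs(enc_tf$pair_final - enc$pair_final)), 1e-8)
    ch <- coordinate_head(model, enc)$coords
    ch_tf <- coordinate_head(model, enc_tf)$coords
    expect_lt(max(abs(apply_rigid(ch, tf) - ch_tf)), 1e-8)
    expect_lt(max(abs(distance_head(model, enc) -
                        distance_head(model, enc_tf))), 1e-8)
  }
})

test_that("permuting real atoms permutes outputs; token embedding unchanged", {
  model <- tiny_model(seed = 4)
  spec <- small_spec(seed = 3)
  mol <- generate_complex(spec, 1)$molecule
  mol_cls <- insert_virtual_atom(mol, "CLS")
  enc <- encode_graph(model, mol_cls)
  perm <- c(3, 1, 4, 5, 2)
  mol_p <- mol
  mol_p$atom_types <- mol$atom_types[perm]
  mol_p$coords <- mol$coords[perm, ]
  inv <- order(perm)
  mol_p$bonds <- data.frame(i = inv[mol$bonds$i], j = inv[mol$bonds$j],
                            type = mol$bonds$type)
  enc_p <- encode_graph(model, insert_virtual_atom(mol_p, "CLS"))
  expect_lt(max(abs(enc_p$atom_reps[seq_along(perm), ] -
                      enc$atom_reps[perm, ])), 1e-9)
  expect_lt(max(abs(enc_p$cls_embedding[[1]] - enc$cls_embedding[[1]])),
            1e-9)
})

test_that("per-atom outputs are independent of batch composition", {
  model <- tiny_model(seed = 6)
  spec <- small_spec(seed = 5)
  g <- generate_complex(spec, 1)$molecule
  h <- generate_complex(spec, 2)$molecule
  solo <- encode_batch(model, batch_graphs(list(g), 8))[[1]]
  both <- encode_batch(model, batch_graphs(list(g, h), 8))[[1]]
  expect_lt(max(abs(solo$atom_reps - both$atom_reps)), 1e-5)
})

test_that("coordinate head: zero pair difference means identity, and the
           two-atom hand example holds", {
  model <- tiny_model(seed = 7)
  spec <- small_spec(seed = 2)
  pair <- generate_complex(spec, 1)
  # freshly initialised head has a zero output layer -> no movement
  enc <- encode_joint(model, pair$pocket, pair$molecule)
  expect_equal(coordinate_head(model, enc)$coords, enc$coords_in)
  # hand example: 2 atoms, c_12 = 1 fixed -> x1_hat = x1 + (x1 - x2)/2
  x <- rbind(c(0, 0, 0), c(2, 0, 0))
  fake <- list(pair_final = array(1, c(2, 2, 2)),
               pair_initial = array(0, c(2, 2, 2)),
               coords_in = x, real_flags = c(TRUE, TRUE),
               movable = c(TRUE, FALSE), atom_reps = matrix(0, 2, 8))
  m2 <- model
  # choose U, W so that c_ij = ReLU(sum over channels of D) = 2 here, except
  # c_ii = 0 because D_ii = 1 - 0 = 1 for the fake tensor as well; instead
  # set the diagonal difference to zero to honour c_ii's (x_i - x_i) = 0 term
  m2$params$coord_U <- matrix(0.5, 2, 5)
  m2$params$coord_W <- matrix(1 / 5, 5, 1)
  # c_ij = ReLU(D %*% U) %*% W = (2 channels * 0.5 * 1) = 1 for every pair
  out <- coordinate_head(m2, fake)$coords
  expect_equal(out[1, ], x[1, ] + (x[1, ] - x[2, ]) / 2)
  expect_equal(out[2, ], x[2, ])
})

test_that("distance head is symmetric, non-negative, zero-diagonal and
           matches a scalar-loop evaluation", {
  model <- tiny_model(seed = 8)
  model$params$dist_W2 <- matrix(stats::rnorm(5, sd = 0.5), ncol = 1)
  spec <- small_spec(seed = 11)
  pair <- generate_complex(spec, 1)
  enc <- encode_joint(model, pair$pocket, pair$molecule)
  dm <- distance_head(model, enc)
  expect_lt(max(abs(dm - t(dm))), 1e-6)
  expect_true(all(dm >= 0))
  expect_true(all(diag(dm) == 0))
  # scalar loop over a 4-atom corner of the pair tensor
  p <- model$params
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    s <- (enc$pair_final[i, j, ] + enc$pair_final[j, i, ]) / 2
    h1 <- pmax(as.numeric(s %*% p$dist_W1) + p$dist_b1, 0)
    z <- sum(h1 * p$dist_W2) + p$dist_b2
    expect_equal(dm[i, j], log1p(exp(z)), tolerance = 1e-6)
  }
})

test_that("hand-derived gradients match finite differences", {
  model <- tiny_model(seed = 12)
  model$params$coord_W <- matrix(stats::rnorm(5, sd = 0.2), ncol = 1)
  spec <- small_spec(seed = 13)
  pair <- generate_complex(spec, 1)
  loss_fn <- function(m) {
    enc <- encode_joint(m, pair$pocket, pair$molecule, keep_cache = TRUE)
    ch <- coordinate_head(m, enc, keep_cache = TRUE)
    pred <- ch$coords[enc$idx_mol_real, , drop = FALSE]
    li <- intra_loss(pred, pair$true_ligand_coords, delta = 1,
                     with_grads = TRUE)
    le <- inter_loss(pred, pair$true_ligand_coords, with_grads = TRUE)
    list(loss = li$loss + le$loss, enc = enc, ch = ch,
         dpred = li$d_pred + le$d_pred)
  }
  f0 <- loss_fn(model)
  dcoords <- matrix(0, nrow(f0$ch$coords), 3)
  dcoords[f0$enc$idx_mol_real, ] <- f0$dpred
  cb <- coordinate_head_bwd(model, f0$enc, f0$ch, dcoords)
  g <- grad_add(grad_add(zero_grads(model), cb$grads),
                encoder_bwd(model, f0$enc, NULL, dqL = cb$dqL,
                            dq0_direct = cb$dq0))
  eps <- 1e-5
  for (nm in c("embed", "rbf_w", "bond_emb", "L1.Wq", "L1.Wv", "L2.Wk",
               "L1.ln1_g", "L1.W1", "coord_U", "coord_W")) {
    for (idx in unique(c(1L, length(model$params[[nm]])))) {
      m2 <- model; m2$params[[nm]][idx] <- m2$params[[nm]][idx] + eps
      m3 <- model; m3$params[[nm]][idx] <- m3$params[[nm]][idx] - eps
      fd <- (loss_fn(m2)$loss - loss_fn(m3)$loss) / (2 * eps)
      expect_equal(g[[nm]][idx], fd, tolerance = 1e-4,
                   label = paste("grad", nm, idx))
    }
  }
})

test_that("encoder rejects oversize inputs and NaN logits fail fast", {
  model <- new_model(tiny_config(max_atoms = 4L), seed = 1)
  spec <- small_spec(seed = 1)
  pair <- generate_complex(spec, 1)
  expect_error(encode_graph(model, pair$pocket), "max_atoms")
})
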