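# The three objectives: similarity bounds, contrastive closed forms and
# oracle, hard-negative mining, matching, Huber/docking losses, composition.

test_that("similarity is a cosine in [-1, 1] with exact endpoints", {
  model <- tiny_model(seed = 1)
  d <- model$config$atom_dim
  # parallel projections -> 1
  v <- with_seed(2, stats::rnorm(d))
  expect_equal(similarity(model, v, v * 0 + v), {
    p <- model$params
    zP <- as.numeric(v %*% p$gP) + p$gP_b
    zM <- as.numeric(v %*% p$gM) + p$gM_b
    sum(zP * zM) / sqrt(sum(zP^2) * sum(zM^2))
  })
  # orthogonal projections -> 0: engineer via parameter surgery
  m2 <- model
  k <- model$config$proj_dim
  m2$params$gP <- cbind(matrix(1, d, 1), matrix(0, d, k - 1))
  m2$params$gP_b <- rep(0, k)
  m2$params$gM <- cbind(matrix(0, d, 1), matrix(1, d, 1),
                        matrix(0, d, k - 2))
  m2$params$gM_b <- rep(0, k)
  expect_equal(similarity(m2, rep(1, d), rep(1, d)), 0)
  # bound sweep
  sims <- vapply(1:200, function(k) {
    vs <- with_seed(100 + k, stats::rnorm(2 * d, sd = 3))
    similarity(model, vs[1:d], vs[-(1:d)])
  }, numeric(1))
  expect_true(all(sims >= -1 - 1e-12 & sims <= 1 + 1e-12))
})

test_that("contrastive loss closed forms: N = 1 gives 0, uniform gives ln N", {
  model <- tiny_model(seed = 2)
  d <- model$config$atom_dim
  one <- matrix(with_seed(1, stats::rnorm(d)), 1)
  expect_equal(contrastive_loss(model, one, one)$loss, 0, tolerance = 1e-10)
  # identical rows -> all similarities equal -> uniform softmax -> ln 4
  cls <- matrix(rep(with_seed(2, stats::rnorm(d)), each = 4), 4)
  expect_equal(contrastive_loss(model, cls, cls)$loss, log(4),
               tolerance = 1e-9)
})

test_that("contrastive loss matches a scalar-loop softmax-CE oracle", {
  # engineer a model whose similarity matrix is a hand-specified 3x3:
  # use identity-like projections on 3-dim one-hot embeddings
  model <- tiny_model(seed = 3)
  model$params$log_tau <- log(1)  # tau = 1
  S_target <- matrix(c(0.9, 0.1, -0.3,
                       0.2, 0.8, 0.0,
                       -0.5, 0.4, 0.6), 3, 3, byrow = TRUE)
  # loop oracle on the actual similarity matrix produced by the model
  cls_P <- with_seed(4, matrix(stats::rnorm(3 * 8), 3))
  cls_M <- with_seed(5, matrix(stats::rnorm(3 * 8), 3))
  res <- contrastive_loss(model, cls_P, cls_M)
  S <- res$S
  ce <- function(target_idx, logits) {
    p <- exp(logits - max(logits)); p <- p / sum(p)
    -log(p[target_idx])
  }
  hand <- 0
  for (i in 1:3) hand <- hand + ce(i, S[i, ]) / 6 + ce(i, S[, i]) / 6
  expect_equal(res$loss, hand, tolerance = 1e-6)
  # and on the hand-specified matrix directly (tau = 1): loop vs formula
  hand2 <- 0
  for (i in 1:3) hand2 <- hand2 + ce(i, S_target[i, ]) / 6 +
    ce(i, S_target[, i]) / 6
  expect_equal(hand2, 0.5 * (mean(-log(diag(softmax_rows(S_target)))) +
                               mean(-log(diag(softmax_rows(t(S_target)))))),
               tolerance = 1e-9)
})

test_that("contrastive loss is permutation-invariant and decreases when the
           diagonal strengthens", {
  model <- tiny_model(seed = 6)
  cls_P <- with_seed(7, matrix(stats::rnorm(4 * 8), 4))
  cls_M <- with_seed(8, matrix(stats::rnorm(4 * 8), 4))
  base <- contrastive_loss(model, cls_P, cls_M)$loss
  perm <- c(3, 1, 4, 2)
  expect_equal(contrastive_loss(model, cls_P[perm, ], cls_M[perm, ])$loss,
               base, tolerance = 1e-10)
  # exact similarity control: identity projections, cls_P rows are basis
  # vectors, cls_M rows carry the desired dot products plus a norm-fixing
  # component, so S is hand-specified and off-diagonals stay fixed while the
  # diagonal is strengthened
  d <- 8; k <- 6
  mid <- tiny_model(seed = 1)
  mid$params$gP <- rbind(diag(k), matrix(0, d - k, k)); mid$params$gP_b[] <- 0
  mid$params$gM <- rbind(diag(k), matrix(0, d - k, k)); mid$params$gM_b[] <- 0
  make_cls <- function(S) {
    cls_P <- cbind(diag(3), matrix(0, 3, d - 3))
    cls_M <- t(vapply(1:3, function(j) {
      v <- c(S[, j], sqrt(1 - sum(S[, j]^2)), 0, 0, 0, 0)
      v
    }, numeric(d)))
    list(P = cls_P, M = cls_M)
  }
  S0 <- matrix(c(0.5, 0.1, -0.2,
                 0.0, 0.4, 0.3,
                 0.2, -0.1, 0.6), 3, 3, byrow = TRUE)
  c0 <- make_cls(S0)
  expect_equal(similarity_matrix(mid, c0$P, c0$M), S0, tolerance = 1e-9)
  l0 <- contrastive_loss(mid, c0$P, c0$M)$loss
  c1 <- make_cls(S0 + diag(0.15, 3))
  expect_lt(contrastive_loss(mid, c1$P, c1$M)$loss, l0)
  c2 <- make_cls(S0 - diag(0.15, 3))
  expect_gt(contrastive_loss(mid, c2$P, c2$M)$loss, l0)
})

test_that("hard-negative mining excludes the diagonal and honours argmax", {
  S <- matrix(c(0.9, 0.8, 0.1,
                0.2, 0.9, 0.7,
                0.6, 0.3, 0.9), 3, 3, byrow = TRUE)
  neg <- mine_hard_negatives(S, seed = 1, strategy = "argmax")
  p2m <- neg[neg$direction == "p2m", ]
  expect_equal(p2m$molecule, c(2L, 3L, 1L))   # largest off-diagonal per row
  m2p <- neg[neg$direction == "m2p", ]
  expect_equal(m2p$pocket, c(3L, 1L, 2L))     # largest off-diagonal per col
  expect_true(all(neg$pocket != neg$molecule))
  # sampling never returns the diagonal and is seed-deterministic
  for (k in 1:50) {
    Sk <- with_seed(k, matrix(stats::rnorm(16), 4))
    nk <- mine_hard_negatives(Sk, seed = k)
    expect_true(all(nk$pocket != nk$molecule))
    expect_identical(nk, mine_hard_negatives(Sk, seed = k))
  }
  expect_equal(nrow(mine_hard_negatives(matrix(1, 1, 1), 1)), 0)
})

test_that("matching loss closed forms and loop oracle", {
  expect_lt(matching_loss(matrix(c(-20, 20), 1), 1)$loss, 1e-8)
  expect_equal(matching_loss(matrix(0, 3, 2), c(0, 1, 1))$loss, log(2),
               tolerance = 1e-12)
  logits <- with_seed(9, matrix(stats::rnorm(8), 4))
  labels <- c(1, 0, 1, 0)
  hand <- mean(vapply(1:4, function(i) {
    p <- exp(logits[i, ] - max(logits[i, ]))
    p <- p / sum(p)
    -log(p[labels[i] + 1])
  }, numeric(1)))
  expect_equal(matching_loss(logits, labels)$loss, hand, tolerance = 1e-6)
  expect_error(matching_loss(logits, c(1, 2, 0, 0)), "0 or 1")
})

test_that("Huber function: branch values, continuity and C1 joint", {
  expect_equal(huber(0.5, 1), 0.125)
  expect_equal(huber(3, 1), 2.5)
  expect_equal(huber(-3, 1), 2.5)
  # both branches give delta^2/2 at |a| = delta
  expect_equal(huber(1, 1), 0.5)
  expect_equal(1 * (1 - 0.5), 0.5)
  eps <- 1e-7
  expect_equal(huber(1 + eps, 1) - huber(1 - eps, 1), 2 * eps,
               tolerance = 1e-6)
})

test_that("intra loss: exact single-pair values and loop oracle", {
  a <- rbind(c(0, 0, 0), c(1, 0, 0))
  b <- rbind(c(0, 0, 0), c(1.5, 0, 0))   # |d - d*| = 0.5
  expect_equal(intra_loss(a, b, delta = 1)$loss, 0.125)
  b2 <- rbind(c(0, 0, 0), c(4, 0, 0))    # |d - d*| = 3
  expect_equal(intra_loss(a, b2, delta = 1)$loss, 2.5)
  expect_equal(intra_loss(a, a)$loss, 0)
  expect_warning(l1 <- intra_loss(matrix(0, 1, 3), matrix(0, 1, 3)),
                 ">= 2")
  expect_equal(l1$loss, 0)
  # loop oracle on a 6-atom instance
  p6 <- with_seed(11, matrix(stats::rnorm(18), 6))
  t6 <- with_seed(12, matrix(stats::rnorm(18), 6))
  hand <- local({
    acc <- 0; m <- 0
    for (i in 1:5) for (j in (i + 1):6) {
      dd <- sqrt(sum((p6[i, ] - p6[j, ])^2)) -
        sqrt(sum((t6[i, ] - t6[j, ])^2))
      acc <- acc + huber(dd, 1); m <- m + 1
    }
    acc / m
  })
  expect_equal(intra_loss(p6, t6, delta = 1)$loss, hand, tolerance = 1e-6)
  # gradient agrees with finite differences
  g <- intra_loss(p6, t6, delta = 1, with_grads = TRUE)$d_pred
  eps <- 1e-6
  for (idx in c(1, 7, 18)) {
    p2 <- p6; p2[idx] <- p2[idx] + eps
    p3 <- p6; p3[idx] <- p3[idx] - eps
    fd <- (intra_loss(p2, t6, 1)$loss - intra_loss(p3, t6, 1)$loss) / (2 * eps)
    expect_equal(g[idx], fd, tolerance = 1e-4)
  }
})

test_that("inter loss: exact values and loop oracle", {
  a <- matrix(c(1, 0, 0), 1)
  expect_equal(inter_loss(a, matrix(0, 1, 3))$loss, 1.0)
  expect_equal(inter_loss(a, a)$loss, 0)
  p6 <- with_seed(13, matrix(stats::rnorm(18), 6))
  t6 <- with_seed(14, matrix(stats::rnorm(18), 6))
  hand <- mean(vapply(1:6, function(i) sum((p6[i, ] - t6[i, ])^2),
                      numeric(1)))
  expect_equal(inter_loss(p6, t6)$loss, hand, tolerance = 1e-9)
  expect_error(inter_loss(p6, t6[1:3, ]), "mismatch")
})

test_that("total loss is the exact unit-weight sum and rejects non-finite
           components", {
  expect_equal(total_loss(0, 0, 0, 0)$total, 0)
  expect_equal(total_loss(1, 2, 3, 4)$total, 10)
  for (k in 1:100) {
    v <- with_seed(200 + k, stats::runif(4, 0, 10))
    rep <- total_loss(v[1], v[2], v[3], v[4])
    expect_identical(rep$total, v[1] + v[2] + v[3] + v[4])
  }
  expect_error(total_loss(NaN, 0, 0, 0), "l_pmc")
})

test_that("losses are invariant under joint rigid transforms, and the
           contrastive side under independent ones", {
  model <- tiny_model(seed = 15)
  model$params$coord_W <- matrix(stats::rnorm(5, sd = 0.2), ncol = 1)
  spec <- small_spec(seed = 16)
  pairs <- lapply(1:3, function(i) generate_complex(spec, i))
  enc_cls <- function(ps, tfP = NULL, tfM = NULL) {
    cls_P <- do.call(rbind, lapply(ps, function(p) {
      g <- ensure_token(p$pocket, "CLS")
      if (!is.null(tfP)) g <- transform_graph(g, tfP)
      encode_graph(model, g)$cls_embedding[["[CLS:pocket]"]]
    }))
    cls_M <- do.call(rbind, lapply(ps, function(p) {
      g <- ensure_token(p$molecule, "CLS")
      if (!is.null(tfM)) g <- transform_graph(g, tfM)
      encode_graph(model, g)$cls_embedding[["[CLS:molecule]"]]
    }))
    contrastive_loss(model, cls_P, cls_M)$loss
  }
  tfA <- random_rigid(21); tfB <- random_rigid(22)
  base <- enc_cls(pairs)
  expect_equal(enc_cls(pairs, tfA, tfA), base, tolerance = 1e-7)
  # independent transforms of pocket and molecule (separate passes)
  expect_equal(enc_cls(pairs, tfA, tfB), base, tolerance = 1e-7)
  # docking losses under a joint transform of pocket, ligand and truth
  pair <- pairs[[1]]
  dockl <- function(pk, ml, truth) {
    enc <- encode_joint(model, pk, ml)
    ch <- coordinate_head(model, enc)
    pred <- ch$coords[enc$idx_mol_real, , drop = FALSE]
    c(intra_loss(pred, truth, 1)$loss, inter_loss(pred, truth)$loss)
  }
  base_d <- dockl(pair$pocket, pair$molecule, pair$true_ligand_coords)
  tf_d <- dockl(transform_graph(pair$pocket, tfA),
                transform_graph(pair$molecule, tfA),
                apply_rigid(pair$true_ligand_coords, tfA))
  expect_equal(tf_d, base_d, tolerance = 1e-7)
})
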