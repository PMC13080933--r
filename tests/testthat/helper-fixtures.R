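# Shared fixtures: tiny SDF / PDB texts built in code, small model configs,
# and rigid-transform helpers.

sdf_atom_line <- function(x, y, z, el) {
  sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
          x, y, z, el)
}

sdf_bond_line <- function(i, j, t) sprintf("%3d%3d%3d  0", i, j, t)

# a 5-heavy-atom branched molecule (neopentane-like skeleton): C(C)(C)(C)C
write_branched_sdf <- function(path, title = "branched5") {
  lines <- c(
    title, "  test                  3D", "",
    " 5 4  0  0  0  0  0  0  0  0999 V2000",
    sdf_atom_line(0, 0, 0, "C"),
    sdf_atom_line(1.54, 0, 0, "C"),
    sdf_atom_line(-0.51, 1.45, 0, "C"),
    sdf_atom_line(-0.51, -0.73, 1.26, "N"),
    sdf_atom_line(-0.51, -0.73, -1.26, "O"),
    sdf_bond_line(1, 2, 1), sdf_bond_line(1, 3, 1),
    sdf_bond_line(1, 4, 1), sdf_bond_line(1, 5, 1),
    "M  END", "$$$$")
  writeLines(lines, path)
  path
}

# 6-membered aromatic ring
write_aromatic_sdf <- function(path) {
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  at <- vapply(seq_len(6), function(k)
    sdf_atom_line(1.39 * cos(ang[k]), 1.39 * sin(ang[k]), 0.01 * k, "C"),
    character(1))
  bd <- vapply(seq_len(6), function(k)
    sdf_bond_line(k, (k %% 6) + 1, 4), character(1))
  writeLines(c("ring6", "  test                  3D", "",
               " 6 6  0  0  0  0  0  0  0  0999 V2000", at, bd,
               "M  END", "$$$$"), path)
  path
}

pdb_atom_line <- function(serial, name, resname, chain, resno, xyz,
                          occ = 1.0, elem = substr(name, 1, 1), alt = " ") {
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resname, chain, resno,
          xyz[1], xyz[2], xyz[3], occ, 0, elem)
}

# three-residue synthetic peptide-like PDB: residue centres at given
# distances from the origin
write_three_residue_pdb <- function(path, d = c(2, 4.8, 8)) {
  lines <- character(0); serial <- 0
  for (r in seq_along(d)) {
    base <- c(d[r], 0, 0)
    for (k in 1:3) {
      serial <- serial + 1
      lines <- c(lines, pdb_atom_line(serial, c("N", "CA", "C")[k], "GLY",
                                      "A", r, base + c(0, 0.6 * (k - 2), 0)))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

tiny_config <- function(...) {
  args <- list(layers = 2, heads = 2, atom_dim = 8, rbf_kernels = 4,
               ffn_dim = 12, proj_dim = 6, coord_hidden = 5,
               dist_hidden = 5)
  over <- list(...)
  args[names(over)] <- over
  do.call(backbone_config, args)
}

tiny_model <- function(seed = 1, ...) new_model(tiny_config(...), seed = seed)

small_spec <- function(seed = 1, ...) {
  synthetic_spec(n_pocket_atoms = 10, n_ligand_atoms = 5, seed = seed, ...)
}

random_rigid <- function(seed) {
  with_seed(seed, {
    R <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    list(R = R, t = stats::rnorm(3, sd = 5))
  })
}

apply_rigid <- function(X, tf) sweep(X %*% t(tf$R), 2, -tf$t)

transform_graph <- function(g, tf) {
  g$coords <- apply_rigid(g$coords, tf)
  g
}

# scalar nested-loop re-implementation of one transformer block (the
# independent oracle for attention + pair update)
loop_attention_block <- function(model, X, q, layer = 1) {
  p <- model$params; cfg <- model$config
  pre <- sprintf("L%d.", layer)
  n <- nrow(X); d <- cfg$atom_dim; H <- cfg$heads; dh <- d / H
  lin <- function(x, W, b) as.numeric(x %*% W) + b
  Qm <- t(vapply(seq_len(n), function(i)
    lin(X[i, , drop = FALSE], p[[paste0(pre, "Wq")]], p[[paste0(pre, "bq")]]),
    numeric(d)))
  Km <- t(vapply(seq_len(n), function(i)
    lin(X[i, , drop = FALSE], p[[paste0(pre, "Wk")]], p[[paste0(pre, "bk")]]),
    numeric(d)))
  Vm <- t(vapply(seq_len(n), function(i)
    lin(X[i, , drop = FALSE], p[[paste0(pre, "Wv")]], p[[paste0(pre, "bv")]]),
    numeric(d)))
  O <- matrix(0, n, d)
  q_out <- q
  for (h in seq_len(H)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    for (i in seq_len(n)) {
      logits <- numeric(n)
      for (j in seq_len(n)) {
        raw <- sum(Qm[i, idx] * Km[j, idx]) / sqrt(dh)
        logits[j] <- raw + q[i, j, h]
        q_out[i, j, h] <- q[i, j, h] + raw
      }
      w <- exp(logits - max(logits)); w <- w / sum(w)
      for (c in seq_along(idx)) O[i, idx[c]] <- sum(w * Vm[, idx[c]])
    }
  }
  att <- t(vapply(seq_len(n), function(i)
    lin(O[i, , drop = FALSE], p[[paste0(pre, "Wo")]], p[[paste0(pre, "bo")]]),
    numeric(d)))
  ln <- function(x, g, b) {
    mu <- mean(x); v <- mean((x - mu)^2)
    g * (x - mu) / sqrt(v + 1e-5) + b
  }
  X1 <- t(vapply(seq_len(n), function(i)
    ln(X[i, ] + att[i, ], p[[paste0(pre, "ln1_g")]], p[[paste0(pre, "ln1_b")]]),
    numeric(d)))
  ff <- t(vapply(seq_len(n), function(i) {
    h1 <- pmax(lin(X1[i, , drop = FALSE], p[[paste0(pre, "W1")]],
                   p[[paste0(pre, "b1")]]), 0)
    lin(matrix(h1, 1), p[[paste0(pre, "W2")]], p[[paste0(pre, "b2")]])
  }, numeric(d)))
  X2 <- t(vapply(seq_len(n), function(i)
    ln(X1[i, ] + ff[i, ], p[[paste0(pre, "ln2_g")]], p[[paste0(pre, "ln2_b")]]),
    numeric(d)))
  list(X = X2, q = q_out)
}
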