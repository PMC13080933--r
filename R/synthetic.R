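# Seeded lock-and-key complex generator.  Pockets are partial spherical
# shells of typed atoms; ligands are self-avoiding chains grown inside the
# cavity; matched pairs carry geometric + type complementarity (each ligand
# atom's element is a fixed permutation of its nearest pocket atom's
# element).  Everything is a pure function of (spec, seed, call sequence).

#' Synthetic complex specification
#'
#' @param n_pocket_atoms pocket shell size (>= 3).
#' @param n_ligand_atoms ligand chain length (>= 3).
#' @param cavity_radius radius (Angstrom) inside which the ligand is grown.
#' @param shell_radius pocket shell radius (> cavity_radius).
#' @param type_vocab_size number of element types drawn from C,N,O,S,P,F.
#' @param complementarity_map permutation of `1:type_vocab_size`; ligand atom
#'   types are this map applied to the nearest pocket atom's type.  Defaults
#'   to the cyclic shift, a fixed derangement.
#' @param coord_noise_sigma Gaussian jitter (Angstrom) added to all
#'   coordinates after type assignment.
#' @param seed integer base seed recorded in every manifest.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_pocket_atoms = 48L, n_ligand_atoms = 12L,
                           cavity_radius = 4, shell_radius = 7,
                           type_vocab_size = 6L,
                           complementarity_map = NULL,
                           coord_noise_sigma = 0.1, seed = 1L) {
  stopifnot(shell_radius > cavity_radius, cavity_radius > 0,
            n_pocket_atoms >= 3, n_ligand_atoms >= 3,
            coord_noise_sigma >= 0,
            type_vocab_size >= 2, type_vocab_size <= 6)
  if (is.null(complementarity_map))
    complementarity_map <- c(seq_len(type_vocab_size)[-1], 1L)
  stopifnot(length(complementarity_map) == type_vocab_size,
            all(sort(complementarity_map) == seq_len(type_vocab_size)))
  structure(list(n_pocket_atoms = as.integer(n_pocket_atoms),
                 n_ligand_atoms = as.integer(n_ligand_atoms),
                 cavity_radius = cavity_radius, shell_radius = shell_radius,
                 type_vocab_size = as.integer(type_vocab_size),
                 complementarity_map = as.integer(complementarity_map),
                 coord_noise_sigma = coord_noise_sigma,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

synthetic_elements <- function(spec) {
  c("C", "N", "O", "S", "P", "F")[seq_len(spec$type_vocab_size)]
}

# uniformly random unit vector
runif_sphere <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Generate one matched pocket-ligand complex
#'
#' Pocket atoms are sampled on a partial spherical shell (polar cap opening
#' left free) at `shell_radius`; the ligand grows as a self-avoiding chain of
#' 1.5-Angstrom steps inside the cavity; ligand types complement the nearest
#' pocket atom's type; Gaussian jitter of `coord_noise_sigma` is then applied
#' to all coordinates.  Output is bit-identical for identical (spec, index).
#'
#' @param spec a [synthetic_spec()].
#' @param index complex index; (spec$seed, index) determine the draw.
#' @return A [complex_pair()] with `match_label = 1` and the true pose.
#' @export
generate_complex <- function(spec, index = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(derive_seed(spec$seed, 101L, index), {
    elems <- synthetic_elements(spec)
    # pocket: partial shell, polar angle in [40, 180] degrees so the top is
    # an opening (a mouth), radius jittered a little
    np <- spec$n_pocket_atoms
    u <- stats::runif(np, min = cos(pi), max = cos(40 / 180 * pi))
    phi <- stats::runif(np, 0, 2 * pi)
    st <- sqrt(pmax(1 - u^2, 0))
    r <- spec$shell_radius + stats::rnorm(np, sd = 0.15)
    pk <- cbind(r * st * cos(phi), r * st * sin(phi), r * u)
    pk_types_code <- sample.int(spec$type_vocab_size, np, replace = TRUE)
    # ligand: self-avoiding chain, 1.5 A steps, inside the cavity
    nl <- spec$n_ligand_atoms
    step <- 1.5; min_sep <- 1.2
    lig <- matrix(NA_real_, nl, 3)
    lig[1, ] <- runif_sphere() * stats::runif(1, 0, spec$cavity_radius / 3)
    for (k in 2:nl) {
      placed <- FALSE
      for (try in 1:200) {
        cand <- lig[k - 1, ] + runif_sphere() * step
        if (sqrt(sum(cand^2)) >= spec$cavity_radius) next
        if (k > 2) {
          d <- sqrt(rowSums(sweep(lig[1:(k - 2), , drop = FALSE], 2,
                                  cand)^2))
          if (min(d) < min_sep) next
        }
        lig[k, ] <- cand; placed <- TRUE; break
      }
      if (!placed)
        stop("cannot fit ligand chain in cavity; increase cavity_radius")
    }
    # complementary types from nearest pocket atom
    lig_types_code <- vapply(seq_len(nl), function(k) {
      j <- which.min(rowSums(sweep(pk, 2, lig[k, ])^2))
      spec$complementarity_map[pk_types_code[j]]
    }, 1L)
    # jitter
    if (spec$coord_noise_sigma > 0) {
      pk <- pk + matrix(stats::rnorm(length(pk), sd = spec$coord_noise_sigma),
                        nrow(pk), 3)
      lig <- lig + matrix(stats::rnorm(length(lig),
                                       sd = spec$coord_noise_sigma),
                          nrow(lig), 3)
    }
    bonds <- if (nl >= 2)
      data.frame(i = 1:(nl - 1), j = 2:nl, type = "single",
                 stringsAsFactors = FALSE) else NULL
    rid <- paste0("A|", rep(seq_len(ceiling(np / 4)), each = 4)[seq_len(np)],
                  "|")
    pocket <- atom_graph("pocket", elems[pk_types_code], pk,
                         source_id = sprintf("synthpocket-%d-%d",
                                             spec$seed, index),
                         residue_ids = rid)
    molecule <- atom_graph("molecule", elems[lig_types_code], lig, bonds,
                           source_id = sprintf("synthlig-%d-%d",
                                               spec$seed, index))
    complex_pair(pocket, molecule, 1L, true_ligand_coords = lig,
                 pair_id = sprintf("synth-%d-%d", spec$seed, index))
  })
}

#' Build a mismatched (negative) pair
#'
#' Takes the pocket of `a` and the ligand of `b`, recentres the ligand at the
#' position of `a`'s own ligand, and labels the pair unmatched.  No true pose
#' is attached.
#'
#' @param a,b two distinct [complex_pair()]s.
#' @return A `complex_pair` with `match_label = 0`.
#' @export
make_negative_pair <- function(a, b) {
  if (identical(a$pair_id, b$pair_id))
    stop("negative pair needs two distinct source complexes")
  mol <- b$molecule
  keep <- !mol$virtual_flags
  target <- colMeans(real_coords(a$molecule))
  shift <- target - colMeans(mol$coords[keep, , drop = FALSE])
  mol$coords <- sweep(mol$coords, 2, -shift)
  complex_pair(a$pocket, mol, 0L,
               pair_id = paste0(a$pair_id, "|neg|", b$pair_id))
}

#' Generate a decoy pose at a controlled RMSD
#'
#' Applies a random rigid transform (rotation about the ligand centroid plus
#' a translation), scaled by bisection so that the plain coordinate RMSD to
#' the true pose lands within 10% of `rmsd_target` (exactly 0 for target 0).
#' Optional Gaussian jitter can be added before rescaling.
#'
#' @param pair a [complex_pair()] with a true pose.
#' @param rmsd_target desired RMSD in Angstrom (>= 0).
#' @param seed integer seed.
#' @param jitter_sigma per-atom Gaussian noise (Angstrom) applied with the
#'   transform (0 keeps the decoy rigid).
#' @return n x 3 matrix of decoy coordinates with attribute
#'   `achieved_rmsd`.
#' @export
make_decoy_pose <- function(pair, rmsd_target, seed = 1L, jitter_sigma = 0) {
  if (is.null(pair$true_ligand_coords)) stop("pair has no true pose")
  stopifnot(rmsd_target >= 0)
  X <- pair$true_ligand_coords
  if (rmsd_target == 0) {
    out <- X
    attr(out, "achieved_rmsd") <- 0
    return(out)
  }
  with_seed(derive_seed(seed, 211L), {
    ctr <- colMeans(X)
    Rfull <- random_rotation()
    axis_angle <- stats::runif(1, 0.3, pi)
    tdir <- runif_sphere()
    tmag <- max(rmsd_target * 1.5, 1)
    J <- if (jitter_sigma > 0)
      matrix(stats::rnorm(length(X), sd = jitter_sigma), nrow(X), 3)
    else matrix(0, nrow(X), 3)
    pose_at <- function(s) {
      # interpolate rotation by fractional power via angle scaling:
      # R(s) = exp(s * log(Rfull)) approximated with rotation about the same
      # axis; use simple linear blend + re-orthogonalisation for robustness
      Rs <- rotation_fraction(Rfull, s)
      sweep(sweep(X, 2, ctr) %*% t(Rs), 2, -ctr) +
        matrix(tdir * tmag * s, nrow(X), 3, byrow = TRUE) + J * s
    }
    f <- function(s) rmsd(pose_at(s), X) - rmsd_target
    lo <- 0; hi <- 1
    while (f(hi) < 0 && hi < 64) hi <- hi * 2
    if (f(hi) < 0) {
      warning("decoy RMSD target unreachable; returning best effort")
      out <- pose_at(hi)
      attr(out, "achieved_rmsd") <- rmsd(out, X)
      return(out)
    }
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    out <- pose_at((lo + hi) / 2)
    attr(out, "achieved_rmsd") <- rmsd(out, X)
    out
  })
}

# fractional rotation: scale the angle of R about its axis by s
rotation_fraction <- function(R, s) {
  tr <- (sum(diag(R)) - 1) / 2
  tr <- min(1, max(-1, tr))
  theta <- acos(tr)
  if (theta < 1e-8) return(diag(3))
  w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(theta))
  th <- theta * s
  K <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Generate a full synthetic dataset with screening libraries
#'
#' Produces `n_complexes` matched pairs plus, per pocket, a screening library
#' of `actives_per_pocket` complementary ligands and `decoys_per_pocket`
#' ligands generated against other pockets, written as JSON lines with a
#' JSON manifest recording the spec, seed, counts and file digests.
#'
#' @param spec a [synthetic_spec()].
#' @param n_complexes number of matched complexes (>= 2).
#' @param actives_per_pocket,decoys_per_pocket library sizes per pocket.
#' @param dir output directory (created if needed).
#' @return The manifest, invisibly; files `pairs.jsonl`, `library.jsonl` and
#'   `manifest.json` are written under `dir`.
#' @export
generate_dataset <- function(spec, n_complexes, actives_per_pocket = 1L,
                             decoys_per_pocket = 1L, dir) {
  stopifnot(n_complexes >= 2, actives_per_pocket >= 1, decoys_per_pocket >= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pairs <- lapply(seq_len(n_complexes), function(i)
    generate_complex(spec, index = i))
  pairs_path <- file.path(dir, "pairs.jsonl")
  write_pairs(pairs, pairs_path)
  lib <- list()
  for (i in seq_len(n_complexes)) {
    for (a in seq_len(actives_per_pocket)) {
      # extra actives: fresh complementary ligands grown in the same pocket
      extra <- generate_complex(spec, index = derive_seed(i, 7L, a) %% 100000L
                                + 100000L * i)
      act <- complex_pair(pairs[[i]]$pocket,
                          if (a == 1) pairs[[i]]$molecule else
                            make_negative_pair(pairs[[i]], extra)$molecule,
                          1L,
                          true_ligand_coords = if (a == 1)
                            pairs[[i]]$true_ligand_coords else NULL,
                          pair_id = sprintf("lib-%d-active-%d", i, a))
      if (a > 1) {
        # re-type the transplanted ligand so it complements THIS pocket
        act <- retype_complementary(act, spec)
      }
      lib[[length(lib) + 1L]] <- act
    }
    for (dcy in seq_len(decoys_per_pocket)) {
      j <- ((i - 1 + dcy) %% n_complexes) + 1
      neg <- make_negative_pair(pairs[[i]], pairs[[j]])
      neg$pair_id <- sprintf("lib-%d-decoy-%d", i, dcy)
      lib[[length(lib) + 1L]] <- neg
    }
  }
  lib_path <- file.path(dir, "library.jsonl")
  write_pairs(lib, lib_path)
  manifest <- list(
    spec = unclass(spec), seed = spec$seed,
    n_complexes = n_complexes,
    actives_per_pocket = actives_per_pocket,
    decoys_per_pocket = decoys_per_pocket,
    digests = list(pairs = unname(tools::md5sum(pairs_path)),
                   library = unname(tools::md5sum(lib_path))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# reassign ligand types as complementarity_map(nearest pocket type)
retype_complementary <- function(pair, spec) {
  elems <- synthetic_elements(spec)
  pk <- real_coords(pair$pocket)
  pk_codes <- match(pair$pocket$atom_types[!pair$pocket$virtual_flags], elems)
  mol <- pair$molecule
  keep <- which(!mol$virtual_flags)
  for (k in keep) {
    j <- which.min(rowSums(sweep(pk, 2, mol$coords[k, ])^2))
    mol$atom_types[k] <- elems[spec$complementarity_map[pk_codes[j]]]
  }
  pair$molecule <- mol
  pair
}

#' Nearest-neighbour complementarity score
#'
#' The hand-coded oracle the generator plants in the data: the fraction of
#' ligand atoms whose element equals the complementarity map applied to their
#' nearest pocket atom's element.  Used to verify that matched pairs carry a
#' detectable signal that mismatched pairs lack.
#'
#' @param pair a [complex_pair()].
#' @param spec the generating [synthetic_spec()].
#' @return Fraction in [0, 1].
#' @export
complementarity_fraction <- function(pair, spec) {
  elems <- synthetic_elements(spec)
  pk <- real_coords(pair$pocket)
  pk_codes <- match(pair$pocket$atom_types[!pair$pocket$virtual_flags], elems)
  mol <- pair$molecule
  keep <- which(!mol$virtual_flags)
  hits <- vapply(keep, function(k) {
    j <- which.min(rowSums(sweep(pk, 2, mol$coords[k, ])^2))
    expected <- elems[spec$complementarity_map[pk_codes[j]]]
    identical(mol$atom_types[k], expected)
  }, logical(1))
  mean(hits)
}
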