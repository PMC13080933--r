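#' Backbone configuration
#'
#' Collects every architectural constant of the dual-track encoder.  The pair
#' track has one channel per attention head, because the pair tensor is added
#' directly inside each head's softmax and receives one logit per head back.
#'
#' @param layers number of transformer blocks.
#' @param heads number of attention heads; `atom_dim` must be divisible by it.
#' @param atom_dim atom-representation width d.
#' @param rbf_kernels number G of Gaussian radial-basis kernels.
#' @param rbf_gammas vector of G positive RBF widths in 1/Angstrom^2;
#'   defaults to a log-spaced bank on [0.01, 10].
#' @param ffn_dim feed-forward hidden width.
#' @param recycles default number of re-encoding rounds for docking (R >= 0).
#' @param max_atoms batch padding bound.
#' @param proj_dim contrastive projection dimension k.
#' @param coord_hidden hidden width of the coordinate-head MLP.
#' @param dist_hidden hidden width of the distance-head MLP.
#' @param tau_init initial contrastive temperature.
#' @param huber_delta Huber threshold delta (Angstrom) for the intra loss.
#' @return A `backbone_config` list.
#' @export
backbone_config <- function(layers = 2L, heads = 4L, atom_dim = 64L,
                            rbf_kernels = 16L, rbf_gammas = NULL,
                            ffn_dim = 128L, recycles = 0L, max_atoms = 256L,
                            proj_dim = 128L, coord_hidden = 64L,
                            dist_hidden = 64L, tau_init = 0.07,
                            huber_delta = 1.0) {
  if (atom_dim %% heads != 0) stop("atom_dim must be divisible by heads")
  if (is.null(rbf_gammas))
    rbf_gammas <- exp(seq(log(0.01), log(10), length.out = rbf_kernels))
  if (length(rbf_gammas) != rbf_kernels || any(rbf_gammas <= 0))
    stop("rbf_gammas must be ", rbf_kernels, " positive values")
  if (recycles < 0) stop("recycles must be >= 0")
  structure(list(layers = as.integer(layers), heads = as.integer(heads),
                 atom_dim = as.integer(atom_dim),
                 pair_channels = as.integer(heads),
                 rbf_kernels = as.integer(rbf_kernels),
                 rbf_gammas = as.numeric(rbf_gammas),
                 ffn_dim = as.integer(ffn_dim),
                 recycles = as.integer(recycles),
                 max_atoms = as.integer(max_atoms),
                 proj_dim = as.integer(proj_dim),
                 coord_hidden = as.integer(coord_hidden),
                 dist_hidden = as.integer(dist_hidden),
                 tau_init = tau_init, huber_delta = huber_delta),
            class = "backbone_config")
}

rnorm_mat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

#' Initialise a model
#'
#' Builds the full parameter set: type embedding, RBF projection and bond
#' embeddings for the pair track, `layers` transformer blocks, the
#' equivariant coordinate head, the distance head, the contrastive projection
#' heads with learnable temperature, the matching classifier, and the docking
#' score head.  Output layers of residual heads start at zero, so a freshly
#' initialised coordinate head is the identity map on coordinates.
#'
#' @param config a [backbone_config()].
#' @param seed integer seed for the parameter draw.
#' @return An object of class `pf_model` with elements `config` and `params`
#'   (a flat named list of numeric arrays).
#' @export
new_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "backbone_config"))
  d <- config$atom_dim; H <- config$heads; G <- config$rbf_kernels
  V <- length(atom_vocab())
  p <- list()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  xav <- function(nr, nc) rnorm_mat(nr, nc, sqrt(2 / (nr + nc)))
  p$embed <- rnorm_mat(V, d, 0.02)
  p$rbf_w <- xav(G, H); p$rbf_b <- numeric(H)
  p$bond_emb <- rnorm_mat(4, H, 0.02)  # no-bond contributes the zero vector
  for (l in seq_len(config$layers)) {
    pre <- sprintf("L%d.", l)
    p[[paste0(pre, "Wq")]] <- xav(d, d); p[[paste0(pre, "bq")]] <- numeric(d)
    p[[paste0(pre, "Wk")]] <- xav(d, d); p[[paste0(pre, "bk")]] <- numeric(d)
    p[[paste0(pre, "Wv")]] <- xav(d, d); p[[paste0(pre, "bv")]] <- numeric(d)
    p[[paste0(pre, "Wo")]] <- xav(d, d); p[[paste0(pre, "bo")]] <- numeric(d)
    p[[paste0(pre, "ln1_g")]] <- rep(1, d); p[[paste0(pre, "ln1_b")]] <- numeric(d)
    p[[paste0(pre, "W1")]] <- xav(d, config$ffn_dim)
    p[[paste0(pre, "b1")]] <- numeric(config$ffn_dim)
    p[[paste0(pre, "W2")]] <- xav(config$ffn_dim, d)
    p[[paste0(pre, "b2")]] <- numeric(d)
    p[[paste0(pre, "ln2_g")]] <- rep(1, d); p[[paste0(pre, "ln2_b")]] <- numeric(d)
  }
  p$coord_U <- xav(H, config$coord_hidden)
  p$coord_W <- matrix(0, config$coord_hidden, 1)
  p$dist_W1 <- xav(H, config$dist_hidden)
  p$dist_b1 <- numeric(config$dist_hidden)
  p$dist_W2 <- matrix(0, config$dist_hidden, 1)
  p$dist_b2 <- numeric(1)
  p$gP <- xav(d, config$proj_dim); p$gP_b <- numeric(config$proj_dim)
  p$gM <- xav(d, config$proj_dim); p$gM_b <- numeric(config$proj_dim)
  p$log_tau <- log(config$tau_init)
  p$match_W <- xav(d, 2); p$match_b <- numeric(2)
  p$score_W1 <- xav(H, 32L); p$score_b1 <- numeric(32L)
  p$score_w2 <- matrix(0, 32L, 1); p$score_b2 <- 0
  p$score_log_lambda <- 0
  structure(list(config = config, params = p), class = "pf_model")
}

#' @export
print.pf_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf("<pf_model: L=%d H=%d d=%d, %d parameters>\n",
              x$config$layers, x$config$heads, x$config$atom_dim, np))
  invisible(x)
}

# ---- RNG plumbing: save/restore so library code never perturbs the user's
# stream, and derive per-call seeds that stay inside 32-bit range.

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  expr
}

derive_seed <- function(seed, ...) {
  ks <- c(seed, ...)
  h <- 0
  for (k in ks) h <- (h * 69069 + as.numeric(k) + 1) %% 2147483629
  as.integer(h)
}

zero_grads <- function(model) {
  lapply(model$params, function(p) {
    z <- p; z[] <- 0; z
  })
}

grad_add <- function(acc, g) {
  for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
  acc
}

grad_scale <- function(g, s) lapply(g, function(x) x * s)
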