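# Training: AdamW with decoupled weight decay, linear-warmup + cosine
# annealing schedule, the three-objective step, checkpointing and JSON-lines
# logging.

#' Training configuration
#'
#' The reference optimisation settings are AdamW with weight decay 0.05 and a
#' 1000-step linear warm-up followed by cosine annealing from a peak of 1e-4
#' to a minimum of 5e-6.  Desk-scale toy runs override `peak_lr` and
#' `warmup_steps` to suit a few hundred steps.
#'
#' @param backbone a [backbone_config()].
#' @param weight_decay decoupled weight decay (skips normalisation gains,
#'   biases and the temperature).
#' @param peak_lr,min_lr schedule endpoints; `peak_lr > min_lr > 0`.
#' @param warmup_steps,total_steps schedule lengths;
#'   `warmup_steps < total_steps`.
#' @param batch_size matched pairs per step.
#' @param seed integer training seed.
#' @param objective_mask subset of `c("contrastive", "matching", "docking")`.
#' @param grad_clip global gradient-norm ceiling (`Inf` disables clipping).
#' @param mining_strategy hard-negative mining: `"sample"` or `"argmax"`.
#' @param dock_start_rmsd range (Angstrom) the perturbed starting poses for
#'   the docking pass are drawn from.
#' @return A `train_config` list.
#' @export
train_config <- function(backbone = backbone_config(),
                         weight_decay = 0.05,
                         peak_lr = 1e-4, min_lr = 5e-6,
                         warmup_steps = 1000L, total_steps = 10000L,
                         batch_size = 8L, seed = 1L,
                         objective_mask = c("contrastive", "matching",
                                            "docking"),
                         grad_clip = 1.0,
                         mining_strategy = "sample",
                         dock_start_rmsd = c(1, 5)) {
  stopifnot(warmup_steps < total_steps, peak_lr > min_lr, min_lr > 0)
  objective_mask <- match.arg(objective_mask,
                              c("contrastive", "matching", "docking"),
                              several.ok = TRUE)
  structure(list(backbone = backbone, weight_decay = weight_decay,
                 peak_lr = peak_lr, min_lr = min_lr,
                 warmup_steps = as.integer(warmup_steps),
                 total_steps = as.integer(total_steps),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 objective_mask = objective_mask,
                 grad_clip = grad_clip,
                 mining_strategy = mining_strategy,
                 dock_start_rmsd = dock_start_rmsd),
            class = "train_config")
}

#' Learning-rate schedule
#'
#' Linear ramp from 0 to `peak_lr` over the warm-up, then cosine annealing to
#' exactly `min_lr` at `total_steps`.
#'
#' @param step step index in `[0, total_steps]`.
#' @param cfg a [train_config()].
#' @return Learning rate.
#' @export
lr_schedule <- function(step, cfg) {
  if (step < 0 || step > cfg$total_steps)
    stop("step out of range [0, ", cfg$total_steps, "]")
  if (step <= cfg$warmup_steps)
    return(cfg$peak_lr * step / cfg$warmup_steps)
  t <- (step - cfg$warmup_steps) / (cfg$total_steps - cfg$warmup_steps)
  cfg$min_lr + 0.5 * (cfg$peak_lr - cfg$min_lr) * (1 + cos(pi * t))
}

#' Desk-scale training configuration
#'
#' The small reference setup used for toy runs and the synthetic benchmark:
#' the default backbone (2 layers, 4 heads, d = 64, G = 16, k = 128), batch
#' size 8, and a compressed schedule (50-step warm-up).  Docking-only runs
#' use a higher peak learning rate (2e-2 vs 1e-3) and 2 refinement recycles:
#' the coordinate pathway trains through a zero-initialised output layer and
#' needs the larger steps over a few hundred iterations.
#'
#' @param objective_mask objectives to train (see [train_config()]).
#' @param total_steps planned run length.
#' @param seed integer seed.
#' @param ... overrides passed on to [train_config()].
#' @return A [train_config()].
#' @export
desk_train_config <- function(objective_mask = c("contrastive", "matching",
                                                 "docking"),
                              total_steps = 300L, seed = 1L, ...) {
  dock_only <- identical(objective_mask, "docking")
  args <- list(
    backbone = backbone_config(recycles = if (dock_only) 2L else 0L),
    peak_lr = if (dock_only) 2e-2 else 1e-3,
    min_lr = if (dock_only) 2e-4 else 1e-5,
    warmup_steps = 50L, total_steps = as.integer(total_steps),
    batch_size = 8L, seed = as.integer(seed),
    objective_mask = objective_mask)
  over <- list(...)
  args[names(over)] <- over
  do.call(train_config, args)
}

# ---- AdamW -----------------------------------------------------------------

clip_grads <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (total > max_norm) grads <- grad_scale(grads, max_norm / total)
  grads
}

adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamw_no_decay <- function(nm) {
  grepl("(_b$|^rbf_b$|\\.b[qkvo12]$|ln[12]_[gb]|log_tau|log_lambda|score_b|match_b|dist_b)",
        nm) || grepl("(^|\\.)b[a-z0-9_]*$", nm)
}

adamw_step <- function(params, grads, state, lr, weight_decay = 0.05,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    if (weight_decay > 0 && !adamw_no_decay(nm))
      params[[nm]] <- params[[nm]] - lr * weight_decay * params[[nm]]
  }
  list(params = params, state = state)
}

# ---- the three-objective step ---------------------------------------------

#' Initial ligand pose for docking training and evaluation
#'
#' Each complex gets one fixed initial conformation: the true pose displaced
#' by a rigid decoy transform whose RMSD target is drawn (deterministically
#' per complex from the training seed) from `cfg$dock_start_rmsd`.  Training
#' the docking objective repeatedly from this pose and evaluating [dock()]
#' from the same pose mirrors the usual fine-tuning setup in which every
#' complex has a single given starting conformation.
#'
#' @param pair a matched [complex_pair()] with a true pose.
#' @param cfg a [train_config()].
#' @return n_mol x 3 starting coordinates.
#' @export
docking_start_pose <- function(pair, cfg) {
  pid <- sum(utf8ToInt(paste0(pair$pair_id, "x")))
  tgt <- with_seed(derive_seed(cfg$seed, 311L, pid),
                   stats::runif(1, cfg$dock_start_rmsd[1],
                                cfg$dock_start_rmsd[2]))
  make_decoy_pose(pair, tgt, seed = derive_seed(cfg$seed, 312L, pid))
}

# Place molecule `mol` (from pair b) into pocket-frame of pair a: recentre at
# the location of a's own ligand.
transplant_molecule <- function(a, mol) {
  keep <- !mol$virtual_flags
  target <- colMeans(real_coords(a$molecule))
  shift <- target - colMeans(mol$coords[keep, , drop = FALSE])
  mol$coords <- sweep(mol$coords, 2, -shift)
  mol
}

#' One training step over a batch of matched pairs
#'
#' Runs (a) one separate pocket and molecule pass per pair for the
#' contrastive loss, (b) joint pocket-grounded passes on the positives plus
#' mined hard negatives for the matching loss, and (c) joint passes with the
#' coordinate head on perturbed starting poses for the intra/inter docking
#' losses; then applies one AdamW update at `lr_schedule(step)`.  Objectives
#' outside `cfg$objective_mask` are skipped and reported as 0.
#'
#' @param model a [new_model()].
#' @param opt AdamW state from `adamw_init(model$params)`.
#' @param batch list of matched [complex_pair()]s with true poses.
#' @param cfg a [train_config()].
#' @param step integer step index (drives the schedule and all in-step
#'   randomness).
#' @return List with updated `model`, `opt` and the `report`
#'   ([total_loss()]).
#' @export
train_step <- function(model, opt, batch, cfg, step) {
  mask <- cfg$objective_mask
  N <- length(batch)
  acc <- grad_acc(model)
  l_pmc <- 0; l_pmm <- 0; l_intra <- 0; l_inter <- 0
  need_sep <- any(c("contrastive", "matching") %in% mask)
  sep_caches <- NULL
  S <- NULL
  if (need_sep) {
    encP <- vector("list", N); encM <- vector("list", N)
    for (i in seq_len(N)) {
      pk <- ensure_token(batch[[i]]$pocket, "CLS")
      ml <- ensure_token(batch[[i]]$molecule, "CLS")
      encP[[i]] <- encode_graph(model, pk, keep_cache = TRUE)
      encM[[i]] <- encode_graph(model, ml, keep_cache = TRUE)
    }
    tokP <- virtual_symbol("CLS", "pocket")
    tokM <- virtual_symbol("CLS", "molecule")
    cls_P <- do.call(rbind, lapply(encP, function(e) e$cls_embedding[[tokP]]))
    cls_M <- do.call(rbind, lapply(encM, function(e) e$cls_embedding[[tokM]]))
    cl <- contrastive_loss(model, cls_P, cls_M,
                           with_grads = "contrastive" %in% mask)
    S <- cl$S
    if ("contrastive" %in% mask) {
      l_pmc <- cl$loss
      acc_add(acc, cl$grads)
      for (i in seq_len(N)) {
        iP <- which(encP[[i]]$cache$types ==
                      atom_type_codes(tokP))
        dXP <- matrix(0, nrow(encP[[i]]$atom_reps), model$config$atom_dim)
        dXP[iP, ] <- cl$d_cls_P[i, ]
        encoder_bwd(model, encP[[i]], dXP, acc = acc)
        iM <- which(encM[[i]]$cache$types == atom_type_codes(tokM))
        dXM <- matrix(0, nrow(encM[[i]]$atom_reps), model$config$atom_dim)
        dXM[iM, ] <- cl$d_cls_M[i, ]
        encoder_bwd(model, encM[[i]], dXM, acc = acc)
      }
    }
  }
  if ("matching" %in% mask && N >= 1) {
    negs <- if (N >= 2)
      mine_hard_negatives(S, seed = derive_seed(cfg$seed, 301L, step),
                          strategy = cfg$mining_strategy)
    else data.frame(pocket = integer(0), molecule = integer(0))
    items <- c(lapply(seq_len(N), function(i) list(p = i, m = i, y = 1)),
               lapply(seq_len(nrow(negs)), function(k)
                 list(p = negs$pocket[k], m = negs$molecule[k], y = 0)))
    tok <- virtual_symbol("ENCODE", "molecule")
    B <- length(items)
    encs <- vector("list", B)
    logit_mat <- matrix(0, B, 2)
    emb_mat <- matrix(0, B, model$config$atom_dim)
    for (k in seq_len(B)) {
      it <- items[[k]]
      pk <- batch[[it$p]]$pocket
      ml <- ensure_token(batch[[it$m]]$molecule, "ENCODE")
      if (it$p != it$m) ml <- transplant_molecule(batch[[it$p]], ml)
      encs[[k]] <- encode_joint(model, pk, ml, keep_cache = TRUE)
      emb_mat[k, ] <- encs[[k]]$cls_embedding[[tok]]
      logit_mat[k, ] <- match_logits(model, emb_mat[k, ])
    }
    labels <- vapply(items, function(it) it$y, 1)
    ml_res <- matching_loss(logit_mat, labels, with_grads = TRUE)
    l_pmm <- ml_res$loss
    acc_add(acc, list(
      match_W = crossprod(emb_mat, ml_res$d_logits),
      match_b = colSums(ml_res$d_logits)))
    for (k in seq_len(B)) {
      demb <- as.numeric(ml_res$d_logits[k, ] %*% t(model$params$match_W))
      itok <- encs[[k]]$idx_mol_virtual[
        match(tok, names(encs[[k]]$cls_embedding))]
      dX <- matrix(0, nrow(encs[[k]]$atom_reps), model$config$atom_dim)
      dX[itok, ] <- demb
      encoder_bwd(model, encs[[k]], dX, acc = acc)
    }
  }
  if ("docking" %in% mask) {
    delta <- model$config$huber_delta
    for (i in seq_len(N)) {
      pair <- batch[[i]]
      if (is.null(pair$true_ligand_coords)) next
      start <- docking_start_pose(pair, cfg)
      # supervise every round of the refinement trajectory; gradients do not
      # flow across rounds (each round's input pose is treated as data)
      rounds <- model$config$recycles + 1
      coords_cur <- start
      for (r in seq_len(rounds)) {
        enc <- encode_joint(model, pair$pocket, pair$molecule,
                            ligand_coords = coords_cur, keep_cache = TRUE)
        ch <- coordinate_head(model, enc, keep_cache = TRUE)
        pred <- ch$coords[enc$idx_mol_real, , drop = FALSE]
        li <- intra_loss(pred, pair$true_ligand_coords, delta = delta,
                         with_grads = TRUE)
        le <- inter_loss(pred, pair$true_ligand_coords, with_grads = TRUE)
        l_intra <- l_intra + li$loss / (N * rounds)
        l_inter <- l_inter + le$loss / (N * rounds)
        dpred <- (li$d_pred + le$d_pred) / (N * rounds)
        dcoords <- matrix(0, nrow(ch$coords), 3)
        dcoords[enc$idx_mol_real, ] <- dpred
        cb <- coordinate_head_bwd(model, enc, ch, dcoords)
        acc_add(acc, cb$grads)
        encoder_bwd(model, enc, NULL, dqL = cb$dqL, dq0_direct = cb$dq0,
                    acc = acc)
        coords_cur <- pred
      }
    }
  }
  report <- total_loss(l_pmc, l_pmm, l_intra, l_inter)
  grads <- acc$g
  if (!is.null(cfg$grad_clip)) grads <- clip_grads(grads, cfg$grad_clip)
  lr <- lr_schedule(min(step, cfg$total_steps), cfg)
  upd <- adamw_step(model$params, grads, opt, lr = lr,
                    weight_decay = cfg$weight_decay)
  list(model = list2model(model, upd$params), opt = upd$state,
       report = report, lr = lr)
}

list2model <- function(model, params) {
  model$params <- params
  model
}

#' Run a training loop
#'
#' Samples a batch of matched pairs per step (deterministically from the
#' config seed), runs [train_step()], and optionally appends one JSON record
#' per step (step, learning rate, all loss components) to `log_path`.
#'
#' @param model a [new_model()].
#' @param pairs list of matched [complex_pair()]s.
#' @param cfg a [train_config()].
#' @param steps number of steps to run (default `cfg$total_steps`).
#' @param log_path optional JSON-lines log file.
#' @return List with the trained `model`, final `opt` state and `reports`
#'   (list of per-step [total_loss()] reports).
#' @export
train <- function(model, pairs, cfg, steps = cfg$total_steps,
                  log_path = NULL) {
  opt <- adamw_init(model$params)
  reports <- vector("list", steps)
  if (!is.null(log_path) && file.exists(log_path)) file.remove(log_path)
  for (st in seq_len(steps)) {
    idx <- with_seed(derive_seed(cfg$seed, 201L, st),
                     sample.int(length(pairs),
                                min(cfg$batch_size, length(pairs))))
    out <- train_step(model, opt, pairs[idx], cfg, st)
    model <- out$model; opt <- out$opt
    reports[[st]] <- out$report
    if (!is.null(log_path)) {
      rec <- jsonlite::toJSON(c(list(step = st, lr = out$lr),
                                unclass(out$report)),
                              auto_unbox = TRUE, digits = NA)
      cat(rec, "\n", sep = "", file = log_path, append = TRUE)
    }
  }
  list(model = model, opt = opt, reports = reports)
}

#' Read a JSON-lines training log
#'
#' @param path log file written by [train()].
#' @return data.frame with one row per step.
#' @export
read_train_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  do.call(rbind, lapply(lines, function(ln)
    as.data.frame(jsonlite::fromJSON(ln))))
}

# ---- checkpoints -----------------------------------------------------------

CKPT_VERSION <- "pocketformer-ckpt-1"

#' Save / load a training checkpoint
#'
#' A single self-describing archive holding the format version, the full
#' backbone configuration, all parameter tensors under stable names, the
#' optimizer state and the RNG state.  Loading refuses a version mismatch
#' and (optionally) a configuration mismatch.
#'
#' @param model a [new_model()].
#' @param opt AdamW state (or `NULL`).
#' @param path file path.
#' @param rng_state optional `.Random.seed` vector to embed.
#' @param step training step reached.
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns `list(model, opt, rng_state, step)`.
#' @export
save_checkpoint <- function(model, opt = NULL, path, rng_state = NULL,
                            step = 0L) {
  obj <- list(version = CKPT_VERSION, config = unclass(model$config),
              params = model$params, opt = opt, rng_state = rng_state,
              step = as.integer(step))
  saveRDS(obj, path, compress = FALSE, version = 3)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param expect_config optional [backbone_config()] the checkpoint must
#'   match.
#' @export
load_checkpoint <- function(path, expect_config = NULL) {
  obj <- readRDS(path)
  if (!identical(obj$version, CKPT_VERSION))
    stop("checkpoint version mismatch: file has '", obj$version,
         "', this package expects '", CKPT_VERSION, "'")
  cfg <- do.call(backbone_config,
                 obj$config[setdiff(names(obj$config), "pair_channels")])
  if (!is.null(expect_config) && !identical(unclass(cfg),
                                            unclass(expect_config)))
    stop("checkpoint configuration does not match the expected configuration")
  model <- structure(list(config = cfg, params = obj$params),
                     class = "pf_model")
  list(model = model, opt = obj$opt, rng_state = obj$rng_state,
       step = obj$step)
}
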