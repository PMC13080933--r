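# Evaluation metrics for the three task modes.

#' Build a ranked score table
#'
#' @param item_id character identifiers.
#' @param score numeric scores (higher is better).
#' @param label optional binary labels (1 = active / native).
#' @return data.frame of class `score_table`, sorted by descending score with
#'   ties broken deterministically by `item_id`; ranks are 1..n.
#' @export
score_table <- function(item_id, score, label = NULL) {
  stopifnot(length(item_id) == length(score))
  ord <- order(-score, as.character(item_id))
  df <- data.frame(item_id = as.character(item_id)[ord],
                   score = score[ord],
                   rank = seq_along(score),
                   stringsAsFactors = FALSE)
  if (!is.null(label)) df$label <- label[ord]
  class(df) <- c("score_table", "data.frame")
  df
}

#' Write a score table as TSV
#'
#' @param tab a [score_table()].
#' @param path output path.
#' @export
write_score_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Root-mean-square deviation between two poses
#'
#' Plain per-atom RMSD in a common frame (no superposition: the pocket frame
#' is fixed in docking evaluation).
#'
#' @param a,b n x 3 coordinate matrices, same atom order.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("coordinate shape mismatch")
  sqrt(sum((a - b)^2) / nrow(a))
}

#' Area under the ROC curve
#'
#' Rank-sum formulation: the probability that a uniformly chosen active
#' outscores a uniformly chosen decoy, ties counting one half.
#'
#' @param scores numeric scores (higher = more active-like).
#' @param labels binary labels (1 = active).
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("auroc needs both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Boltzmann-enhanced discrimination of ROC
#'
#' Exponentially early-weighted rank metric (Truchon-Bayly): actives near the
#' top of the ranked list are weighted by `exp(-alpha * rank / N)`, the sum
#' is normalised by its value under ideal early ranking, and the result is
#' mapped to [0, 1].
#'
#' @param scores numeric scores (higher ranks first).
#' @param labels binary labels (1 = active).
#' @param alpha early-recognition weight (default 80.5, the community
#'   convention for 0.5%-focused screening).
#' @return BEDROC in [0, 1].
#' @export
bedroc <- function(scores, labels, alpha = 80.5) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  N <- length(scores)
  n <- sum(labels == 1)
  if (n == 0 || n == N) stop("bedroc needs both classes")
  ord <- order(-scores)
  ranks <- which(labels[ord] == 1)          # 1-based ranks of actives
  Ra <- n / N
  s <- sum(exp(-alpha * ranks / N))
  rand_sum <- Ra * (1 - exp(-alpha)) / (exp(alpha / N) - 1)
  rie <- s / rand_sum
  rie * Ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * Ra)) +
    1 / (1 - exp(alpha * (1 - Ra)))
}

#' Enrichment factor
#'
#' Hit-rate ratio: the fraction of actives in the top `ceiling(f * N)` of
#' the ranked list divided by the overall active fraction.
#'
#' @param scores numeric scores.
#' @param labels binary labels (1 = active).
#' @param fraction top fraction f in (0, 1].
#' @return EF value >= 0.
#' @export
enrichment_factor <- function(scores, labels, fraction) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  N <- length(scores)
  n_act <- sum(labels == 1)
  top <- ceiling(fraction * N)
  ord <- order(-scores)
  hits <- sum(labels[ord][seq_len(top)] == 1)
  (hits / top) / (n_act / N)
}

#' Top-k docking success rate
#'
#' The CASF-style docking-power protocol: for each decoy set (a ranked table
#' with per-pose RMSD annotations), success means at least one of the top-k
#' poses by score has RMSD below the threshold.  Returns the percentage of
#' successful sets.
#'
#' @param decoy_sets list of data.frames with columns `score` and `rmsd`.
#' @param k number of top poses inspected (>= 1).
#' @param threshold RMSD success threshold in Angstrom (default 2).
#' @return Success rate in percent.
#' @export
topk_success <- function(decoy_sets, k = 1, threshold = 2) {
  if (k < 1) stop("k must be >= 1")
  ok <- vapply(decoy_sets, function(tab) {
    stopifnot(all(c("score", "rmsd") %in% names(tab)))
    ord <- order(-tab$score)
    any(tab$rmsd[ord][seq_len(min(k, nrow(tab)))] < threshold)
  }, logical(1))
  100 * mean(ok)
}
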