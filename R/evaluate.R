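# Segmentation scoring: per-class semantic metrics (recall, precision, IoU,
# F1) and instance-partition indices (Rand, adjusted Rand, adjusted mutual
# information, completeness, homogeneity).

#' Per-class semantic segmentation scores
#'
#' One-vs-rest counting per class: `Re_c = TP/(TP+FN)`, `Pr_c = TP/(TP+FP)`,
#' `IoU_c = TP/(TP+FN+FP)`, `F1_c = TP/(TP+0.5(FP+FN))`. The macro F1 averages
#' per-class F1 over the classes present in the ground truth. An optional
#' class map (named vector old -> new) is applied to both label arrays before
#' scoring, e.g. to merge apex into leaf blade and branch/petiole into stem
#' when the ground truth is coarser.
#'
#' @param pred predicted per-point class labels.
#' @param gt ground-truth per-point class labels (same length).
#' @param class_map optional named character vector mapping labels to merged
#'   labels (unnamed labels pass through).
#' @return List with `per_class` (data frame: class, recall, precision, iou,
#'   f1, support) and `macro_f1`.
#' @export
semantic_scores <- function(pred, gt, class_map = NULL) {
  if (length(pred) != length(gt)) .stopf("label arrays differ in length (%d vs %d)",
                                         length(pred), length(gt))
  pred <- as.character(pred); gt <- as.character(gt)
  if (!is.null(class_map)) {
    map <- function(x) ifelse(x %in% names(class_map), unname(class_map[x]), x)
    pred <- map(pred); gt <- map(gt)
  }
  classes <- sort(unique(gt))
  rows <- lapply(classes, function(cl) {
    tp <- sum(pred == cl & gt == cl)
    fp <- sum(pred == cl & gt != cl)
    fn <- sum(pred != cl & gt == cl)
    data.frame(class = cl,
               recall = tp / (tp + fn),
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               iou = tp / (tp + fn + fp),
               f1 = tp / (tp + 0.5 * (fp + fn)),
               support = tp + fn)
  })
  per_class <- do.call(rbind, rows)
  list(per_class = per_class, macro_f1 = mean(per_class$f1))
}

# Shannon entropy (nats) of a count vector.
.entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

# Expected mutual information between two partitions with fixed marginals
# under the hypergeometric model (Vinh, Epps & Bailey 2010).
.expected_mi <- function(a, b, n) {
  emi <- 0
  lfn <- lfactorial(n)
  for (ai in a) {
    for (bj in b) {
      lo <- max(1L, ai + bj - n)
      hi <- min(ai, bj)
      if (lo > hi) next
      nij <- lo:hi
      lterm <- lfactorial(ai) + lfactorial(bj) + lfactorial(n - ai) + lfactorial(n - bj) -
        lfn - lfactorial(nij) - lfactorial(ai - nij) - lfactorial(bj - nij) -
        lfactorial(n - ai - bj + nij)
      emi <- emi + sum(nij / n * log(n * nij / (ai * bj)) * exp(lterm))
    }
  }
  emi
}

#' Instance-partition similarity scores
#'
#' Compares two partitions of the same points: Rand index (pair counting),
#' adjusted Rand index (chance-corrected), adjusted mutual information
#' (expected-MI correction, arithmetic-mean normalizer), and the
#' entropy-based completeness `1 - H(pred|gt)/H(gt)` and homogeneity
#' `1 - H(gt|pred)/H(pred)` (each defined as 1 when the conditioning
#' entropy is 0).
#'
#' @param pred predicted per-point instance ids.
#' @param gt ground-truth per-point instance ids (same length).
#' @return List with `rand`, `adjusted_rand`, `adjusted_mutual_information`,
#'   `completeness`, `homogeneity`.
#' @export
instance_scores <- function(pred, gt) {
  if (length(pred) != length(gt)) .stopf("instance arrays differ in length (%d vs %d)",
                                         length(pred), length(gt))
  n <- length(pred)
  pf <- as.integer(factor(pred)); gf <- as.integer(factor(gt))
  R <- max(pf); C <- max(gf)
  nij <- matrix(tabulate(pf + R * (gf - 1L), R * C), R, C)
  a <- rowSums(nij)  # pred marginals
  b <- colSums(nij)  # gt marginals

  # Rand / ARI via pair counts
  s_ij <- sum(choose(nij, 2))
  s_a <- sum(choose(a, 2))
  s_b <- sum(choose(b, 2))
  s_n <- choose(n, 2)
  rand <- (s_n + 2 * s_ij - s_a - s_b) / s_n
  exp_idx <- s_a * s_b / s_n
  max_idx <- (s_a + s_b) / 2
  ari <- if (max_idx == exp_idx) 1 else (s_ij - exp_idx) / (max_idx - exp_idx)

  # entropies and MI
  h_pred <- .entropy(a)
  h_gt <- .entropy(b)
  p <- nij / n
  nzmask <- nij > 0
  mi <- sum(p[nzmask] * log(p[nzmask] / (outer(a, b) / n^2)[nzmask]))
  emi <- .expected_mi(a, b, n)
  denom <- (h_pred + h_gt) / 2 - emi
  ami <- if (abs(denom) < 1e-15) 1 else (mi - emi) / denom

  h_pred_given_gt <- max(0, h_pred - mi)  # H(pred|gt) = H(pred) - I
  h_gt_given_pred <- max(0, h_gt - mi)
  # completeness: each ground-truth cluster stays within one predicted cluster
  completeness <- if (h_pred == 0) 1 else 1 - h_pred_given_gt / h_pred
  # homogeneity: each predicted cluster contains points of a single gt cluster
  homogeneity <- if (h_gt == 0) 1 else 1 - h_gt_given_pred / h_gt
  list(rand = rand, adjusted_rand = ari, adjusted_mutual_information = ami,
       completeness = completeness, homogeneity = homogeneity)
}
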