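# Ranking evaluation: how well does the significance ranking recover a
# binary known-indication label set? ROC AUC (Mann-Whitney), partial AUC
# over a low false-positive-rate strip, DCG/NDCG/NDCG@k, and enrichment
# of labelled drugs above a significance cut-off.

#' Discounted cumulative gain of the top k positions
#'
#' Default (classic) convention: `DCG_k = rel_1 + sum_{i=2..k} rel_i /
#' log2(i)`. The alternative `"log2i1"` convention `sum_{i=1..k} rel_i /
#' log2(i+1)` is selectable.
#'
#' @param rels Relevance scores in ranked order (best first).
#' @param k Truncation depth, `1 <= k <= length(rels)`.
#' @param convention `"rel1"` (default) or `"log2i1"`.
#' @return Non-negative double.
#' @export
dcg_at <- function(rels, k = length(rels), convention = c("rel1", "log2i1")) {
  convention <- match.arg(convention)
  if (length(k) != 1L || k < 1) stop("k must be a positive integer", call. = FALSE)
  if (k > length(rels)) stop("k exceeds the ranking length", call. = FALSE)
  i <- seq_len(k)
  disc <- switch(convention,
    rel1   = c(1, 1 / log2(i[-1])),
    log2i1 = 1 / log2(i + 1)
  )
  sum(rels[i] * disc)
}

#' Normalized discounted cumulative gain
#'
#' `NDCG@k = DCG@k / IDCG@k` where the ideal ordering sorts the full
#' relevance multiset descending before truncating at `k`; the result
#' lies in `[0, 1]` and is 1 iff all relevant items are ranked first.
#'
#' @inheritParams dcg_at
#' @param k Truncation depth or `"all"` for the full list.
#' @return Double in `[0, 1]`.
#' @export
ndcg <- function(rels, k = "all", convention = c("rel1", "log2i1")) {
  convention <- match.arg(convention)
  if (identical(k, "all")) k <- length(rels)
  if (all(rels <= 0)) {
    stop("all-zero relevance: ideal DCG is zero, NDCG undefined", call. = FALSE)
  }
  ideal <- sort(rels, decreasing = TRUE)
  dcg_at(rels, k, convention) / dcg_at(ideal, k, convention)
}

check_labels <- function(labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (sum(labels == 1) == 0L || sum(labels == 0) == 0L) {
    stop("both label classes must be present", call. = FALSE)
  }
}

#' ROC area under the curve (Mann-Whitney form)
#'
#' Fraction of (positive, negative) pairs where the positive scores
#' higher, ties credited 0.5 — identical to the area under the empirical
#' ROC curve with tie groups traced as diagonal segments.
#'
#' @param scores Numeric ranking keys, higher = ranked better. For a
#'   significance ranking use [signal_scores()].
#' @param labels 0/1 relevance per score; both classes must be present.
#' @return Double in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  check_labels(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores)  # midranks handle ties as 0.5 credit
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Empirical ROC points (FPR, TPR), one per distinct score level in
# descending order, starting at (0, 0); ties form single steps whose
# chords are the tie-group diagonals.
roc_points <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  last <- !duplicated(s, fromLast = TRUE)  # last index of each tie group
  tp <- cumsum(y)[last]; fp <- cumsum(1 - y)[last]
  list(fpr = c(0, fp / sum(labels == 0)), tpr = c(0, tp / sum(labels == 1)))
}

#' Partial area under the ROC curve over a low-FPR strip
#'
#' Unnormalized area of the empirical ROC curve over false-positive rate
#' `[0, fpr_max]`, trapezoidal on the step curve with linear
#' interpolation at the `fpr_max` boundary. A perfect classifier scores
#' `fpr_max`; the chance diagonal scores `fpr_max^2 / 2`.
#'
#' @inheritParams roc_auc
#' @param fpr_max Upper false-positive-rate bound, in `(0, 1]`.
#' @return Double in `[0, fpr_max]`.
#' @export
partial_auc <- function(scores, labels, fpr_max = 0.1) {
  stopifnot(length(fpr_max) == 1L, fpr_max > 0, fpr_max <= 1)
  check_labels(labels)
  pts <- roc_points(scores, labels)
  area <- 0
  for (j in seq_len(length(pts$fpr) - 1L)) {
    x0 <- pts$fpr[j]; x1 <- pts$fpr[j + 1L]
    y0 <- pts$tpr[j]; y1 <- pts$tpr[j + 1L]
    if (x0 >= fpr_max) break
    if (x1 > fpr_max) {  # clip the segment at the boundary
      y1 <- if (x1 > x0) y0 + (y1 - y0) * (fpr_max - x0) / (x1 - x0) else y1
      x1 <- fpr_max
    }
    area <- area + (x1 - x0) * (y0 + y1) / 2
  }
  area
}

#' Ranking keys from signal results
#'
#' Converts a [signal_screen()] table into numeric scores (higher =
#' better) encoding the ranking key (`log10_p` ascending, `ror`
#' descending): drugs tied on both get equal scores, so AUC tie handling
#' matches the significance ordering exactly.
#'
#' @param results A `signal_results` tibble.
#' @return Numeric vector aligned with `results` rows.
#' @export
signal_scores <- function(results) {
  stopifnot(all(c("log10_p", "ror") %in% names(results)))
  neg_ror <- -results$ror
  neg_ror[is.nan(neg_ror)] <- Inf
  o <- order(results$log10_p, neg_ror)
  lp <- results$log10_p[o]; nr <- neg_ror[o]
  n <- length(lp)
  new_grp <- c(TRUE, lp[-1] != lp[-n] | nr[-1] != nr[-n])
  key <- numeric(n)
  key[o] <- cumsum(new_grp)
  -key
}

#' Enrichment of labelled drugs above a significance cut-off
#'
#' Builds the 2x2 table (labelled-significant, labelled-nonsignificant,
#' unlabelled-significant, unlabelled-nonsignificant) at an unadjusted-P
#' cut-off and attaches the conditional-MLE odds ratio (the estimate
#' conventionally reported with a Fisher exact test; the cross-product
#' ratio is returned alongside) and the log-space Fisher P.
#'
#' @param results A `signal_results` tibble (one row per drug).
#' @param labels Named 0/1 vector (names = drugs) or a data frame with
#'   columns `drug` and `rel`, covering every ranked drug.
#' @param threshold Significance cut-off on the display-scale P
#'   (default `1e-10`); a drug is "significant" when `P < threshold`,
#'   i.e. `log10_p < log10(threshold)`.
#' @return List with `table` (a [contingency_table()]), `or`
#'   (conditional MLE), `ror` (cross-product ratio), `log10_p`, and
#'   `threshold`.
#' @export
enrichment <- function(results, labels, threshold = 1e-10) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("threshold must be a positive number", call. = FALSE)
  }
  rel <- align_labels(results$drug, labels)
  check_labels(rel)
  sig <- results$log10_p < log10(threshold)
  tab <- contingency_table(sum(rel == 1 & sig), sum(rel == 1 & !sig),
                           sum(rel == 0 & sig), sum(rel == 0 & !sig))
  list(table = tab,
       or = conditional_mle_or(tab),
       ror = ror(tab),
       log10_p = fisher_exact_log(tab) / log(10),
       threshold = threshold)
}

align_labels <- function(drugs, labels) {
  if (is.data.frame(labels)) {
    stopifnot(all(c("drug", "rel") %in% names(labels)))
    labels <- setNames(labels$rel, labels$drug)
  }
  if (is.null(names(labels))) {
    if (length(labels) != length(drugs)) {
      stop("unnamed labels must align with the drug list", call. = FALSE)
    }
    return(as.numeric(labels))
  }
  missing <- setdiff(drugs, names(labels))
  if (length(missing)) {
    stop("labels missing for drug(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  as.numeric(labels[drugs])
}

#' All ranking-quality metrics for a screened drug list
#'
#' @inheritParams enrichment
#' @param fpr_max Strip width for [partial_auc()].
#' @param k Truncation depth for NDCG@k.
#' @param convention DCG convention, see [dcg_at()].
#' @return List with `auc`, `partial_auc`, `ndcg`, `ndcg_at_k`,
#'   `enrichment_or`, `enrichment_log10_p`, `threshold`, `fpr_max`, `k`
#'   and `convention`.
#' @export
ranking_metrics <- function(results, labels, fpr_max = 0.1, k = 20,
                            threshold = 1e-10,
                            convention = c("rel1", "log2i1")) {
  convention <- match.arg(convention)
  stopifnot(inherits(results, "signal_results"))
  results <- results[order(results$rank), , drop = FALSE]
  rel <- align_labels(results$drug, labels)
  check_labels(rel)
  scores <- signal_scores(results)
  enr <- enrichment(results, setNames(rel, results$drug), threshold)
  list(
    auc = roc_auc(scores, rel),
    partial_auc = partial_auc(scores, rel, fpr_max),
    ndcg = ndcg(rel, "all", convention),
    ndcg_at_k = ndcg(rel, min(k, length(rel)), convention),
    enrichment_or = enr$or,
    enrichment_log10_p = enr$log10_p,
    threshold = threshold, fpr_max = fpr_max, k = k, convention = convention
  )
}
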