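test_that("DCG follows the classic rel_1 + sum rel_i/log2(i) form", {
  expect_equal(dcg_at(c(1, 1, 0), 3), 2.0)
  expect_equal(dcg_at(rep(0, 10), 10), 0)
  # 1s at ranks 6, 9, 11, 15, 17, 19 of a depth-20 list
  rels <- rep(0, 20); rels[c(6, 9, 11, 15, 17, 19)] <- 1
  expect_equal(dcg_at(rels, 20),
               sum(1 / log2(c(6, 9, 11, 15, 17, 19))))
  # alternate convention discounts position 1 as log2(2)
  expect_equal(dcg_at(c(1, 1, 0), 3, convention = "log2i1"),
               1 / log2(2) + 1 / log2(3))
  expect_error(dcg_at(c(1, 0), 0), "positive")
  expect_error(dcg_at(c(1, 0), 3), "exceeds")
})

test_that("NDCG is 1 for ideal orderings and handles the single-item case", {
  expect_equal(ndcg(c(1, 1, 1, 0, 0)), 1.0)
  expect_equal(ndcg(c(1, 0, 0, 0), k = 2), 1.0)
  n <- 7
  rels <- c(rep(0, n - 1), 1)
  expect_equal(ndcg(rels), (1 / log2(n)) / 1)
  expect_error(ndcg(rep(0, 5)), "all-zero")
})

test_that("reverse-sorted ordering minimizes NDCG over all permutations", {
  # exhaustive over every permutation of a small relevance multiset
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  for (rels in list(c(1, 1, 0, 0, 0), c(1, 0, 0, 0, 0, 0), c(1, 1, 1, 0, 0, 0, 0))) {
    vals <- vapply(unique(perms(rels)), ndcg, 0)
    worst <- ndcg(sort(rels))  # ascending = all relevant last
    expect_equal(min(vals), worst, tolerance = 1e-12)
    expect_equal(max(vals), 1)
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("NDCG at depth k ignores irrelevant items appended beyond k", {
  rels <- c(1, 0, 1, 1, 0, 0, 1, 0, 0, 0)
  expect_equal(ndcg(c(rels, rep(0, 15)), k = 10), ndcg(rels, k = 10))
})

test_that("ROC AUC equals brute-force pairwise counting", {
  pairwise_auc <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    total <- 0
    for (p in pos) for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
    total / (length(pos) * length(neg))
  }
  expect_equal(roc_auc(c(5, 4, 3, 2, 1), c(1, 1, 0, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(1, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  set.seed(31)
  for (i in 1:10) {
    scores <- sample(1:8, 30, replace = TRUE)  # ties guaranteed
    labels <- rbinom(30, 1, 0.4)
    if (sum(labels) %in% c(0, 30)) next
    expect_equal(roc_auc(scores, labels), pairwise_auc(scores, labels))
    # complement symmetry
    expect_equal(roc_auc(scores, 1 - labels), 1 - roc_auc(scores, labels))
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both label classes")
})

test_that("partial AUC matches closed forms and fine-grid integration", {
  expect_equal(partial_auc(c(5, 4, 3, 2, 1), c(1, 1, 0, 0, 0), 0.1), 0.1)
  # chance diagonal: all scores tied
  expect_equal(partial_auc(rep(1, 10), rep(c(1, 0), 5), 0.1), 0.005)
  grid_pauc <- function(scores, labels, fpr_max) {
    # numerically integrate the empirical ROC: TPR as a function of FPR;
    # vertical segments (duplicated FPR) are opened by an infinitesimal
    # x-nudge so linear interpolation traces the true polyline
    thr <- sort(unique(scores), decreasing = TRUE)
    fpr <- c(0, vapply(thr, function(t) mean(scores[labels == 0] >= t), 0))
    tpr <- c(0, vapply(thr, function(t) mean(scores[labels == 1] >= t), 0))
    fpr <- fpr + seq_along(fpr) * 1e-9
    xs <- seq(0, fpr_max, length.out = 10001)
    ys <- approx(fpr, tpr, xout = xs, rule = 2)$y
    sum((ys[-1] + ys[-length(ys)]) / 2) * (xs[2] - xs[1])
  }
  set.seed(53)
  for (i in 1:8) {
    scores <- sample(1:10, 40, replace = TRUE)
    labels <- rbinom(40, 1, 0.5)
    if (sum(labels) %in% c(0, 40)) next
    expect_equal(partial_auc(scores, labels, 0.3),
                 grid_pauc(scores, labels, 0.3), tolerance = 1e-3)
    # full-strip partial AUC recovers the Mann-Whitney AUC
    expect_equal(partial_auc(scores, labels, 1), roc_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("enrichment reproduces the published antihypertensive odds ratio", {
  n_lab <- 56; n_unlab <- 627
  sig_lab <- 48; sig_unlab <- 247
  results <- rank_signals(tibble::tibble(
    drug = sprintf("d%03d", 1:(n_lab + n_unlab)),
    ror = 2,
    log10_p = c(rep(-20, sig_lab), rep(-2, n_lab - sig_lab),
                rep(-20, sig_unlab), rep(-2, n_unlab - sig_unlab))
  ))
  labels <- setNames(rep(c(1, 0), c(n_lab, n_unlab)),
                     sprintf("d%03d", 1:(n_lab + n_unlab)))
  enr <- enrichment(results, labels, threshold = 1e-10)
  expect_equal(unlist(enr$table[c("n11", "n10", "n01", "n00")],
                      use.names = FALSE),
               c(48, 8, 247, 380))
  expect_equal(round(enr$or, 2), 9.20)   # conditional MLE (prints 9.21 at
                                         # fisher.test's coarser tolerance)
  expect_equal(enr$or, 9.2035, tolerance = 1e-4)
  expect_equal(enr$ror, (48 * 380) / (8 * 247))  # cross-product 9.2308...
  expect_lt(enr$log10_p, -10)
  # derived percentages behind the table
  expect_equal(round(100 * 48 / 56), 86)
  expect_equal(round(100 * 247 / 627, 1), 39.4)
})

test_that("null enrichment is near 1 and degenerate thresholds error", {
  set.seed(71)
  n <- 400
  results <- rank_signals(tibble::tibble(
    drug = sprintf("d%03d", 1:n), ror = 2,
    log10_p = sample(rep(c(-20, -2), each = n / 2))
  ))
  labels <- setNames(rbinom(n, 1, 0.5), results$drug)
  enr <- enrichment(results, labels, threshold = 1e-10)
  expect_lt(abs(log(enr$or)), log(2))
  # threshold below every P: a margin empties out
  expect_error(enrichment(results, labels, threshold = 1e-40),
               "degenerate margin")
  expect_error(enrichment(results, labels, threshold = -1), "positive")
})

test_that("signal scores encode the ranking key with exact tie groups", {
  res <- rank_signals(tibble::tibble(
    drug = c("a", "b", "c", "d"),
    ror = c(3, 3, 2, 5),
    log10_p = c(-5, -5, -5, -2)
  ))
  sc <- signal_scores(res)
  expect_equal(sc[res$drug == "a"], sc[res$drug == "b"])  # full tie
  expect_gt(sc[res$drug == "a"], sc[res$drug == "c"])     # ror tiebreak
  expect_gt(sc[res$drug == "c"], sc[res$drug == "d"])     # p dominates
})

test_that("ranking_metrics ties all evaluation pieces together", {
  res <- rank_signals(tibble::tibble(
    drug = sprintf("d%02d", 1:30),
    ror = seq(5, 2, length.out = 30),
    log10_p = seq(-40, -1, length.out = 30)
  ))
  labels <- setNames(c(rep(1, 10), rep(0, 20)), sprintf("d%02d", 1:30))
  m <- ranking_metrics(res, labels, fpr_max = 0.1, k = 5, threshold = 1e-10)
  expect_equal(m$auc, 1.0)
  expect_equal(m$ndcg, 1.0)
  expect_equal(m$ndcg_at_k, 1.0)
  expect_equal(m$partial_auc, 0.1)
  expect_error(ranking_metrics(res, labels[-1]), "missing")
})
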