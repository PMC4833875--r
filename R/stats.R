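# Disproportionality statistics on a 2x2 table.
#
# P values at corpus scale routinely fall below the smallest positive
# double (Fisher P ~ 1e-600 is normal for a strong signal over millions
# of reports), so every tail computation stays in natural-log space and
# ranking consumes log10 P, never the underflowed display value.

logsumexp <- function(lp) {
  m <- max(lp)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lp - m)))
}

#' Reporting odds ratio of a 2x2 table
#'
#' `ROR = (n11 * n00) / (n10 * n01)`. By convention the result is `Inf`
#' when the denominator product is zero but the numerator is positive,
#' and `NaN` (undefined) when both products are zero. With
#' `haldane = TRUE`, 0.5 is added to every cell first (Haldane-Anscombe
#' correction; default off).
#'
#' @param table A [contingency_table()] or numeric vector
#'   `c(n11, n10, n01, n00)`.
#' @param haldane Apply the +0.5 continuity correction to all cells.
#' @return Positive double, `Inf`, or `NaN` when undefined.
#' @export
ror <- function(table, haldane = FALSE) {
  x <- as_table_cells(table)
  if (haldane) x <- x + 0.5
  num <- x[1] * x[4]
  den <- x[2] * x[3]
  if (den == 0 && num > 0) return(Inf)
  if (den == 0 && num == 0) return(NaN)
  num / den
}

# Log-scale hypergeometric point masses over the full support of n11
# given the table's margins. Returns support k and log P(X = k).
hyper_support <- function(x) {
  r1 <- x[1] + x[2]; r2 <- x[3] + x[4]
  c1 <- x[1] + x[3]; c2 <- x[2] + x[4]
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    stop("degenerate margin: a row or column total is zero", call. = FALSE)
  }
  k <- max(0, c1 - r2):min(r1, c1)
  list(k = k, lp = dhyper(k, c1, c2, r1, log = TRUE),
       r1 = r1, c1 = c1)
}

#' Fisher exact test in log space
#'
#' Exact hypergeometric test of independence in a 2x2 table, with all
#' tail arithmetic in natural-log space (log-gamma point masses,
#' log-sum-exp accumulation), so the result is meaningful far below
#' double-precision underflow. The two-sided P value sums the
#' probabilities of all tables with the observed margins whose point
#' probability is at most the observed one times `(1 + 1e-7)` (the
#' conventional relative-tolerance guard against ties broken by
#' rounding).
#'
#' @inheritParams ror
#' @param alternative `"two.sided"` (default), `"greater"` (drug
#'   positively associated with event), or `"less"`.
#' @return The natural-log P value (a non-positive double). Divide by
#'   `log(10)` for log10; exponentiate only when above
#'   `log(.Machine$double.xmin)`.
#' @export
fisher_exact_log <- function(table, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- as_table_cells(table)
  h <- hyper_support(x)
  obs <- which(h$k == x[1])
  lp <- switch(alternative,
    two.sided = logsumexp(h$lp[h$lp <= h$lp[obs] + log1p(1e-7)]),
    greater   = logsumexp(h$lp[obs:length(h$k)]),
    less      = logsumexp(h$lp[1:obs])
  )
  min(lp, 0)
}

# Expected value of the noncentral (Fisher) hypergeometric distribution
# with log odds ratio `lpsi`, computed in log space on the central
# support.
nchyper_mean <- function(h, lpsi) {
  lw <- h$lp + h$k * lpsi
  lw <- lw - logsumexp(lw)
  sum(exp(lw) * h$k)
}

#' Conditional maximum-likelihood odds ratio
#'
#' The odds-ratio value maximizing the noncentral hypergeometric
#' likelihood of `n11` given the table margins — the estimate
#' conventionally reported alongside a Fisher exact test (it is what
#' `fisher.test()$estimate` reports). Found by monotone root-finding on
#' the expected-count equation `E_psi[n11] = n11` to relative tolerance
#' 1e-8. When `n11` sits on the boundary of its support the estimate is
#' `0` (lower bound) or `Inf` (upper bound).
#'
#' @inheritParams ror
#' @return Positive double (possibly 0 or `Inf`).
#' @export
conditional_mle_or <- function(table) {
  x <- as_table_cells(table)
  h <- hyper_support(x)
  if (x[1] == min(h$k)) return(0)
  if (x[1] == max(h$k)) return(Inf)
  f <- function(lpsi) nchyper_mean(h, lpsi) - x[1]
  lo <- -1; hi <- 1
  while (f(lo) > 0) lo <- lo * 2
  while (f(hi) < 0) hi <- hi * 2
  root <- uniroot(f, c(lo, hi), tol = 1e-10)$root
  exp(root)
}

#' Score a counts table: ROR, log-space Fisher P, significance rank
#'
#' Runs [ror()] and [fisher_exact_log()] on every row of a counts table
#' (as produced by [count_all()] or read from a TSV of printed
#' contingency rows), then ranks by significance via [rank_signals()].
#' Rows with an empty drug margin (`n11 + n10 = 0`, drugs absent from
#' the corpus) get `ror = NaN`, `log10_p = 0` and sort last.
#'
#' Bonferroni and Benjamini-Hochberg columns (`p_bonferroni`, `p_bh`,
#' computed from the display-scale P) are emitted for context only and
#' never used for ordering — the ranking uses the unadjusted log10 P.
#'
#' @param counts Tibble with columns `drug`, `n11`, `n10`, `n01`, `n00`.
#' @param alternative Sidedness passed to [fisher_exact_log()].
#' @param haldane Passed to [ror()].
#' @return A tibble of class `signal_results`: the counts columns plus
#'   `ror`, `log10_p`, `p_display` (0 when `log10_p < -308`),
#'   `p_bonferroni`, `p_bh` and `rank`, sorted by rank.
#' @export
signal_screen <- function(counts, alternative = "two.sided", haldane = FALSE) {
  need <- c("drug", "n11", "n10", "n01", "n00")
  stopifnot(all(need %in% names(counts)))
  n <- nrow(counts)
  ror_v <- numeric(n)
  lp10 <- numeric(n)
  for (i in seq_len(n)) {
    cells <- as.numeric(counts[i, c("n11", "n10", "n01", "n00")])
    ror_v[i] <- ror(cells, haldane = haldane)
    lp10[i] <- if (cells[1] + cells[2] == 0) {
      0  # absent drug: no evidence either way
    } else {
      fisher_exact_log(cells, alternative) / log(10)
    }
  }
  out <- tibble::as_tibble(counts)
  out$ror <- ror_v
  out$log10_p <- lp10
  out$p_display <- ifelse(lp10 >= -308, 10^lp10, 0)
  out$p_bonferroni <- pmin(1, out$p_display * n)
  out$p_bh <- p.adjust(out$p_display, method = "BH")
  rank_signals(out)
}

#' Rank signal results by significance
#'
#' Ascending by `log10_p`; ties broken by descending `ror`, then
#' ascending drug name. Ranking in log10-P space preserves the ordering
#' of signals whose display P values all underflow to zero.
#'
#' @param results Tibble with columns `drug`, `ror`, `log10_p`.
#' @return The tibble sorted into rank order with a `rank` column 1..N,
#'   classed `signal_results`.
#' @export
rank_signals <- function(results) {
  stopifnot(all(c("drug", "ror", "log10_p") %in% names(results)))
  neg_ror <- -results$ror
  neg_ror[is.nan(neg_ror)] <- Inf  # undefined ROR loses every tie
  o <- order(results$log10_p, neg_ror, results$drug)
  out <- results[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  class(out) <- unique(c("signal_results", class(out)))
  out
}
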