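# Synthetic FAERS-like corpora with known ground-truth association
# strength, plus exact reconstruction of corpora from printed 2x2 tables.
#
# Event model: a report's event odds are o0 * prod(theta_d) over the
# drugs it carries (odds multiply). theta_d = 1 encodes a null drug; for
# rare usage the single-drug marginal ROR converges to theta_d, which is
# what the recovery tests exploit. This is a reporting model, not a
# causal one.

default_decoy_reactions <- c(
  "nausea", "headache", "dizziness", "rash", "fatigue", "vomiting",
  "pruritus", "diarrhoea", "insomnia", "dyspnoea", "arthralgia", "cough"
)

#' Specification of a synthetic report corpus
#'
#' @param n_reports Number of reports to generate.
#' @param drugs Data frame with columns `name` (canonical drug name),
#'   `usage_prob` (per-report inclusion probability, in (0,1)) and
#'   `theta` (true odds multiplier; 1 = no association).
#' @param background_odds Event odds `o0` for a report carrying only
#'   null drugs (must be positive and finite).
#' @param decoy_reactions Pool of non-event reaction terms; must not
#'   intersect the event terms, so negative matches are exercised.
#' @param event_terms An [event_term_set()]; generated event reports
#'   carry one of these terms.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return An object of class `synthetic_corpus_spec`.
#' @export
synthetic_corpus_spec <- function(n_reports,
                                  drugs,
                                  background_odds = 0.02,
                                  decoy_reactions = default_decoy_reactions,
                                  event_terms = event_term_set(),
                                  seed = 1L) {
  drugs <- tibble::as_tibble(drugs)
  stopifnot(all(c("name", "usage_prob", "theta") %in% names(drugs)),
            n_reports >= 1, length(seed) == 1L)
  drugs$name <- squish(drugs$name)
  if (any(!nzchar(drugs$name))) stop("empty drug name in spec", call. = FALSE)
  if (anyDuplicated(drugs$name)) stop("duplicate drug name in spec", call. = FALSE)
  if (any(drugs$usage_prob <= 0 | drugs$usage_prob >= 1)) {
    stop("usage_prob must lie in (0, 1)", call. = FALSE)
  }
  if (any(!is.finite(drugs$theta) | drugs$theta <= 0)) {
    stop("theta must be positive and finite", call. = FALSE)
  }
  if (!is.finite(background_odds) || background_odds <= 0) {
    stop("background_odds must be positive and finite", call. = FALSE)
  }
  boost <- drugs$name[drugs$theta > 1]
  worst <- background_odds * prod(drugs$theta[drugs$theta > 1])
  if (!is.finite(worst) || worst / (1 + worst) >= 1) {
    stop("event probability overflows for drug combination: ",
         paste(boost, collapse = " + "), call. = FALSE)
  }
  decoy_reactions <- unique(squish(decoy_reactions))
  if (any(decoy_reactions %in% event_terms$terms)) {
    stop("decoy reactions must not contain event terms", call. = FALSE)
  }
  structure(list(n_reports = as.integer(n_reports), drugs = drugs,
                 background_odds = background_odds,
                 decoy_reactions = decoy_reactions,
                 event_terms = event_terms, seed = as.integer(seed)),
            class = "synthetic_corpus_spec")
}

#' Generate a synthetic report corpus
#'
#' For each report, drugs are drawn independently with their
#' `usage_prob` (empty draws are rejected and redrawn, so every report
#' names at least one drug); the event occurs with odds
#' `o0 * prod(theta_d)` over the report's drugs. Every report carries
#' one decoy reaction; event reports additionally carry one event term.
#' Byte-identical regeneration from the same spec and seed; the
#' generator identity and seed are recorded in the corpus metadata.
#'
#' @param spec A [synthetic_corpus_spec()].
#' @param seed Optional override of `spec$seed`.
#' @return A [report_corpus()] of `spec$n_reports` weight-1 reports.
#' @export
generate_corpus <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_corpus_spec"))
  set.seed(seed)
  n <- spec$n_reports
  D <- nrow(spec$drugs)
  p <- spec$drugs$usage_prob
  ltheta <- log(spec$drugs$theta)

  mem <- matrix(runif(n * D), n, D) < matrix(p, n, D, byrow = TRUE)
  empty <- which(rowSums(mem) == 0L)
  while (length(empty)) {  # rejection: redraw empty rows
    redraw <- matrix(runif(length(empty) * D), length(empty), D) <
      matrix(p, length(empty), D, byrow = TRUE)
    mem[empty, ] <- redraw
    empty <- empty[rowSums(redraw) == 0L]
  }

  odds <- spec$background_odds * exp(as.vector(mem %*% ltheta))
  event <- runif(n) < odds / (1 + odds)

  decoy <- sample(spec$decoy_reactions, n, replace = TRUE)
  evterm <- sample(spec$event_terms$terms, n, replace = TRUE)
  rx_row <- c(seq_len(n), which(event))
  rx <- c(decoy, evterm[event])
  reactions <- split(rx, factor(rx_row, levels = seq_len(n)))

  hit <- which(mem, arr.ind = TRUE)
  drugs <- split(spec$drugs$name[hit[, 2]], factor(hit[, 1], levels = seq_len(n)))

  # inputs are clean by spec validation, so skip per-report checks
  new_report_corpus(
    report_id = paste0("s", seq_len(n)),
    drugs = unname(drugs),
    reactions = unname(reactions),
    weight = rep(1L, n),
    metadata = list(generator = "rorscreen::generate_corpus",
                    seed = as.integer(seed),
                    spec_hash = config_hash(spec[c("n_reports", "drugs",
                                                   "background_odds")]))
  )
}

#' Reconstruct a weighted corpus realizing a printed contingency table
#'
#' Emits up to four weighted pseudo-report groups — (drug, event) with
#' weight `n11`, (drug, decoy) with `n10`, (background, event) with
#' `n01`, (background, decoy) with `n00` — such that
#' [count_cooccurrence()] on the result reproduces the input table
#' exactly. This lets corpus-scale printed rows (millions of reports) be
#' screened without materializing them.
#'
#' @param drug Canonical drug name for the "with drug" cells.
#' @param table A [contingency_table()] or numeric `c(n11,n10,n01,n00)`.
#' @param terms An [event_term_set()]; its first term marks event rows.
#' @param placeholder Drug name used for the "without drug" cells.
#' @param decoy Reaction term used for the "without event" cells.
#' @return A [report_corpus()] with total weight equal to the table sum.
#' @export
corpus_from_table <- function(drug, table,
                              terms = event_term_set(),
                              placeholder = "background product",
                              decoy = "no event reported") {
  x <- as_table_cells(table)
  ev <- terms$terms[1]
  if (squish(decoy) %in% terms$terms) {
    stop("decoy reaction collides with the event terms", call. = FALSE)
  }
  if (squish(placeholder) == squish(drug)) {
    stop("placeholder drug collides with the study drug", call. = FALSE)
  }
  groups <- list(
    list(id = "cell-n11", drugs = drug, reactions = ev, w = x[1]),
    list(id = "cell-n10", drugs = drug, reactions = decoy, w = x[2]),
    list(id = "cell-n01", drugs = placeholder, reactions = ev, w = x[3]),
    list(id = "cell-n00", drugs = placeholder, reactions = decoy, w = x[4])
  )
  groups <- Filter(function(g) g$w > 0, groups)
  if (length(groups) == 0L) stop("all cells are zero", call. = FALSE)
  report_corpus(
    report_id = vapply(groups, `[[`, "", "id"),
    drugs = lapply(groups, `[[`, "drugs"),
    reactions = lapply(groups, `[[`, "reactions"),
    weight = vapply(groups, `[[`, 0, "w")
  )
}
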