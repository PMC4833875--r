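# Contingency-table counting: one pass over the corpus yields, for each
# study drug, the 2x2 table of drug co-occurrence x event occurrence.
# n01/n00 come from corpus totals by subtraction, so the cost is
# O(reports x drugs-per-report), not O(reports x drugs).

#' A 2x2 drug x event contingency table
#'
#' Cell layout follows the disproportionality convention: `n11` reports
#' with drug and event, `n10` with drug without event, `n01` without drug
#' with event, `n00` with neither.
#'
#' @param n11,n10,n01,n00 Non-negative integer counts (stored as doubles;
#'   corpus-scale cell products exceed 32-bit range).
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(n11, n10, n01, n00) {
  cells <- c(n11 = n11, n10 = n10, n01 = n01, n00 = n00)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != floor(cells))) {
    stop("contingency cells must be non-negative integers", call. = FALSE)
  }
  structure(as.list(as.numeric(cells)) |> setNames(names(cells)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$n11, x$n10, x$n01, x$n00), 2, 2, byrow = TRUE,
              dimnames = list(c("drug", "no drug"), c("event", "no event")))
  print(m)
  invisible(x)
}

as_table_cells <- function(table) {
  if (inherits(table, "contingency_table")) {
    c(table$n11, table$n10, table$n01, table$n00)
  } else if (is.numeric(table) && length(table) == 4L) {
    as.numeric(table)
  } else {
    stop("expected a contingency_table or a numeric vector of 4 cells",
         call. = FALSE)
  }
}

# Flatten a corpus into vectorized pieces shared by the counting
# operations: per-row weight, per-row event flag, and the deduplicated
# (row, canonical drug) pairs with combination products dropped from
# drug membership.
flatten_corpus <- function(corpus, terms, rules) {
  stopifnot(inherits(corpus, "report_corpus"),
            inherits(terms, "event_term_set"),
            inherits(rules, "normalization_rules"))
  n <- nrow(corpus)
  w <- as.numeric(corpus$weight)

  rx_len <- lengths(corpus$reactions)
  rx <- squish(unlist(corpus$reactions, use.names = FALSE))
  rx_row <- rep.int(seq_len(n), rx_len)
  event <- logical(n)
  event[unique(rx_row[rx %in% terms$terms])] <- TRUE

  d_len <- lengths(corpus$drugs)
  d_raw <- unlist(corpus$drugs, use.names = FALSE)
  d_row <- rep.int(seq_len(n), d_len)
  keep <- !is_combination(d_raw, rules)
  d_raw <- d_raw[keep]
  d_row <- d_row[keep]
  d_can <- normalize_drug_name(d_raw, rules)
  dedup <- !duplicated(paste0(d_row, "\r", d_can))

  list(n = n, weight = w, event = event,
       drug_row = d_row[dedup], drug = d_can[dedup],
       total = sum(w), total_event = sum(w[event]))
}

#' Count drug/event co-occurrence for one drug
#'
#' Each report contributes its weight to exactly one cell, determined by
#' (canonical drug in the report's normalized drug set?) x (reaction set
#' matches the event?). Duplicate drug entries within a report count
#' once (set semantics).
#'
#' @param corpus A [report_corpus()] (non-empty).
#' @param drug Canonical drug name (as produced by
#'   [normalize_drug_name()]).
#' @param terms An [event_term_set()].
#' @param rules A [normalization_rules()] object.
#' @return A [contingency_table()].
#' @export
count_cooccurrence <- function(corpus, drug,
                               terms = event_term_set(),
                               rules = normalization_rules()) {
  counts <- count_all(corpus, drug, terms, rules)
  contingency_table(counts$n11, counts$n10, counts$n01, counts$n00)
}

#' Count co-occurrence tables for a list of study drugs in one pass
#'
#' @param corpus A [report_corpus()] (non-empty).
#' @param drugs Character vector of canonical drug names, no duplicates.
#' @param terms An [event_term_set()].
#' @param rules A [normalization_rules()] object.
#' @return A tibble with columns `drug`, `n11`, `n10`, `n01`, `n00` and
#'   `absent` (`TRUE` for drugs never seen in the corpus, whose
#'   `n11 = n10 = 0`). Every row's four cells sum to the corpus total.
#' @export
count_all <- function(corpus, drugs,
                      terms = event_term_set(),
                      rules = normalization_rules()) {
  if (!inherits(corpus, "report_corpus") || nrow(corpus) == 0L) {
    stop("corpus must be a non-empty report_corpus", call. = FALSE)
  }
  drugs <- as.character(drugs)
  if (length(drugs) == 0L) stop("drugs must be non-empty", call. = FALSE)
  dup <- unique(drugs[duplicated(drugs)])
  if (length(dup)) {
    stop("duplicate drug in study list: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  fl <- flatten_corpus(corpus, terms, rules)

  n11 <- n10 <- numeric(length(drugs))
  names(n11) <- names(n10) <- drugs
  sel <- fl$drug %in% drugs
  if (any(sel)) {
    rw <- fl$weight[fl$drug_row[sel]]
    ev <- fl$event[fl$drug_row[sel]]
    dg <- factor(fl$drug[sel], levels = drugs)
    n11[] <- vapply(split(rw * ev, dg), sum, 0)
    n10[] <- vapply(split(rw * !ev, dg), sum, 0)
  }
  n01 <- fl$total_event - n11
  n00 <- fl$total - fl$total_event - n10
  stopifnot(all(n11 + n10 + n01 + n00 == fl$total))
  tibble::tibble(drug = drugs, n11 = unname(n11), n10 = unname(n10),
                 n01 = unname(n01), n00 = unname(n00),
                 absent = unname(n11 + n10 == 0))
}

#' Read / write the counts interchange table
#'
#' TSV with columns `drug`, `n11`, `n10`, `n01`, `n00` (extra columns are
#' preserved), the format emitted by [count_all()] and accepted directly
#' by [signal_screen()] — so printed contingency rows can be fed in
#' verbatim without a corpus. Lines starting with `#` are comments.
#'
#' @param path TSV file path.
#' @return `read_counts_tsv`: a tibble. `write_counts_tsv`: `path`,
#'   invisibly.
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("drug", "n11", "n10", "n01", "n00")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("counts TSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' @rdname read_counts_tsv
#' @param counts Tibble/data frame of counts.
#' @param comments Optional character vector written as leading `#` lines.
#' @export
write_counts_tsv <- function(counts, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  write.table(counts, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
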