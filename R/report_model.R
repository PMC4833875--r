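# Report corpus container and JSONL / openFDA readers.
#
# A corpus is a tibble with one row per (possibly weighted) report:
#   report_id <chr>, drugs <list of chr>, reactions <list of chr>,
#   weight <int>. Weighted rows stand for `weight` identical reports, so a
# corpus matching multi-million-report margins fits in a handful of rows.

clean_set <- function(x, what, id) {
  x <- trimws(as.character(unlist(x, use.names = FALSE)))
  if (length(x) == 0L || any(!nzchar(x))) {
    stop(sprintf("report '%s': %s must be non-empty strings", id, what),
         call. = FALSE)
  }
  unique(x)
}

#' Construct an adverse-event report corpus
#'
#' @param report_id Character vector of unique report identifiers.
#' @param drugs List of character vectors, one per report; raw drug-name
#'   strings as reported (normalization is a separate stage).
#' @param reactions List of character vectors of reaction terms, one per
#'   report.
#' @param weight Positive integer multiplicity per report (default 1); a
#'   weighted row counts as that many identical reports downstream.
#' @param metadata Optional named list recorded on the corpus (e.g.
#'   generator identity and seed) and serialized as a header comment by
#'   [write_reports_jsonl()].
#'
#' @return A tibble of class `report_corpus` with columns `report_id`,
#'   `drugs`, `reactions`, `weight`. Iteration (row) order is the input
#'   order and is preserved by the readers and writer.
#' @export
report_corpus <- function(report_id, drugs, reactions,
                          weight = rep(1L, length(report_id)),
                          metadata = list()) {
  report_id <- as.character(report_id)
  n <- length(report_id)
  if (length(drugs) != n || length(reactions) != n || length(weight) != n) {
    stop("report_id, drugs, reactions and weight must have equal length",
         call. = FALSE)
  }
  dup <- report_id[duplicated(report_id)]
  if (length(dup)) {
    stop("duplicate report_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(weight)) || any(weight < 1) || any(weight != floor(weight))) {
    stop("weight must be a positive integer", call. = FALSE)
  }
  drugs <- Map(clean_set, drugs, "drugs", report_id)
  reactions <- Map(clean_set, reactions, "reactions", report_id)
  new_report_corpus(report_id, unname(drugs), unname(reactions),
                    as.integer(weight), metadata)
}

# Internal constructor without per-report validation, for callers whose
# inputs are clean by construction (the synthetic generator validates
# names once at spec level, not per report).
new_report_corpus <- function(report_id, drugs, reactions, weight,
                              metadata = list()) {
  out <- tibble::tibble(report_id = report_id, drugs = drugs,
                        reactions = reactions, weight = weight)
  class(out) <- c("report_corpus", class(out))
  attr(out, "metadata") <- metadata
  out
}

#' Total number of reports in a corpus (sum of weights)
#' @param corpus A `report_corpus`.
#' @return Numeric scalar: the number of reports the corpus represents.
#' @export
n_reports <- function(corpus) {
  stopifnot(inherits(corpus, "report_corpus"))
  sum(as.numeric(corpus$weight))
}

#' @export
print.report_corpus <- function(x, ...) {
  cat(sprintf("<report_corpus> %d rows representing %s reports\n",
              nrow(x), format(n_reports(x), big.mark = ",")))
  NextMethod()
}

#' Read a corpus from canonical JSONL
#'
#' One JSON object per line with keys `report_id` (string), `drugs`
#' (array of strings), `reactions` (array of strings) and optional
#' `weight` (positive integer, default 1). Lines starting with `#` are
#' metadata comments and are skipped.
#'
#' @param path Path to a JSONL file.
#' @return A [report_corpus()] preserving line order.
#' @export
read_reports_jsonl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(report_corpus(character(), list(), list(), integer()))
  }
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
      error = function(e) {
        stop(sprintf("malformed JSON on line %d of %s: %s",
                     lineno[i], path, conditionMessage(e)), call. = FALSE)
      }
    )
    for (key in c("report_id", "drugs", "reactions")) {
      if (is.null(rec[[key]])) {
        stop(sprintf("line %d of %s: missing key '%s'", lineno[i], path, key),
             call. = FALSE)
      }
    }
    recs[[i]] <- rec
  }
  report_corpus(
    report_id = vapply(recs, function(r) as.character(r$report_id)[1], ""),
    drugs = lapply(recs, `[[`, "drugs"),
    reactions = lapply(recs, `[[`, "reactions"),
    weight = vapply(recs, function(r) {
      if (is.null(r$weight)) 1L else as.integer(r$weight)
    }, 1L)
  )
}

#' Write a corpus as canonical JSONL
#'
#' Inverse of [read_reports_jsonl()]: the round trip reproduces the corpus
#' exactly (ids, sets, weights). Corpus metadata, if any, is written as a
#' single leading `#` comment line that readers ignore.
#'
#' @param corpus A [report_corpus()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reports_jsonl <- function(corpus, path) {
  stopifnot(inherits(corpus, "report_corpus"))
  meta <- attr(corpus, "metadata")
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(meta)) {
    writeLines(paste0("# rorscreen-meta ",
                      jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)),
               con, useBytes = TRUE)
  }
  for (i in seq_len(nrow(corpus))) {
    rec <- list(report_id = corpus$report_id[[i]],
                drugs = corpus$drugs[[i]],
                reactions = corpus$reactions[[i]])
    if (corpus$weight[[i]] != 1L) rec$weight <- corpus$weight[[i]]
    writeLines(as.character(jsonlite::toJSON(rec, auto_unbox = FALSE)),
               con, useBytes = TRUE)
  }
  invisible(path)
}

openfda_one <- function(rec) {
  id <- rec[["safetyreportid"]]
  if (is.null(id) || !nzchar(trimws(as.character(id)[1]))) {
    return(NULL)
  }
  patient <- rec[["patient"]]
  drug_entries <- patient[["drug"]]
  reaction_entries <- patient[["reaction"]]
  drugs <- character()
  for (d in drug_entries) {
    gn <- unlist(d[["openfda"]][["generic_name"]], use.names = FALSE)
    nm <- if (length(gn)) gn else d[["medicinalproduct"]]
    nm <- trimws(as.character(unlist(nm, use.names = FALSE)))
    drugs <- c(drugs, nm[nzchar(nm)])
  }
  reactions <- character()
  for (r in reaction_entries) {
    term <- trimws(as.character(unlist(r[["reactionmeddrapt"]], use.names = FALSE)))
    reactions <- c(reactions, term[nzchar(term)])
  }
  if (length(drugs) == 0L || length(reactions) == 0L) return(NULL)
  list(report_id = as.character(id)[1],
       drugs = unique(drugs), reactions = unique(reactions))
}

#' Import openFDA-style adverse-event records
#'
#' Accepts either the `results` array of an openFDA drug/event query
#' response (a JSON array, possibly wrapped in `{"results": [...]}`) or a
#' JSON-lines dump of such records. Each record must carry
#' `safetyreportid`, `patient.drug[]` and `patient.reaction[]`; for each
#' drug entry the `openfda.generic_name` values are used when present,
#' otherwise `medicinalproduct`; reaction terms come from
#' `reactionmeddrapt`. Records missing an id, drugs or reactions are
#' skipped with a warning; the number skipped is recorded in the
#' `skipped` attribute of the result.
#'
#' @param path Path to the JSON (or JSON-lines) file.
#' @return A [report_corpus()]; `attr(, "skipped")` holds the skip tally.
#' @export
read_reports_openfda <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
               collapse = "\n")
  parsed <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                     error = function(e) NULL)
  if (is.null(parsed)) {
    # fall back to one record per line
    lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(trimws(lines))]
    parsed <- lapply(lines, jsonlite::fromJSON, simplifyVector = FALSE)
  } else if (!is.null(parsed[["results"]])) {
    parsed <- parsed[["results"]]
  } else if (!is.null(names(parsed)) && !is.null(parsed[["safetyreportid"]])) {
    parsed <- list(parsed)
  }
  recs <- lapply(parsed, openfda_one)
  skipped <- sum(vapply(recs, is.null, TRUE))
  if (skipped > 0L) {
    warning(sprintf(
      "skipped %d openFDA record(s) missing safetyreportid, drugs or reactions",
      skipped), call. = FALSE)
  }
  recs <- recs[!vapply(recs, is.null, TRUE)]
  out <- report_corpus(
    report_id = vapply(recs, `[[`, "", "report_id"),
    drugs = lapply(recs, `[[`, "drugs"),
    reactions = lapply(recs, `[[`, "reactions")
  )
  attr(out, "skipped") <- skipped
  out
}
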