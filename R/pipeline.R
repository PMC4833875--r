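# Pipeline stages (simulate / screen / evaluate) with files as the only
# interface between them, so each stage is independently testable and a
# thin command-line wrapper (inst/cli/rorscreen) can drive them.

# 32-bit FNV-1a over the canonical JSON of a config: a short, stable
# fingerprint stamped into every output for auditability.
fnv1a32 <- function(txt) {
  bytes <- utf8ToInt(enc2utf8(txt)) %% 256
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256  # xor touches only the low byte (b < 256)
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply by the FNV prime 16777619 = 2^24 + 403,
    # kept exact in doubles: (h * 2^24) mod 2^32 = (h mod 2^8) * 2^24
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Stable fingerprint of a configuration object
#'
#' @param config Any jsonlite-serializable R object.
#' @return 8-hex-digit string; identical configs hash identically.
#' @export
config_hash <- function(config) {
  fnv1a32(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                        digits = NA, force = TRUE)))
}

log_msg <- function(...) message(sprintf(...))

#' Simulate a synthetic report corpus to a JSONL file
#'
#' @param config List (or path to a JSON file) with fields `n_reports`,
#'   `drugs` (records with `name`, `usage_prob`, `theta`),
#'   `background_odds`, `seed`, and optionally `decoy_reactions` and
#'   `event_terms`.
#' @param out Output JSONL path.
#' @return `out`, invisibly. The file embeds the generator seed and spec
#'   hash as a `#` metadata header; rerunning with the same config
#'   produces identical bytes.
#' @export
run_simulate <- function(config, out) {
  config <- load_config(config)
  spec <- synthetic_corpus_spec(
    n_reports = config$n_reports,
    drugs = tibble::as_tibble(as.data.frame(config$drugs)),
    background_odds = config$background_odds %||% 0.02,
    decoy_reactions = config$decoy_reactions %||% default_decoy_reactions,
    event_terms = event_term_set(config$event_terms %||%
                                   event_term_set()$terms),
    seed = config$seed %||% 1L
  )
  corpus <- generate_corpus(spec)
  write_reports_jsonl(corpus, out)
  log_msg("simulated %d reports -> %s", nrow(corpus), out)
  invisible(out)
}

#' Screen a corpus (or a counts table) into ranked signal results
#'
#' Runs normalization -> counting -> statistics -> ranking and writes a
#' TSV sorted by rank, with the config hash and exclusion tallies as
#' `#` header comments. Accepts either a JSONL corpus plus a study-drug
#' list, or a bare counts TSV (e.g. printed contingency rows) screened
#' directly.
#'
#' @param reports Path to a canonical JSONL corpus (or a
#'   [report_corpus()]); ignored when `counts` is given.
#' @param counts Path to a counts TSV (or a counts tibble).
#' @param drugs Character vector of raw study-drug names, or path to a
#'   one-name-per-line file. Combination products are excluded (tallied
#'   to stderr); duplicate canonical names are an error.
#' @param out Output TSV path (optional).
#' @param event_terms Character vector of event reaction terms.
#' @param rules A [normalization_rules()] object.
#' @param alternative,haldane Passed to [signal_screen()].
#' @return The ranked `signal_results` tibble, invisibly if `out` is
#'   written.
#' @export
run_screen <- function(reports = NULL, counts = NULL, drugs = NULL,
                       out = NULL,
                       event_terms = event_term_set()$terms,
                       rules = normalization_rules(),
                       alternative = "two.sided", haldane = FALSE) {
  terms <- event_term_set(event_terms)
  if (!is.null(counts)) {
    tab <- if (is.character(counts)) read_counts_tsv(counts) else counts
    log_msg("screening %d counts rows (no corpus)", nrow(tab))
  } else {
    if (is.null(reports) || is.null(drugs)) {
      stop("need either a counts table or reports + a drug list", call. = FALSE)
    }
    corpus <- if (is.character(reports)) read_reports_jsonl(reports) else reports
    if (is.character(drugs) && length(drugs) == 1L && file.exists(drugs)) {
      drugs <- readLines(drugs, warn = FALSE)
      drugs <- trimws(drugs[nzchar(trimws(drugs))])
    }
    combo <- is_combination(drugs, rules)
    if (any(combo)) {
      log_msg("excluded %d combination product(s) from the drug list",
              sum(combo))
    }
    study <- normalize_drug_name(drugs[!combo], rules)
    if (length(study) == 0L) {
      stop("drug list is empty after combination exclusion", call. = FALSE)
    }
    dup <- unique(study[duplicated(study)])
    if (length(dup)) {
      stop("duplicate drug after normalization: ",
           paste(dup, collapse = ", "), call. = FALSE)
    }
    log_msg("read %s reports; counting %d drugs",
            format(n_reports(corpus), big.mark = ","), length(study))
    tab <- count_all(corpus, study, terms, rules)
    if (any(tab$absent)) {
      log_msg("%d drug(s) absent from the corpus", sum(tab$absent))
    }
  }
  signals <- signal_screen(tab, alternative = alternative, haldane = haldane)
  if (!is.null(out)) {
    cfg <- list(event_terms = terms$terms, alternative = alternative,
                haldane = haldane, salt_suffixes = rules$salt_suffixes)
    write_counts_tsv(signals, out,
                     comments = c(paste0("config-hash ", config_hash(cfg)),
                                  paste0("event-terms ",
                                         paste(terms$terms, collapse = "; "))))
    log_msg("wrote %d ranked signals -> %s", nrow(signals), out)
    return(invisible(signals))
  }
  signals
}

#' Evaluate a significance ranking against indication labels
#'
#' @param signals Path to a signals TSV (from [run_screen()]) or a
#'   `signal_results` tibble.
#' @param labels Path to a labels TSV with columns `drug`, `rel` (0/1),
#'   or such a data frame; must cover every ranked drug.
#' @param out Optional path for the metrics JSON.
#' @param threshold,fpr_max,k,convention See [ranking_metrics()].
#' @return The metrics list (also serialized to `out` with the config
#'   hash and package version when `out` is given).
#' @export
run_evaluate <- function(signals, labels, out = NULL,
                         threshold = 1e-10, fpr_max = 0.1, k = 20,
                         convention = "rel1") {
  if (is.character(signals)) {
    signals <- rank_signals(read_counts_tsv(signals))
  }
  if (is.character(labels)) {
    labels <- tibble::as_tibble(read.delim(labels, sep = "\t",
                                           comment.char = "#",
                                           stringsAsFactors = FALSE))
  }
  metrics <- ranking_metrics(signals, labels, fpr_max = fpr_max, k = k,
                             threshold = threshold, convention = convention)
  if (!is.null(out)) {
    payload <- c(metrics, list(
      n_drugs = nrow(signals),
      config_hash = config_hash(metrics[c("threshold", "fpr_max", "k",
                                          "convention")]),
      version = as.character(utils::packageVersion("rorscreen"))
    ))
    jsonlite::write_json(payload, out, auto_unbox = TRUE, digits = NA)
    log_msg("wrote metrics -> %s", out)
  }
  metrics
}

load_config <- function(config) {
  if (is.character(config)) {
    jsonlite::fromJSON(config, simplifyVector = TRUE)
  } else {
    config
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Top-20 hypotension co-occurrence counts (published screen excerpt)
#'
#' The 20 drugs most significantly co-reported with hypotension events
#' in a 2004-2013 FAERS extract of ~3.8 million reports, with their
#' printed 2x2 counts, reporting odds ratios, P values and
#' approved-antihypertensive status. Shipped as a plain-text fixture
#' (`inst/extdata/hypotension_top20.tsv`) and used as the worked example
#' throughout the package: feeding its count columns through
#' [signal_screen()] reproduces the printed ROR column.
#'
#' @return Tibble with columns `drug`, `atc_code`, `printed_p`,
#'   `printed_ror`, `n11`, `n10`, `n01`, `n00`, `antihypertensive`.
#' @export
hypotension_top20 <- function() {
  path <- system.file("extdata", "hypotension_top20.tsv",
                      package = "rorscreen", mustWork = TRUE)
  read_counts_tsv(path)
}
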