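# Drug-name normalization and event-term matching.
#
# Raw FAERS-style generic names mix case, whitespace and salt/ester
# suffixes ("Abacavir Sulfate" vs "abacavir"); normalization maps these to
# one canonical single-ingredient identity. Multi-ingredient products
# ("oxycodone and acetaminophen") are detected so they can be excluded
# from the study-drug list without dropping their reports.

# Common salt/ester/counter-ion tokens stripped from the end of a name.
# Configuration, not a dictionary: the list is editable and recorded in
# output metadata so the merging rule is auditable.
default_salt_suffixes <- c(
  "sulfate", "sulphate", "tartrate", "bitartrate", "hydrochloride", "hcl",
  "sodium", "disodium", "potassium", "dipotassium", "calcium", "maleate",
  "besylate", "mesylate", "tosylate", "fumarate", "succinate", "citrate",
  "phosphate", "diphosphate", "acetate", "bromide", "chloride", "nitrate",
  "oxalate", "lactate", "gluconate", "pamoate", "propionate", "valerate",
  "stearate", "palmitate", "edisylate", "hydrobromide"
)

squish <- function(x) gsub("\\s+", " ", trimws(tolower(x)))

#' Normalization rules for raw drug-name strings
#'
#' @param salt_suffixes Lowercase tokens stripped repeatedly from the end
#'   of a name (right-to-left) during [normalize_drug_name()].
#' @param combination_markers Regular expressions (applied to the
#'   lowercased, whitespace-collapsed name) whose match flags a
#'   multi-ingredient product. The defaults flag the token `" and "` and a
#'   `/` or `+` between alphabetic tokens.
#' @return An object of class `normalization_rules`.
#' @export
normalization_rules <- function(salt_suffixes = default_salt_suffixes,
                                combination_markers = c(
                                  " and ",
                                  "[[:alpha:]]\\s*/\\s*[[:alpha:]]",
                                  "[[:alpha:]]\\s*\\+\\s*[[:alpha:]]"
                                )) {
  salt_suffixes <- unique(squish(salt_suffixes))
  stopifnot(all(nzchar(salt_suffixes)), length(combination_markers) >= 1L)
  structure(list(salt_suffixes = salt_suffixes,
                 combination_markers = combination_markers),
            class = "normalization_rules")
}

#' Event definition as a set of reaction terms
#'
#' Terms are stored lowercase and whitespace-collapsed; matching is exact
#' set membership, never substring (see [match_event()]). The default is
#' the hypotension event definition: "hypotension", "blood pressure
#' decreased", "orthostatic hypotension".
#'
#' @param terms Character vector of reaction terms (MedDRA-style
#'   preferred terms).
#' @return An object of class `event_term_set`.
#' @export
event_term_set <- function(terms = c("hypotension",
                                     "blood pressure decreased",
                                     "orthostatic hypotension")) {
  terms <- unique(squish(terms))
  if (length(terms) == 0L || any(!nzchar(terms))) {
    stop("event term set must contain non-empty terms", call. = FALSE)
  }
  structure(list(terms = terms), class = "event_term_set")
}

norm_one <- function(x, suffixes) {
  toks <- strsplit(x, " ", fixed = TRUE)[[1]]
  while (length(toks) > 1L && toks[length(toks)] %in% suffixes) {
    toks <- toks[-length(toks)]
  }
  paste(toks, collapse = " ")
}

#' Map a raw drug name to its canonical single-ingredient form
#'
#' Lowercases, collapses whitespace, then repeatedly strips trailing
#' salt/ester tokens (right-to-left) until none of the listed tokens
#' remains. Never returns an empty name: if stripping would consume every
#' token, the last one is kept (so the drug "potassium" survives even
#' though "potassium" is also a counter-ion token). Idempotent and
#' case-insensitive. Vectorized over `raw`.
#'
#' @param raw Character vector of non-empty raw names.
#' @param rules A [normalization_rules()] object.
#' @return Character vector of canonical names.
#' @export
normalize_drug_name <- function(raw, rules = normalization_rules()) {
  x <- squish(raw)
  if (any(!nzchar(x))) stop("drug name must be non-empty", call. = FALSE)
  u <- unique(x)
  canon <- vapply(u, norm_one, "", suffixes = rules$salt_suffixes,
                  USE.NAMES = FALSE)
  canon[match(x, u)]
}

#' Does a raw name denote a multi-ingredient combination product?
#'
#' @inheritParams normalize_drug_name
#' @return Logical vector: `TRUE` where any combination marker matches.
#'   Combination names are excluded from study-drug lists; the reports
#'   carrying them are kept.
#' @export
is_combination <- function(raw, rules = normalization_rules()) {
  x <- squish(raw)
  if (any(!nzchar(x))) stop("drug name must be non-empty", call. = FALSE)
  hit <- rep(FALSE, length(x))
  for (marker in rules$combination_markers) {
    hit <- hit | grepl(marker, x)
  }
  hit
}

#' Does a report's reaction set contain the event?
#'
#' Exact membership after lowercasing and whitespace collapsing; never a
#' substring match, so "orthostatic hypotension" in the term set does not
#' make "orthostatic hypotension aggravated" an event.
#'
#' @param reactions Non-empty character vector of reaction terms from one
#'   report.
#' @param terms An [event_term_set()].
#' @return Single logical.
#' @export
match_event <- function(reactions, terms = event_term_set()) {
  stopifnot(inherits(terms, "event_term_set"))
  if (length(reactions) == 0L) stop("reactions must be non-empty", call. = FALSE)
  any(squish(reactions) %in% terms$terms)
}
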