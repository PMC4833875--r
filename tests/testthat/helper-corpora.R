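# Shared fixture builders. All randomness is seeded locally so tests are
# deterministic.

random_corpus <- function(n, seed, drug_pool = paste0("drug", 1:6),
                          reaction_pool = c("hypotension", "nausea",
                                            "headache", "rash"),
                          max_weight = 1L) {
  set.seed(seed)
  report_corpus(
    report_id = paste0("r", seq_len(n)),
    drugs = lapply(seq_len(n), function(i)
      sample(drug_pool, sample(1:3, 1))),
    reactions = lapply(seq_len(n), function(i)
      sample(reaction_pool, sample(1:2, 1))),
    weight = sample(seq_len(max_weight), n, replace = TRUE)
  )
}

# spell out a small corpus: list of c(drugs..., "|", reactions...)
corpus_of <- function(...) {
  rows <- list(...)
  split_row <- function(r) {
    bar <- which(r == "|")
    list(drugs = r[seq_len(bar - 1)], reactions = r[-seq_len(bar)])
  }
  parts <- lapply(rows, split_row)
  report_corpus(
    report_id = paste0("r", seq_along(parts)),
    drugs = lapply(parts, `[[`, "drugs"),
    reactions = lapply(parts, `[[`, "reactions")
  )
}

table1_counts <- function() hypotension_top20()

# exact two-sided Fisher P by enumeration with binomial coefficients --
# the independent oracle for fisher_exact_log on small tables
fisher_enum <- function(n11, n10, n01, n00) {
  r1 <- n11 + n10; c1 <- n11 + n01; N <- n11 + n10 + n01 + n00
  lo <- max(0, c1 - (N - r1)); hi <- min(r1, c1)
  k <- lo:hi
  pr <- choose(r1, k) * choose(N - r1, c1 - k) / choose(N, c1)
  sum(pr[pr <= pr[n11 - lo + 1] * (1 + 1e-7)])
}
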