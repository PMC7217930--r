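# Fixture builders shared across the test files. Everything is built in
# code; no binary fixtures.

# Quick literature-dialect association tibble.
lit_df <- function(subject, object, n_documents, confidence,
                   subject_kind = "gene", object_kind = "disease") {
  tibble::tibble(
    subject = subject, subject_kind = subject_kind,
    object = object, object_kind = object_kind,
    n_documents = n_documents, confidence = confidence
  )
}

lit_records <- function(...) as_associations(lit_df(...), "literature",
                                             quiet = TRUE)

score_records <- function(subject, object, score,
                          subject_kind = "drug",
                          object_kind = "disease") {
  as_associations(
    data.frame(subject = subject, subject_kind = subject_kind,
               object = object, object_kind = object_kind,
               score = score),
    "score", quiet = TRUE
  )
}

# Two disjoint triangles {a,b,c} and {d,e,f}.
two_triangles <- function() {
  data.frame(from = c("a", "b", "c", "d", "e", "f"),
             to   = c("b", "c", "a", "e", "f", "d"))
}

# Erdos-Renyi edge list with guaranteed >= 1 edge, named nodes.
random_edges <- function(n_nodes, p_edge = 0.4) {
  pairs <- t(utils::combn(n_nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  if (!any(keep)) keep[sample.int(nrow(pairs), 1)] <- TRUE
  data.frame(from = paste0("v", pairs[keep, 1]),
             to = paste0("v", pairs[keep, 2]))
}

# Brute-force upper-tail hypergeometric by enumerating every outcome of
# the 2x2 table (independent oracle for the log-factorial path).
enum_hyper_tail <- function(k, K, n, N) {
  xs <- max(0, n - (N - K)):min(K, n)
  probs <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
  sum(probs[xs >= k])
}

# Random GMT-style collection over a gene universe.
random_collection <- function(universe, n_terms, set_size, seed) {
  withr::with_seed(seed, {
    sets <- lapply(seq_len(n_terms), function(i) {
      sample(universe, set_size)
    })
    names(sets) <- sprintf("term%03d", seq_len(n_terms))
    gene_set_collection(sets)
  })
}
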