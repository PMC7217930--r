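#' Gene-set over-representation with a permutation combined score
#'
#' For every term in the collection (intersected with the universe), the
#' overlap p-value is the one-sided exact hypergeometric tail -- the
#' same implementation as [fisher_overlap()]. The rank-deviation score z
#' compares the term's observed p-value rank against the rank
#' distribution obtained from `n_permutations` random queries of the
#' same size: \eqn{z = (\bar{r}_{perm} - r_{obs}) / sd(r_{perm})}. The
#' combined score is \eqn{-\ln(p) \times z}, non-positive whenever the
#' term ranks no better than chance. Terms with zero overlap are
#' reported with p = 1, z computed as usual, never dropped.
#'
#' @param query_genes Character vector of query genes, subset of
#'   `universe`, non-empty.
#' @param collection A `reponet_gene_sets` collection (see
#'   [read_gmt()]).
#' @param universe Character vector of background genes.
#' @param n_permutations Number of random same-size queries used for the
#'   rank null; 0 disables the z/combined-score computation (z = 0).
#'   Default 1000.
#' @param seed Integer seed for the permutation draws.
#' @return Tibble of class `reponet_enrichment`, sorted by
#'   `combined_score` descending: `term`, `k`, `set_size`, `query_size`,
#'   `p_value`, `z`, `combined_score`, `retained` (the default
#'   retention rule of [filter_enriched()]).
#' @export
enrich <- function(query_genes, collection, universe,
                   n_permutations = 1000, seed = 1L) {
  query_genes <- unique(query_genes)
  universe <- unique(universe)
  if (length(query_genes) == 0) abort("Empty query gene list.")
  extra <- setdiff(query_genes, universe)
  if (length(extra) > 0) {
    abort(paste0("Query gene(s) outside the universe: ",
                 paste(head(extra, 10), collapse = ", ")))
  }
  if (length(collection) == 0) {
    warn("Empty gene-set collection; returning no results.")
    return(empty_enrichment())
  }
  sets <- lapply(collection, function(s) intersect(s, universe))
  keep <- lengths(sets) > 0
  if (!any(keep)) {
    warn("No collection term overlaps the universe; returning no results.")
    return(empty_enrichment())
  }
  sets <- sets[keep]
  N <- length(universe)
  n_q <- length(query_genes)
  set_sizes <- lengths(sets)

  # indicator matrix terms x universe genes for fast overlap counting
  M <- matrix(FALSE, length(sets), N,
              dimnames = list(names(sets), universe))
  for (j in seq_along(sets)) M[j, sets[[j]]] <- TRUE

  p_for_query <- function(q_ind) {
    k <- as.integer(M %*% q_ind)
    vapply(seq_along(k), function(j) {
      tb <- tail_tables[[as.character(set_sizes[j])]]
      tb[k[j] + 1]
    }, 0)
  }
  tail_tables <- lapply(
    setNames(nm = as.character(unique(set_sizes))),
    function(sz) hyper_tail_table(as.integer(sz), n_q, N)
  )

  q_ind <- as.numeric(universe %in% query_genes)
  p_obs <- p_for_query(q_ind)
  k_obs <- as.integer(M %*% q_ind)
  r_obs <- rank(p_obs, ties.method = "average")

  if (n_permutations > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(split_seed(seed, "enrich-permutations"))
    rank_sum <- numeric(length(sets))
    rank_sq <- numeric(length(sets))
    for (b in seq_len(n_permutations)) {
      perm_ind <- numeric(N)
      perm_ind[sample.int(N, n_q)] <- 1
      r <- rank(p_for_query(perm_ind), ties.method = "average")
      rank_sum <- rank_sum + r
      rank_sq <- rank_sq + r^2
    }
    mean_r <- rank_sum / n_permutations
    var_r <- (rank_sq - n_permutations * mean_r^2) /
      max(1, n_permutations - 1)
    sd_r <- sqrt(pmax(var_r, 0))
    z <- ifelse(sd_r > 0, (mean_r - r_obs) / sd_r, 0)
  } else {
    z <- rep(0, length(sets))
  }
  combined <- -log(p_obs) * z
  combined[p_obs >= 1] <- 0

  out <- tibble(
    term = names(sets),
    k = k_obs,
    set_size = unname(set_sizes),
    query_size = n_q,
    p_value = p_obs,
    z = z,
    combined_score = combined,
    retained = combined >= 20 & p_obs < 0.01
  )
  out <- arrange(out, desc(.data$combined_score), .data$p_value,
                 .data$term)
  structure(out, class = c("reponet_enrichment", class(out)),
            n_permutations = n_permutations, seed = seed,
            universe_size = N)
}

empty_enrichment <- function() {
  out <- tibble(
    term = character(0), k = integer(0), set_size = integer(0),
    query_size = integer(0), p_value = numeric(0), z = numeric(0),
    combined_score = numeric(0), retained = logical(0)
  )
  structure(out, class = c("reponet_enrichment", class(out)))
}

#' Retention filter for enrichment results
#'
#' Keeps terms with combined score at least `min_combined` (inclusive)
#' and p-value strictly below `max_p`; row order is preserved.
#'
#' @param results Tibble from [enrich()].
#' @param min_combined Inclusive combined-score threshold. Default 20.
#' @param max_p Strict p-value threshold. Default 0.01.
#' @return The retained rows.
#' @export
filter_enriched <- function(results, min_combined = 20, max_p = 0.01) {
  keep <- results$combined_score >= min_combined &
    results$p_value < max_p
  results[keep, , drop = FALSE]
}
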