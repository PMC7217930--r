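#' Upper-tail hypergeometric probability via log-factorials
#'
#' Returns \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(N, K, n):
#' drawing `n` items from a universe of `N` containing `K` marked items.
#' Each point mass is evaluated on the log scale
#' (\eqn{\log C(K,x) + \log C(N-K, n-x) - \log C(N,n)}) so large tables
#' do not overflow.
#'
#' @param k Observed overlap count (can be a vector).
#' @param K Number of marked items in the universe.
#' @param n Draw size.
#' @param N Universe size.
#' @return \eqn{P(X \ge k)}, in (0, 1].
#' @export
#' @examples
#' hypergeom_tail(4, 5, 5, 20)  # 76/15504
hypergeom_tail <- function(k, K, n, N) {
  stopifnot(length(K) == 1, length(n) == 1, length(N) == 1)
  if (K < 0 || n < 0 || N < 1 || K > N || n > N) {
    abort("Inconsistent counts: require 0 <= K, n <= N and N >= 1.")
  }
  if (any(k < 0 | k > pmin(K, n))) {
    abort("Inconsistent counts: require 0 <= k <= min(K, n).")
  }
  upper <- min(K, n)
  x <- max(0, n - (N - K)):upper
  logp <- lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
  p <- exp(logp)
  # tail sums accumulated from the top so small tails lose no precision
  tails <- rev(cumsum(rev(p)))
  out <- vapply(k, function(ki) {
    if (ki <= x[1]) 1 else tails[match(ki, x)]
  }, 0)
  pmin(out, 1)
}

# Full tail lookup for repeated queries with fixed (K, n, N): element
# j+1 is P(X >= j), j = 0..min(K, n).
hyper_tail_table <- function(K, n, N) {
  upper <- min(K, n)
  lower <- max(0, n - (N - K))
  x <- lower:upper
  p <- exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n))
  tails <- rev(cumsum(rev(p)))
  out <- numeric(upper + 1)
  out[seq_len(lower)] <- 1  # k below support -> whole tail
  out[x + 1] <- pmin(tails, 1)
  out
}

#' Exact significance of the overlap between two sets
#'
#' Builds the 2x2 table from \eqn{|A \cap B|}, \eqn{|A \setminus B|},
#' \eqn{|B \setminus A|} and the rest of the universe, and returns the
#' one-sided (enrichment) exact p-value together with
#' \eqn{-\log_{10} p}. A two-sided mode (summing all tables with point
#' probability not exceeding the observed one, the usual exact-test
#' convention) is available.
#'
#' @param set_a,set_b Character vectors, subsets of `universe`.
#' @param universe Character vector defining the background.
#' @param alpha Significance level for the `significant` flag (strict
#'   `<`). Default 0.01.
#' @param alternative `"greater"` (overlap enrichment, default) or
#'   `"two.sided"`.
#' @return One-row tibble with columns `k`, `K_a`, `K_b`, `N`,
#'   `p_value`, `neg_log10_p`, `significant`.
#' @export
#' @examples
#' u <- paste0("G", 1:20)
#' fisher_overlap(u[1:5], u[c(1:4, 6)], u)
fisher_overlap <- function(set_a, set_b, universe, alpha = 0.01,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  universe <- unique(universe)
  if (length(universe) < 1) abort("Universe must be non-empty.")
  out_a <- setdiff(set_a, universe)
  out_b <- setdiff(set_b, universe)
  if (length(out_a) + length(out_b) > 0) {
    abort(paste0("Set element(s) outside the universe: ",
                 paste(head(c(out_a, out_b), 10), collapse = ", ")))
  }
  k <- length(intersect(set_a, set_b))
  K_a <- length(set_a)
  K_b <- length(set_b)
  N <- length(universe)
  if (alternative == "greater") {
    p <- hypergeom_tail(k, K_a, K_b, N)
  } else {
    lower <- max(0, K_b - (N - K_a))
    x <- lower:min(K_a, K_b)
    px <- exp(lchoose(K_a, x) + lchoose(N - K_a, K_b - x) -
                lchoose(N, K_b))
    p_obs <- px[match(k, x)]
    p <- min(1, sum(px[px <= p_obs * (1 + 1e-7)]))
  }
  tibble(
    k = k, K_a = K_a, K_b = K_b, N = N,
    p_value = p, neg_log10_p = -log10(p),
    significant = p < alpha
  )
}

#' Pairwise disease-overlap significance matrix
#'
#' Runs [fisher_overlap()] on every unordered pair of disease entity
#' sets against a shared universe (by default the union of all sets,
#' i.e. the network's own entity catalogue), reporting
#' \eqn{-\log_{10} p} and a strict `p < alpha` significance flag.
#'
#' @param sets Tibble from [disease_entity_sets()] (columns `disease`,
#'   `entities`) or a named list of character vectors.
#' @param universe Background entity vector; default `NULL` means the
#'   union of all sets.
#' @param alpha Significance level (strict). Default 0.01.
#' @param alternative Passed to [fisher_overlap()].
#' @return A tibble of class `reponet_overlap`, one row per unordered
#'   pair: `disease_a`, `disease_b`, `k`, `K_a`, `K_b`, `N`, `p_value`,
#'   `neg_log10_p`, `significant`. Attributes record the universe size,
#'   alpha and sidedness.
#' @export
pairwise_overlap_matrix <- function(sets, universe = NULL, alpha = 0.01,
                                    alternative = c("greater",
                                                    "two.sided")) {
  alternative <- match.arg(alternative)
  if (is.data.frame(sets)) {
    sets <- setNames(sets$entities, sets$disease)
  }
  if (length(sets) < 2) abort("Need at least two disease sets.")
  universe <- universe %||% unique(unlist(sets, use.names = FALSE))
  pairs <- utils::combn(names(sets), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]
    b <- pairs[2, j]
    res <- fisher_overlap(sets[[a]], sets[[b]], universe, alpha = alpha,
                          alternative = alternative)
    dplyr::bind_cols(tibble(disease_a = a, disease_b = b), res)
  })
  out <- bind_rows(rows)
  structure(out, class = c("reponet_overlap", class(out)),
            universe_size = length(universe), alpha = alpha,
            alternative = alternative)
}

#' Benjamini--Hochberg adjustment for an overlap table
#'
#' Off by default in the pipeline (the retention rule is a raw p
#' cutoff); provided for users who want FDR control across pairs.
#'
#' @param overlap A `reponet_overlap` tibble.
#' @param alpha FDR level for the adjusted significance flag.
#' @return The table with columns `p_adjusted` and
#'   `significant_adjusted` appended.
#' @export
adjust_overlap <- function(overlap, alpha = 0.01) {
  overlap$p_adjusted <- stats::p.adjust(overlap$p_value, method = "BH")
  overlap$significant_adjusted <- overlap$p_adjusted < alpha
  overlap
}
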