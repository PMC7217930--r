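#' Tidy a knowledge network into its edge table
#'
#' @param x A `reponet_network`.
#' @param ... Unused.
#' @return Tibble of edges with evidence columns.
#' @method tidy reponet_network
#' @export
tidy.reponet_network <- function(x, ...) {
  as_tibble(x$edges)
}

#' One-row summary of a knowledge network
#'
#' @param x A `reponet_network`.
#' @param ... Unused.
#' @return Tibble with node/edge counts per kind.
#' @method glance reponet_network
#' @export
glance.reponet_network <- function(x, ...) {
  kinds <- table(x$nodes$kind)
  out <- tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
                dialect = x$dialect)
  for (k in names(kinds)) out[[paste0("n_", k)]] <- as.integer(kinds[[k]])
  out
}

#' Tidy a partition into a node/community table
#'
#' @param x A `reponet_partition`.
#' @param ... Unused.
#' @return Tibble with columns `node`, `community`.
#' @method tidy reponet_partition
#' @export
tidy.reponet_partition <- function(x, ...) {
  tibble(node = x$node, community = x$community)
}

#' One-row summary of a partition
#'
#' @param x A `reponet_partition`.
#' @param ... Unused.
#' @return Tibble with modularity, community count, resolution, seed.
#' @method glance reponet_partition
#' @export
glance.reponet_partition <- function(x, ...) {
  tibble(
    modularity = attr(x, "modularity"),
    n_communities = length(unique(x$community)),
    n_nodes = nrow(x),
    resolution = attr(x, "resolution"),
    seed = attr(x, "seed")
  )
}

#' Tidy a module eigengene into a sample/value table
#'
#' @param x A `reponet_eigengene`.
#' @param ... Unused.
#' @return Tibble with columns `sample`, `value`.
#' @method tidy reponet_eigengene
#' @export
tidy.reponet_eigengene <- function(x, ...) {
  tibble(sample = names(x$vector) %||%
           as.character(seq_along(x$vector)),
         value = unname(x$vector))
}

#' One-row summary of a module eigengene
#'
#' @param x A `reponet_eigengene`.
#' @param ... Unused.
#' @return Tibble with module, gene count and variance explained.
#' @method glance reponet_eigengene
#' @export
glance.reponet_eigengene <- function(x, ...) {
  tibble(module = x$module, n_genes = x$n_genes,
         var_explained = x$var_explained)
}

#' Tidy a repositioning run into its candidate table
#'
#' @param x A `reponet_run`.
#' @param ... Unused.
#' @return The candidate tibble.
#' @method tidy reponet_run
#' @export
tidy.reponet_run <- function(x, ...) {
  as_tibble(x$candidates)
}

#' One-row summary of a repositioning run
#'
#' @param x A `reponet_run`.
#' @param ... Unused.
#' @return Tibble of headline stage counts.
#' @method glance reponet_run
#' @export
glance.reponet_run <- function(x, ...) {
  s <- x$report$stages
  tibble(
    n_diseases = s$diseases,
    n_exclusive_genes = s$exclusive_genes,
    n_hubs = s$hubs,
    n_target_genes = s$target_genes,
    n_drugs_searched = s$drugs_in,
    n_candidates = s$candidates_retained,
    n_removed = s$drugs_removed
  )
}
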