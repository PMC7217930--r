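#' Heatmap of pairwise overlap significance
#'
#' Tiles of \eqn{-\log_{10} p} for every disease pair, with significant
#' pairs (strict `p < alpha`) outlined.
#'
#' @param object A `reponet_overlap` tibble from
#'   [pairwise_overlap_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot reponet_overlap
#' @export
autoplot.reponet_overlap <- function(object, ...) {
  sym <- bind_rows(
    as_tibble(object),
    rename(as_tibble(object), disease_a = "disease_b",
           disease_b = "disease_a")
  )
  ggplot2::ggplot(sym, ggplot2::aes(.data$disease_a, .data$disease_b,
                                    fill = .data$neg_log10_p)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = sym[sym$significant, , drop = FALSE],
                       colour = "black", linewidth = 0.6,
                       fill = NA) +
    ggplot2::scale_fill_viridis_c(name = expression(-log[10] ~ p)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Disease-pair overlap significance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 45, hjust = 1))
}

#' Community size bars for a partition
#'
#' @param object A `reponet_partition`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot reponet_partition
#' @export
autoplot.reponet_partition <- function(object, ...) {
  df <- dplyr::count(as_tibble(object), .data$community)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$community), .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "community", y = "nodes",
      title = paste0("Louvain partition (Q = ",
                     format(attr(object, "modularity"), digits = 4),
                     ")")
    ) +
    ggplot2::theme_minimal()
}

#' kME distribution with the hub cutoff
#'
#' @param object A `reponet_kme` tibble from [kme_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot reponet_kme
#' @export
autoplot.reponet_kme <- function(object, ...) {
  cutoff <- attr(object, "hub_cutoff") %||% 0.5
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$kme, fill = .data$is_hub)) +
    ggplot2::geom_histogram(bins = 40, boundary = 0) +
    ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "firebrick"),
                               name = "hub") +
    ggplot2::labs(x = "kME (module membership)", y = "genes",
                  title = "Module membership and hub calls") +
    ggplot2::theme_minimal()
}

#' Top enriched terms by combined score
#'
#' @param object A `reponet_enrichment` tibble from [enrich()].
#' @param n_terms Number of top terms shown. Default 15.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot reponet_enrichment
#' @export
autoplot.reponet_enrichment <- function(object, n_terms = 15, ...) {
  df <- head(as_tibble(object), n_terms)
  df$term <- factor(df$term, levels = rev(df$term))
  ggplot2::ggplot(df, ggplot2::aes(.data$combined_score, .data$term,
                                   fill = .data$retained)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "darkorange"),
                               name = "retained") +
    ggplot2::labs(x = "combined score", y = NULL,
                  title = "Gene-set enrichment") +
    ggplot2::theme_minimal()
}

#' Candidate evidence overview
#'
#' @param object A `reponet_candidates` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot reponet_candidates
#' @export
autoplot.reponet_candidates <- function(object, ...) {
  df <- as_tibble(object)
  ev <- if ("n_documents" %in% names(df)) "n_documents" else "score"
  ggplot2::ggplot(df, ggplot2::aes(.data[[ev]],
                                   stats::reorder(.data$drug,
                                                  -.data$rank))) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$disease)) +
    ggplot2::labs(x = ev, y = NULL,
                  title = "Retained repositioning candidates") +
    ggplot2::theme_minimal()
}
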