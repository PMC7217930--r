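#' Apply the evidence retention filter to association records
#'
#' Literature-dialect records are kept when they have at least
#' `min_documents` supporting documents AND a confidence strictly above
#' `min_confidence_pct`. Score-dialect records are kept when the overall
#' association score is strictly above `min_score`. Input order is
#' preserved.
#'
#' @param records A `reponet_associations` tibble (see
#'   [as_associations()]).
#' @param min_documents Minimum document count (inclusive). Default 2.
#' @param min_confidence_pct Confidence threshold, percent, strict.
#'   Default 50.
#' @param min_score Score threshold, strict. Default 0.5.
#' @return The retained records, same class and dialect.
#' @export
#' @examples
#' df <- data.frame(
#'   subject = c("G1", "G2", "G3"), subject_kind = "gene",
#'   object = "depression", object_kind = "disease",
#'   n_documents = c(2L, 3L, 1L), confidence = c(51, 50, 99)
#' )
#' rec <- as_associations(df, "literature")
#' filter_associations(rec)  # keeps only G1
filter_associations <- function(records, min_documents = 2,
                                min_confidence_pct = 50,
                                min_score = 0.5) {
  dialect <- attr(records, "dialect")
  if (is.null(dialect)) {
    abort("`records` must come from as_associations()/read_associations().")
  }
  keep <- if (dialect == "literature") {
    records$n_documents >= min_documents &
      records$confidence > min_confidence_pct
  } else {
    records$score > min_score
  }
  out <- records[keep, , drop = FALSE]
  structure(out, class = class(records), dialect = dialect)
}

#' Build a bipartite knowledge network from filtered associations
#'
#' One node per distinct entity, one undirected edge per record, with the
#' record's evidence carried as edge attributes. All records must share a
#' single (subject_kind, object_kind) pair; the bipartition between the
#' two kinds is recorded.
#'
#' @param records Filtered `reponet_associations` of one kind pair.
#' @return An object of class `reponet_network`: a list with elements
#'   `graph` (igraph), `nodes`, `edges` (tibbles), `bipartition`,
#'   `dialect`.
#' @export
build_network <- function(records) {
  dialect <- attr(records, "dialect")
  if (is.null(dialect)) {
    abort("`records` must come from as_associations()/read_associations().")
  }
  if (nrow(records) == 0) abort("Cannot build a network from zero records.")
  pair <- unique(paste0(records$subject_kind, "->", records$object_kind))
  if (length(pair) > 1) {
    abort(paste0("Records mix kind pairs: ", paste(pair, collapse = ", ")))
  }
  loops <- which(records$subject == records$object)
  if (length(loops) > 0) {
    abort(paste0("Self-loop record(s) (subject == object) at row(s): ",
                 paste(head(loops, 10), collapse = ", ")))
  }
  subject_kind <- records$subject_kind[1]
  object_kind <- records$object_kind[1]

  nodes <- bind_rows(
    tibble(node = unique(records$subject), kind = subject_kind),
    tibble(node = unique(records$object), kind = object_kind)
  )
  evidence_cols <- intersect(c("n_documents", "confidence", "score"),
                             names(records))
  edges <- tibble(
    from = records$subject,
    to = records$object
  )
  edges <- dplyr::bind_cols(edges, records[evidence_cols])
  n_dup <- nrow(edges) - nrow(distinct(edges, .data$from, .data$to))
  if (n_dup > 0) {
    inform(paste0("Collapsed ", n_dup, " duplicate edge(s)."))
    edges <- edges |>
      group_by(.data$from, .data$to) |>
      summarise(across(dplyr::all_of(evidence_cols), max),
                .groups = "drop")
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = as.data.frame(nodes)
  )
  structure(
    list(graph = g, nodes = nodes, edges = edges,
         bipartition = c(subject_kind, object_kind), dialect = dialect),
    class = "reponet_network"
  )
}

#' @export
print.reponet_network <- function(x, ...) {
  cat("<knowledge network> ", paste(x$bipartition, collapse = " -- "),
      ": ", nrow(x$nodes), " nodes, ", nrow(x$edges), " edges (",
      x$dialect, " evidence)\n", sep = "")
  invisible(x)
}

#' Per-disease entity sets of a knowledge network
#'
#' Maps each disease node to the set of its neighbours (the genes or
#' drugs associated with it after filtering). Diseases with no surviving
#' association are retained with an empty set.
#'
#' @param network A `reponet_network` whose bipartition includes
#'   `"disease"`.
#' @return A tibble with columns `disease`, `entities` (list of character
#'   vectors) and `n`.
#' @export
disease_entity_sets <- function(network) {
  stopifnot(inherits(network, "reponet_network"))
  if (!"disease" %in% network$bipartition) {
    abort("Network bipartition has no 'disease' side.")
  }
  diseases <- network$nodes$node[network$nodes$kind == "disease"]
  # edges run entity -> disease or disease -> entity; orient them
  e <- network$edges
  is_dis_from <- e$from %in% diseases
  dis <- ifelse(is_dis_from, e$from, e$to)
  ent <- ifelse(is_dis_from, e$to, e$from)
  sets <- split(ent, factor(dis, levels = diseases))
  tibble(
    disease = diseases,
    entities = lapply(sets, function(s) sort(unique(s))),
    n = lengths(sets)
  )
}

#' Entities exclusively associated with a single disease
#'
#' An entity is exclusive to disease D when it belongs to D's set and to
#' no other disease's set among the diseases present in the input. The
#' resulting sets are pairwise disjoint.
#'
#' @param sets Tibble from [disease_entity_sets()] (columns `disease`,
#'   `entities`).
#' @return A tibble of the same shape restricted to exclusive entities.
#' @export
#' @examples
#' sets <- tibble::tibble(
#'   disease = c("D1", "D2"),
#'   entities = list(c("G1", "G2"), c("G2", "G3"))
#' )
#' exclusive_entities(sets)
exclusive_entities <- function(sets) {
  stopifnot(is.data.frame(sets), nrow(sets) >= 1)
  all_ent <- unlist(sets$entities, use.names = FALSE)
  counts <- table(all_ent)
  uniq <- names(counts)[counts == 1]
  tibble(
    disease = sets$disease,
    entities = lapply(sets$entities, function(s) sort(intersect(s, uniq))),
    n = vapply(sets$entities, function(s) length(intersect(s, uniq)), 0L)
  )
}
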