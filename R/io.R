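#' Build a validated association table
#'
#' An association table is a tibble of subject--object assertions
#' (gene--disease, drug--disease or drug--gene), one of two evidence
#' dialects:
#'
#' * `"literature"` -- text-mining style records carrying `n_documents`
#'   (supporting document count) and `confidence` (a 0--100 percentage);
#' * `"score"` -- records carrying a single overall association `score`
#'   in \[0, 1\] (the convention of public target--disease platforms).
#'
#' Duplicate `(subject, object)` rows are merged keeping the maximum of
#' each evidence field, and the number of merges is reported.
#'
#' @param df Data frame with columns `subject`, `subject_kind`, `object`,
#'   `object_kind` and either (`n_documents`, `confidence`) or `score`.
#'   An optional `source` column is carried through.
#' @param dialect `"literature"` or `"score"`.
#' @param synonyms Optional two-column data frame (old label, canonical
#'   label) applied to subject and object labels before validation.
#' @param quiet Suppress the merge message.
#' @return A tibble of class `reponet_associations` with attribute
#'   `dialect`.
#' @export
#' @examples
#' df <- data.frame(
#'   subject = c("apoe", "APP"), subject_kind = "gene",
#'   object = "Alzheimer's disease", object_kind = "disease",
#'   n_documents = c(5L, 3L), confidence = c(80, 60)
#' )
#' as_associations(df, "literature")
as_associations <- function(df, dialect = c("literature", "score"),
                            synonyms = NULL, quiet = FALSE) {
  dialect <- match.arg(dialect)
  df <- as_tibble(df)

  required <- c("subject", "subject_kind", "object", "object_kind")
  evidence_cols <- if (dialect == "literature") {
    c("n_documents", "confidence")
  } else {
    "score"
  }
  missing_cols <- setdiff(c(required, evidence_cols), names(df))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Association table is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  other_dialect <- setdiff(c("n_documents", "confidence", "score"),
                           evidence_cols)
  present_other <- intersect(other_dialect, names(df))
  if (length(present_other) > 0 &&
      any(!is.na(unlist(df[present_other])))) {
    abort(paste0(
      "Dialect '", dialect, "' forbids populated column(s): ",
      paste(present_other, collapse = ", ")
    ))
  }

  check_kind_pairs(df$subject_kind, df$object_kind)

  df$subject <- apply_synonyms(
    normalize_label(df$subject, df$subject_kind), synonyms)
  df$object <- apply_synonyms(
    normalize_label(df$object, df$object_kind), synonyms)

  if (any(!nzchar(df$subject)) || any(!nzchar(df$object))) {
    abort("Empty entity label after whitespace trimming.")
  }

  if (dialect == "literature") {
    df$n_documents <- as.integer(df$n_documents)
    df$confidence <- as.numeric(df$confidence)
    bad <- which(is.na(df$n_documents) | df$n_documents < 0 |
                   is.na(df$confidence) |
                   df$confidence < 0 | df$confidence > 100)
    if (length(bad) > 0) {
      abort(paste0(
        "Invalid evidence values (n_documents must be an integer >= 0, ",
        "confidence in [0, 100]) at row(s): ",
        paste(head(bad, 10), collapse = ", ")
      ))
    }
  } else {
    df$score <- as.numeric(df$score)
    bad <- which(is.na(df$score) | df$score < 0 | df$score > 1)
    if (length(bad) > 0) {
      abort(paste0("Invalid score values (must lie in [0, 1]) at row(s): ",
                   paste(head(bad, 10), collapse = ", ")))
    }
  }
  if (!"source" %in% names(df)) df$source <- NA_character_

  keep <- c(required, evidence_cols, "source")
  df <- df[keep]

  if (nrow(df) == 0) {
    return(structure(df, class = c("reponet_associations", class(df)),
                     dialect = dialect, n_merged = 0L))
  }
  n_before <- nrow(df)
  df <- df |>
    group_by(.data$subject, .data$subject_kind,
             .data$object, .data$object_kind) |>
    summarise(
      across(dplyr::any_of(c("n_documents", "confidence", "score")),
             ~ max(.x)),
      source = paste(sort(unique(stats::na.omit(.data$source))),
                     collapse = ";"),
      .groups = "drop"
    ) |>
    mutate(source = ifelse(nzchar(.data$source), .data$source,
                           NA_character_))
  n_merged <- n_before - nrow(df)
  if (n_merged > 0 && !quiet) {
    inform(paste0("Merged ", n_merged,
                  " duplicate association row(s) keeping max evidence."))
  }
  structure(df, class = c("reponet_associations", class(df)),
            dialect = dialect, n_merged = n_merged)
}

#' Read an association table from TSV
#'
#' @param path Path to a UTF-8 TSV with header columns `subject`,
#'   `subject_kind`, `object`, `object_kind` and the evidence columns of
#'   the chosen dialect.
#' @inheritParams as_associations
#' @return A validated `reponet_associations` tibble.
#' @seealso [as_associations()] for the schema and merge rule.
#' @export
read_associations <- function(path, dialect = c("literature", "score"),
                              synonyms = NULL, quiet = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  as_associations(df, dialect, synonyms = synonyms, quiet = quiet)
}

#' Write an association table to TSV
#'
#' @param records A `reponet_associations` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(records, path) {
  readr::write_tsv(as_tibble(records), path, progress = FALSE)
  invisible(path)
}

#' Read a gene expression matrix from TSV
#'
#' First column holds gene labels; the remaining columns are numeric
#' sample values. At least two samples are required (a single sample
#' leaves correlations undefined).
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix, genes in rows, samples in columns.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (ncol(df) < 3) {
    abort("Expression table needs a gene column plus >= 2 sample columns.")
  }
  genes <- df[[1]]
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0) {
    abort(paste0("Duplicate gene label(s): ", paste(dup, collapse = ", ")))
  }
  vals <- as.matrix(df[-1])
  num <- matrix(suppressWarnings(as.numeric(vals)), nrow = nrow(vals),
                dimnames = list(NULL, colnames(vals)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    b <- bad[1, ]
    abort(paste0("Non-numeric expression value at gene '", genes[b[1]],
                 "', sample '", colnames(vals)[b[2]], "'."))
  }
  rownames(num) <- genes
  num
}

#' Write an expression matrix to TSV
#'
#' @param mat Numeric matrix, genes in rows (rownames), samples in
#'   columns (colnames).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  df <- tibble::as_tibble(mat, rownames = "gene")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene labels. Genes are de-duplicated within each set.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors of class
#'   `reponet_gene_sets`, with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warn("Empty GMT file; returning an empty collection.")
    return(gene_set_collection(list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    abort(paste0("GMT line(s) with fewer than 3 fields: line ",
                 paste(short, collapse = ", ")))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1)
  desc <- vapply(fields, `[[`, "", 2)
  gene_set_collection(sets, descriptions = desc)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character gene vectors.
#' @param descriptions Optional character vector, one per set.
#' @return A `reponet_gene_sets` object.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (length(sets) > 0) {
    if (is.null(names(sets)) || anyDuplicated(names(sets))) {
      abort("Gene-set names must be present and unique.")
    }
    empty <- names(sets)[lengths(sets) == 0]
    if (length(empty) > 0) {
      abort(paste0("Empty gene set(s): ", paste(empty, collapse = ", ")))
    }
    sets <- lapply(sets, unique)
  }
  structure(sets, class = "reponet_gene_sets",
            descriptions = descriptions %||% rep("", length(sets)))
}

#' Write a gene-set collection to GMT
#'
#' @param collection A `reponet_gene_sets` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  desc <- attr(collection, "descriptions") %||% rep("", length(collection))
  lines <- mapply(function(nm, d, genes) {
    paste(c(nm, d, genes), collapse = "\t")
  }, names(collection), desc, collection)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Export a knowledge network to GraphML or JSON
#'
#' Node attributes include `kind` (and `module` when a partition has been
#' attached); edge attributes carry the surviving evidence fields.
#' Reading the file back reproduces the node and edge sets exactly.
#'
#' @param network A [knowledge_network] object.
#' @param path Output path.
#' @param format `"graphml"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("graphml", "json")) {
  if (!inherits(network, "reponet_network")) {
    abort("`network` must be a knowledge_network object.")
  }
  if (!is.character(format) ||
      !all(format %in% c("graphml", "json"))) {
    abort(paste0("Unknown network format tag: ",
                 paste(setdiff(format, c("graphml", "json")),
                       collapse = ", ")))
  }
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network$graph, path, format = "graphml")
  } else {
    out <- list(
      nodes = network$nodes,
      edges = network$edges,
      bipartition = network$bipartition,
      dialect = network$dialect
    )
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' Read a knowledge network written by [write_network()]
#'
#' @param path File path.
#' @param format `"graphml"` or `"json"`.
#' @return A list with `nodes` and `edges` tibbles.
#' @export
read_network <- function(path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- as_tibble(igraph::as_data_frame(g, what = "vertices"))
    edges <- as_tibble(igraph::as_data_frame(g, what = "edges"))
    nodes <- rename(nodes, node = "name")
    list(nodes = nodes, edges = edges)
  } else {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    list(nodes = as_tibble(raw$nodes), edges = as_tibble(raw$edges))
  }
}

#' Write a candidate table to TSV
#'
#' Fixed column order (drug, target gene, disease, evidence, audit flags,
#' rank); rows ordered by rank then drug name so repeated runs are
#' byte-identical.
#'
#' @param table A candidate tibble from [filter_candidates()] or
#'   [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(table, path) {
  cols <- c("drug", "target_gene", "disease",
            intersect(c("n_documents", "confidence", "score"),
                      names(table)),
            "passed_evidence", "single_target", "not_known_for_pnds",
            "manual_exclusion_applied", "trial_annotation", "rank")
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols) > 0) {
    abort(paste0("Candidate table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- table[cols]
  out <- arrange(out, .data$rank, .data$drug)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a drug-to-clinical-trial annotation table
#'
#' @param path TSV with columns `drug` and `trial_id`.
#' @return A tibble with those two columns.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (!all(c("drug", "trial_id") %in% names(df))) {
    abort("Trials table must have columns 'drug' and 'trial_id'.")
  }
  as_tibble(df[c("drug", "trial_id")])
}
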