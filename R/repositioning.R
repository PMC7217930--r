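#' Intersect disease-exclusive genes with co-expression hubs
#'
#' The cascade's target genes are those exclusively associated with a
#' single disease AND called as co-expression module hubs. Diseases
#' whose intersection is empty are retained with an empty set (and
#' reported), so downstream accounting stays complete.
#'
#' @param exclusive Tibble from [exclusive_entities()] (columns
#'   `disease`, `entities`).
#' @param hubs Character vector of hub genes (see [module_hubs()]).
#' @param quiet Suppress the empty-set message.
#' @return Tibble with columns `disease`, `genes` (list), `n`.
#' @export
select_target_genes <- function(exclusive, hubs, quiet = FALSE) {
  stopifnot(is.data.frame(exclusive))
  genes <- lapply(exclusive$entities, function(s) sort(intersect(s, hubs)))
  empty <- exclusive$disease[lengths(genes) == 0]
  if (length(empty) > 0 && !quiet) {
    inform(paste0("No exclusive co-expressed hub gene for: ",
                  paste(empty, collapse = ", ")))
  }
  tibble(disease = exclusive$disease, genes = genes,
         n = lengths(genes))
}

#' Collect drugs targeting the selected genes
#'
#' Applies the same evidence retention filter as the first cascade stage
#' to the drug--gene records, then keeps records whose gene belongs to
#' some disease's target set, emitting one row per (drug, gene,
#' disease).
#'
#' @param drug_gene `reponet_associations` of drug--gene records (raw;
#'   the evidence filter is applied here).
#' @param target_genes Tibble from [select_target_genes()].
#' @param min_documents,min_confidence_pct,min_score Thresholds passed
#'   to [filter_associations()].
#' @return List with `rows` (tibble drug/target_gene/disease plus
#'   evidence), `below_threshold` (drugs with no record surviving the
#'   evidence filter) and `non_target` (drugs surviving evidence but
#'   targeting no selected gene).
#' @export
find_candidate_drugs <- function(drug_gene, target_genes,
                                 min_documents = 2,
                                 min_confidence_pct = 50,
                                 min_score = 0.5) {
  all_drugs <- unique(drug_gene$subject)
  filtered <- filter_associations(drug_gene,
                                  min_documents = min_documents,
                                  min_confidence_pct = min_confidence_pct,
                                  min_score = min_score)
  below <- setdiff(all_drugs, unique(filtered$subject))

  gene_to_disease <- tibble(
    target_gene = unlist(target_genes$genes, use.names = FALSE),
    disease = rep(target_genes$disease, lengths(target_genes$genes))
  )
  evidence_cols <- intersect(c("n_documents", "confidence", "score"),
                             names(filtered))
  rows <- as_tibble(filtered) |>
    rename(drug = "subject", target_gene = "object") |>
    select(dplyr::all_of(c("drug", "target_gene", evidence_cols))) |>
    dplyr::inner_join(gene_to_disease, by = "target_gene") |>
    select(dplyr::all_of(c("drug", "target_gene", "disease",
                           evidence_cols)))
  non_target <- setdiff(unique(filtered$subject), unique(rows$drug))
  list(rows = rows, below_threshold = sort(below),
       non_target = sort(non_target))
}

#' Apply the candidate removal filters
#'
#' Removes (i) drugs already linked to ANY of the study diseases in the
#' filtered drug--disease records (repositioning requires no prior
#' indication in the disease class), (ii) drugs whose surviving records
#' span more than one distinct target gene, and (iii) drugs on the
#' manual-curation exclusion list. Every removal is logged with its
#' reason; retained rows carry all audit flags true and a dense rank
#' ordered by evidence strength.
#'
#' @param candidates Output of [find_candidate_drugs()] (the list, or
#'   just its `rows` tibble).
#' @param drug_disease Filtered drug--disease `reponet_associations`
#'   (the first-stage drug network).
#' @param exclusions Character vector of drug names to exclude
#'   (machine-readable stand-in for manual document curation).
#' @return A tibble of class `reponet_candidates` (the retained rows
#'   with audit flags and rank), with attributes `removals` (tibble
#'   drug/reason, one row per removed drug) and `audit` (every
#'   candidate row with its per-filter flags).
#' @export
filter_candidates <- function(candidates, drug_disease,
                              exclusions = character(0)) {
  below <- character(0)
  non_target <- character(0)
  if (is.list(candidates) && !is.data.frame(candidates)) {
    below <- candidates$below_threshold %||% character(0)
    non_target <- candidates$non_target %||% character(0)
    rows <- candidates$rows
  } else {
    rows <- candidates
  }
  known_drugs <- unique(drug_disease$subject)
  multi <- rows |>
    distinct(.data$drug, .data$target_gene) |>
    dplyr::count(.data$drug) |>
    filter(.data$n > 1)

  audit <- rows |>
    mutate(
      passed_evidence = TRUE,
      single_target = !(.data$drug %in% multi$drug),
      not_known_for_pnds = !(.data$drug %in% known_drugs),
      manual_exclusion_applied = !(.data$drug %in% exclusions)
    )
  retained <- audit |>
    filter(.data$single_target, .data$not_known_for_pnds,
           .data$manual_exclusion_applied)

  removed <- setdiff(unique(rows$drug), unique(retained$drug))
  reason_for <- function(d) {
    if (d %in% known_drugs) "known_pnd_drug"
    else if (d %in% multi$drug) "multi_gene"
    else "manual_exclusion"
  }
  removals <- bind_rows(
    tibble(drug = below,
           reason = rep("below_evidence_threshold", length(below))),
    tibble(drug = non_target,
           reason = rep("gene_not_target", length(non_target))),
    tibble(drug = removed,
           reason = unname(vapply(removed, reason_for, "")))
  ) |> arrange(.data$drug)

  evidence_cols <- intersect(c("n_documents", "confidence", "score"),
                             names(retained))
  key <- retained[evidence_cols]
  ord <- do.call(order, c(lapply(key, function(x) -x),
                          list(retained$drug)))
  retained <- retained[ord, , drop = FALSE]
  if (nrow(retained) > 0) {
    # dense rank: rows share a rank iff they tie on every evidence field
    keystr <- do.call(paste, c(key[ord, , drop = FALSE], sep = "\r"))
    retained$rank <- as.integer(factor(keystr, levels = unique(keystr)))
  } else {
    retained$rank <- integer(0)
  }
  retained$trial_annotation <- "none found"
  structure(retained,
            class = c("reponet_candidates", class(retained)),
            removals = removals, audit = audit)
}

#' Attach clinical-trial annotations to a candidate table
#'
#' Left-joins a drug-to-trial table on the canonical drug name.
#' Multiple trials per drug are concatenated, semicolon-separated and
#' sorted; unmatched drugs are annotated `"none found"`.
#'
#' @param table A `reponet_candidates` tibble.
#' @param trials Data frame with columns `drug` and `trial_id`, a file
#'   path to such a TSV, or `NULL` (no annotation available).
#' @return The table with `trial_annotation` filled in.
#' @export
annotate_trials <- function(table, trials = NULL) {
  if (is.null(trials)) {
    table$trial_annotation <- "none found"
    return(table)
  }
  if (is.character(trials)) trials <- read_trials(trials)
  if (!all(c("drug", "trial_id") %in% names(trials))) {
    abort("Trials table must have columns 'drug' and 'trial_id'.")
  }
  agg <- trials |>
    group_by(.data$drug) |>
    summarise(trial_annotation = paste(sort(unique(.data$trial_id)),
                                       collapse = ";"),
              .groups = "drop")
  idx <- match(table$drug, agg$drug)
  table$trial_annotation <- ifelse(is.na(idx), "none found",
                                   agg$trial_annotation[idx])
  table
}

resolve_associations <- function(x, dialect, what) {
  if (is.character(x) && length(x) == 1) {
    read_associations(x, dialect, quiet = TRUE)
  } else if (inherits(x, "reponet_associations")) {
    x
  } else if (is.data.frame(x)) {
    as_associations(x, dialect, quiet = TRUE)
  } else {
    abort(paste0("Cannot interpret ", what,
                 " input: give a path or association table."))
  }
}

#' Run the full drug-repositioning cascade
#'
#' Executes the stages in order: evidence filtering of the gene--disease
#' and drug--disease records, knowledge-network construction,
#' disease-exclusive gene selection, co-expression hub calling (kME),
#' drug--gene search over the selected targets, the removal filters,
#' and trial annotation. The run report records per-stage counts,
#' thresholds, the seed and input digests; the output is deterministic
#' for a fixed configuration.
#'
#' @param gene_disease,drug_disease,drug_gene Association inputs: file
#'   paths, data frames, or `reponet_associations`.
#' @param expression Expression matrix (genes x samples) or TSV path.
#' @param module_assignment Data frame (`gene`, `module`) or named
#'   vector assigning genes to co-expression modules.
#' @param dialect Evidence dialect of the association inputs.
#' @param min_documents,min_confidence_pct,min_score Evidence
#'   thresholds (see [filter_associations()]).
#' @param hub_cutoff Strict kME cutoff for hub calling. Default 0.5.
#' @param exclusions Character vector of manually excluded drugs.
#' @param trials Optional trial table or path (see [annotate_trials()]).
#' @param seed Integer seed recorded in the report (the cascade itself
#'   is deterministic).
#' @return A list of class `reponet_run`: `candidates`
#'   (`reponet_candidates`), `removals`, `target_genes`, `exclusive`,
#'   `hubs`, and `report` (named list of stage counts and settings).
#' @export
run_pipeline <- function(gene_disease, drug_disease, drug_gene,
                         expression, module_assignment,
                         dialect = c("literature", "score"),
                         min_documents = 2, min_confidence_pct = 50,
                         min_score = 0.5, hub_cutoff = 0.5,
                         exclusions = character(0), trials = NULL,
                         seed = 1L) {
  dialect <- match.arg(dialect)
  digest_of <- function(x) {
    if (is.character(x) && length(x) == 1 && file.exists(x)) {
      unname(tools::md5sum(x))
    } else {
      NA_character_
    }
  }
  digests <- c(gene_disease = digest_of(gene_disease),
               drug_disease = digest_of(drug_disease),
               drug_gene = digest_of(drug_gene),
               expression = if (is.character(expression))
                 digest_of(expression) else NA_character_)

  gd <- resolve_associations(gene_disease, dialect, "gene_disease")
  dd <- resolve_associations(drug_disease, dialect, "drug_disease")
  dg <- resolve_associations(drug_gene, dialect, "drug_gene")
  if (is.character(expression)) expression <- read_expression(expression)

  gd_f <- filter_associations(gd, min_documents, min_confidence_pct,
                              min_score)
  dd_f <- filter_associations(dd, min_documents, min_confidence_pct,
                              min_score)

  gene_net <- build_network(gd_f)
  sets <- disease_entity_sets(gene_net)
  excl <- exclusive_entities(sets)

  kme <- suppressWarnings(
    kme_table(expression, module_assignment, hub_cutoff = hub_cutoff))
  hubs <- module_hubs(kme)

  targets <- select_target_genes(excl, hubs, quiet = TRUE)
  found <- find_candidate_drugs(dg, targets,
                                min_documents = min_documents,
                                min_confidence_pct = min_confidence_pct,
                                min_score = min_score)
  cand <- filter_candidates(found, dd_f, exclusions = exclusions)
  cand <- annotate_trials(cand, trials)

  report <- list(
    dialect = dialect,
    thresholds = list(min_documents = min_documents,
                      min_confidence_pct = min_confidence_pct,
                      min_score = min_score, hub_cutoff = hub_cutoff),
    seed = as.integer(seed),
    input_digests = as.list(digests),
    stages = list(
      gene_disease_records = c(raw = nrow(gd), filtered = nrow(gd_f)),
      drug_disease_records = c(raw = nrow(dd), filtered = nrow(dd_f)),
      diseases = nrow(sets),
      exclusive_genes = sum(excl$n),
      genes_with_kme = nrow(kme),
      hubs = length(hubs),
      target_genes = sum(targets$n),
      drug_gene_records = c(raw = nrow(dg),
                            on_targets = nrow(found$rows)),
      drugs_in = length(unique(dg$subject)),
      candidates_retained = nrow(cand),
      drugs_removed = nrow(attr(cand, "removals"))
    ),
    ranking = "n_documents desc, confidence/score desc, drug name"
  )
  structure(
    list(candidates = cand, removals = attr(cand, "removals"),
         target_genes = targets, exclusive = excl, hubs = hubs,
         kme = kme, report = report),
    class = "reponet_run"
  )
}

#' @export
print.reponet_run <- function(x, ...) {
  s <- x$report$stages
  cat("<repositioning run>\n",
      "  gene-disease records: ", s$gene_disease_records["raw"], " -> ",
      s$gene_disease_records["filtered"], " after evidence filter\n",
      "  exclusive genes: ", s$exclusive_genes,
      "; hubs: ", s$hubs, "; target genes: ", s$target_genes, "\n",
      "  drugs searched: ", s$drugs_in,
      "; retained candidates: ", s$candidates_retained,
      "; removed: ", s$drugs_removed, "\n", sep = "")
  invisible(x)
}

#' Write a run report as JSON
#'
#' @param run A `reponet_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(run, path) {
  jsonlite::write_json(run$report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
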