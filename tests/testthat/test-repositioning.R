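test_that("target genes are the exclusive/hub intersection per disease", {
  excl <- tibble::tibble(
    disease = c("D1", "D2"),
    entities = list(c("G1", "G2"), c("G3", "G4"))
  )
  out <- select_target_genes(excl, hubs = c("G2", "G3", "G9"),
                             quiet = TRUE)
  expect_equal(out$genes[[1]], "G2")
  expect_equal(out$genes[[2]], "G3")

  # disjoint inputs -> empty set retained and reported
  expect_message(
    out2 <- select_target_genes(excl, hubs = "G9"),
    "No exclusive co-expressed hub"
  )
  expect_equal(out2$n, c(0L, 0L))

  # hubs superset -> identity
  out3 <- select_target_genes(excl, hubs = paste0("G", 1:9),
                              quiet = TRUE)
  expect_equal(out3$genes, lapply(excl$entities, sort))
})

test_that("candidate search applies the stage-one evidence thresholds", {
  dg <- lit_records(
    c("Drug X", "Drug Y", "Drug Z"), c("G2", "G2", "G7"),
    c(2L, 1L, 5L), c(60, 60, 90),
    subject_kind = "drug", object_kind = "gene"
  )
  targets <- tibble::tibble(disease = "D1", genes = list("G2"), n = 1L)
  found <- find_candidate_drugs(dg, targets)
  expect_equal(found$rows$drug, "Drug X")
  expect_equal(found$rows$disease, "D1")
  expect_equal(found$below_threshold, "Drug Y")  # one document only
  expect_equal(found$non_target, "Drug Z")       # gene not selected
})

test_that("removal filters log known drugs, multi-gene drugs and exclusions", {
  dg <- lit_records(
    c("Keep", "Multi", "Multi", "Known", "Banned"),
    c("G1", "G2", "G3", "G4", "G5"),
    c(3L, 3L, 3L, 3L, 3L), c(80, 80, 80, 80, 80),
    subject_kind = "drug", object_kind = "gene"
  )
  targets <- tibble::tibble(
    disease = paste0("D", 1:5),
    genes = list("G1", "G2", "G3", "G4", "G5"), n = 1L
  )
  dd <- lit_records("Known", "D1", 4L, 90, subject_kind = "drug")
  found <- find_candidate_drugs(dg, targets)
  cand <- filter_candidates(found, dd, exclusions = "Banned")
  expect_equal(cand$drug, "Keep")
  expect_true(all(cand$single_target, cand$not_known_for_pnds,
                  cand$manual_exclusion_applied, cand$passed_evidence))
  removals <- attr(cand, "removals")
  expect_equal(removals$reason[removals$drug == "Multi"], "multi_gene")
  expect_equal(removals$reason[removals$drug == "Known"],
               "known_pnd_drug")
  expect_equal(removals$reason[removals$drug == "Banned"],
               "manual_exclusion")
  # retained drugs are unique (single-target rule)
  expect_equal(anyDuplicated(cand$drug), 0)
  # rank is dense from 1
  expect_equal(sort(unique(cand$rank)), seq_along(unique(cand$rank)))
})

test_that("trial annotation joins, aggregates and defaults deterministically", {
  cand <- tibble::tibble(
    drug = c("Alphatrexone", "Other"), target_gene = c("G1", "G2"),
    disease = "D1", n_documents = 3L, confidence = 80,
    rank = c(1L, 2L)
  )
  trials <- tibble::tibble(
    drug = c("Alphatrexone", "Alphatrexone", "Alphatrexone"),
    trial_id = c("NCT00000042", "NCT00000001", "NCT00000042")
  )
  out <- annotate_trials(cand, trials)
  expect_equal(out$trial_annotation[1], "NCT00000001;NCT00000042")
  expect_equal(out$trial_annotation[2], "none found")
  out2 <- annotate_trials(cand, NULL)
  expect_true(all(out2$trial_annotation == "none found"))
  expect_error(annotate_trials(cand, tibble::tibble(x = 1)), "columns")
})

test_that("pipeline recovers exactly the planted candidates on noiseless data", {
  cfg <- corpus_config(evidence_noise = 0, seed = 21)
  corp <- generate_knowledge_corpus(cfg)
  expr <- generate_corpus_expression(corp, seed = 21)
  run <- run_pipeline(corp$gene_disease, corp$drug_disease,
                      corp$drug_gene, expr$matrix, expr$assignment,
                      seed = 21)
  got <- dplyr::arrange(tidy(run)[c("drug", "target_gene", "disease")],
                        drug)
  want <- dplyr::arrange(
    dplyr::rename(corp$truth$planted, target_gene = gene), drug)
  expect_equal(got, want, ignore_attr = TRUE)
  # every decoy appears in the removal log with its planted reason
  removals <- run$removals
  for (i in seq_len(nrow(corp$truth$decoys))) {
    d <- corp$truth$decoys$drug[i]
    expect_equal(removals$reason[removals$drug == d],
                 corp$truth$decoys$reason[i])
  }
})

test_that("every input drug lands in exactly one accounting bucket", {
  cfg <- corpus_config(evidence_noise = 0.15, seed = 30)
  corp <- generate_knowledge_corpus(cfg)
  expr <- generate_corpus_expression(corp, seed = 30)
  run <- run_pipeline(corp$gene_disease, corp$drug_disease,
                      corp$drug_gene, expr$matrix, expr$assignment,
                      seed = 30)
  all_drugs <- unique(corp$drug_gene$subject)
  buckets <- c(run$candidates$drug, run$removals$drug)
  expect_setequal(buckets, all_drugs)
  expect_equal(anyDuplicated(buckets), 0)
})

test_that("candidate search is monotone in the document threshold", {
  # with the first-stage outputs held fixed, raising min_documents on
  # the drug-gene search never adds retained candidates
  cfg <- corpus_config(evidence_noise = 0.1, seed = 33)
  corp <- generate_knowledge_corpus(cfg)
  expr <- generate_corpus_expression(corp, seed = 33)
  gd_f <- filter_associations(corp$gene_disease)
  dd_f <- filter_associations(corp$drug_disease)
  excl <- exclusive_entities(disease_entity_sets(build_network(gd_f)))
  kme <- kme_table(expr$matrix, expr$assignment)
  targets <- select_target_genes(excl, module_hubs(kme), quiet = TRUE)
  prev_rows <- NULL
  for (md in c(2, 4, 6, 11)) {
    found <- find_candidate_drugs(corp$drug_gene, targets,
                                  min_documents = md)
    rows_key <- paste(found$rows$drug, found$rows$target_gene)
    if (!is.null(prev_rows)) {
      expect_true(all(rows_key %in% prev_rows))
    }
    prev_rows <- rows_key
  }
  # at min_documents above the generator's range nothing survives
  expect_length(prev_rows, 0)
})

test_that("identical configuration gives byte-identical outputs", {
  cfg <- corpus_config(seed = 40)
  corp <- generate_knowledge_corpus(cfg)
  expr <- generate_corpus_expression(corp, seed = 40)
  paths <- c(withr::local_tempfile(fileext = ".tsv"),
             withr::local_tempfile(fileext = ".tsv"))
  reports <- c(withr::local_tempfile(fileext = ".json"),
               withr::local_tempfile(fileext = ".json"))
  for (i in 1:2) {
    run <- run_pipeline(corp$gene_disease, corp$drug_disease,
                        corp$drug_gene, expr$matrix, expr$assignment,
                        seed = 40)
    write_candidates(run$candidates, paths[i])
    write_run_report(run, reports[i])
  }
  expect_identical(readLines(paths[1]), readLines(paths[2]))
  expect_identical(readLines(reports[1]), readLines(reports[2]))
})

test_that("run report records thresholds, counts and stage structure", {
  cfg <- corpus_config(seed = 44)
  corp <- generate_knowledge_corpus(cfg)
  expr <- generate_corpus_expression(corp, seed = 44)
  run <- run_pipeline(corp$gene_disease, corp$drug_disease,
                      corp$drug_gene, expr$matrix, expr$assignment,
                      min_documents = 2, seed = 44)
  rep <- run$report
  expect_equal(rep$thresholds$min_documents, 2)
  expect_equal(rep$thresholds$hub_cutoff, 0.5)
  expect_equal(rep$stages$candidates_retained, nrow(run$candidates))
  expect_equal(rep$stages$drugs_in,
               length(unique(corp$drug_gene$subject)))
  g <- glance(run)
  expect_equal(g$n_candidates, nrow(run$candidates))
})
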