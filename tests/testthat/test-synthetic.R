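test_that("corpus config validates groups, fractions and exclusivity", {
  expect_error(corpus_config(disease_groups = list(c(1, 2), c(2, 3))),
               "disjoint")
  expect_error(corpus_config(n_diseases = 3,
                             disease_groups = list(c(1, 5))),
               "out of range")
  expect_error(corpus_config(shared_fraction = 1.2), "\\[0, 1\\]")
  # no exclusive genes left -> refusal
  expect_error(corpus_config(shared_fraction = 1), "exclusive")
})

test_that("within-group diseases share the planted fraction of their pools", {
  cfg <- corpus_config(n_diseases = 4,
                       disease_groups = list(c(1, 2), c(3, 4)),
                       genes_per_group = 40, shared_fraction = 0.5,
                       evidence_noise = 0, seed = 2)
  corp <- generate_knowledge_corpus(cfg)
  dg <- corp$truth$disease_genes
  overlap <- length(intersect(dg$genes[[1]], dg$genes[[2]]))
  expect_equal(overlap / length(dg$genes[[1]]), 0.5, tolerance = 1e-12)
  # across groups: no sharing
  expect_length(intersect(dg$genes[[1]], dg$genes[[3]]), 0)
})

test_that("noiseless corpora pass the evidence filter in full", {
  cfg <- corpus_config(evidence_noise = 0, n_decoys_per_type = 0,
                       seed = 5)
  corp <- generate_knowledge_corpus(cfg)
  expect_equal(nrow(filter_associations(corp$gene_disease)),
               nrow(corp$gene_disease))
  expect_equal(nrow(filter_associations(corp$drug_disease)),
               nrow(corp$drug_disease))
})

test_that("evidence noise generates records the filter must remove", {
  cfg <- corpus_config(evidence_noise = 0.2, seed = 6)
  corp <- generate_knowledge_corpus(cfg)
  n_raw <- nrow(corp$gene_disease)
  n_kept <- nrow(filter_associations(corp$gene_disease))
  expect_lt(n_kept, n_raw)
  # noise fraction approximately as configured
  expect_equal((n_raw - n_kept) / n_raw, 0.2, tolerance = 0.05)
  # after filtering, exclusivity matches the planted truth
  net <- build_network(filter_associations(corp$gene_disease))
  ex <- exclusive_entities(disease_entity_sets(net))
  truth_ex <- corp$truth$exclusive_genes
  # grouped diseases: planted exclusive genes are recovered exactly for
  # diseases in multi-member groups (singleton-group diseases also own
  # their planted shared genes)
  grouped <- unlist(lapply(cfg$disease_groups, function(g) {
    if (length(g) > 1) sprintf("Disease %02d", g)
  }))
  for (d in grouped) {
    expect_setequal(ex$entities[[match(d, ex$disease)]],
                    truth_ex$genes[[match(d, truth_ex$disease)]])
  }
})

test_that("planted candidates and decoys are structured as promised", {
  cfg <- corpus_config(n_planted_candidates = 3, n_decoys_per_type = 2,
                       seed = 7)
  corp <- generate_knowledge_corpus(cfg)
  truth <- corp$truth
  expect_equal(nrow(truth$planted), 3)
  dd_drugs <- unique(corp$drug_disease$subject)
  dg <- corp$drug_gene
  for (i in seq_len(3)) {
    drug <- truth$planted$drug[i]
    # exactly one target gene, passing evidence, no disease link
    rows <- dg[dg$subject == drug, ]
    expect_equal(nrow(rows), 1)
    expect_equal(rows$object, truth$planted$gene[i])
    expect_gte(rows$n_documents, 2)
    expect_gt(rows$confidence, 50)
    expect_false(drug %in% dd_drugs)
    # the target is a planted exclusive co-expressed gene of the disease
    d <- truth$planted$disease[i]
    expect_true(truth$planted$gene[i] %in%
                  truth$exclusive_genes$genes[[
                    match(d, truth$exclusive_genes$disease)]])
    expect_true(truth$planted$gene[i] %in% truth$gene_modules$gene)
  }
  expect_setequal(unique(truth$decoys$reason),
                  c("multi_gene", "known_pnd_drug",
                    "below_evidence_threshold", "gene_not_target"))
})

test_that("corpus generation is deterministic in the seed", {
  c1 <- generate_knowledge_corpus(corpus_config(seed = 9))
  c2 <- generate_knowledge_corpus(corpus_config(seed = 9))
  c3 <- generate_knowledge_corpus(corpus_config(seed = 10))
  expect_identical(as.data.frame(c1$gene_disease),
                   as.data.frame(c2$gene_disease))
  expect_identical(c1$truth$planted, c2$truth$planted)
  expect_false(identical(as.data.frame(c1$gene_disease),
                         as.data.frame(c3$gene_disease)))
})

test_that("expression generator honours the latent-factor model", {
  # noiseless limit: perfect pairwise correlation within a module
  sim0 <- generate_expression(10, c(4), factor_loading = 1,
                              noise_sd = 0, seed = 1)
  cc <- cor(t(sim0$matrix[sim0$assignment$gene, ]))
  expect_equal(unname(cc), matrix(1, 4, 4), tolerance = 1e-12)

  # determinism
  a <- generate_expression(12, c(3, 2), seed = 4)
  b <- generate_expression(12, c(3, 2), seed = 4)
  expect_identical(a$matrix, b$matrix)

  expect_error(generate_expression(2, c(3)), "n_samples")
  expect_error(generate_expression(10, c(0, 3)), "Module sizes")
  expect_error(generate_expression(10, 3, factor_loading = 0),
               "factor_loading")

  # output satisfies the expression-matrix invariants end to end
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(a$matrix, path)
  expect_equal(read_expression(path), a$matrix, tolerance = 1e-12)
})

test_that("ground truth serializes to JSON", {
  corp <- generate_knowledge_corpus(corpus_config(seed = 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(corp$truth, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$planted$drug, corp$truth$planted$drug)
})

test_that("louvain recovers planted disease groups on the gene network", {
  ari <- numeric(0)
  for (s in 1:5) {
    cfg <- corpus_config(n_diseases = 6,
                         disease_groups = list(c(1, 2), c(3, 4), c(5, 6)),
                         genes_per_group = 40, shared_fraction = 0.5,
                         evidence_noise = 0, seed = s)
    corp <- generate_knowledge_corpus(cfg)
    net <- build_network(filter_associations(corp$gene_disease))
    part <- louvain(net, seed = s)
    comm <- setNames(part$community, part$node)
    diseases <- sprintf("Disease %02d", 1:6)
    truth_lab <- rep(1:3, each = 2)
    ari <- c(ari, mclust::adjustedRandIndex(comm[diseases], truth_lab))
  }
  expect_gte(mean(ari), 0.9)
})
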