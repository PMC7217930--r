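#' Configuration for a synthetic knowledge corpus
#'
#' Describes the planted structure of a simulated association corpus:
#' disease clusters sharing gene pools, exclusive genes per disease,
#' background genes, known drugs, and planted repositioning candidates
#' alongside decoy drugs that each violate exactly one cascade filter.
#'
#' The defaults mirror a study of nine related disorders organised as
#' four clustered pairs plus one unclustered disease, with each cluster
#' drawing on a pool of 30 genes of which half are shared within the
#' cluster.
#'
#' @param n_diseases Number of diseases. Default 9.
#' @param disease_groups List of integer vectors (disjoint disease
#'   indices) defining planted clusters; unlisted diseases form
#'   singleton groups. Default four pairs.
#' @param genes_per_group Gene-pool size per disease within a group.
#'   Default 30.
#' @param shared_fraction Fraction of each member disease's pool shared
#'   by the whole group, in \[0, 1\]. Default 0.5.
#' @param n_background_genes Genes with no disease association (pure
#'   noise in expression; decoy targets). Default 100.
#' @param n_drugs Number of known drugs with disease links. Default 20.
#' @param n_planted_candidates Drugs that should survive the full
#'   cascade. Default 3.
#' @param n_decoys_per_type Decoy drugs per violation type (multi-gene
#'   target, prior disease link, sub-threshold evidence, non-target
#'   gene). Default 2.
#' @param evidence_noise Fraction of association records generated with
#'   sub-threshold evidence (removed by the retention filter).
#'   Default 0.1.
#' @param dialect Evidence dialect of the generated records.
#' @param seed Master integer seed.
#' @return A validated `reponet_corpus_config` list.
#' @export
corpus_config <- function(n_diseases = 9,
                          disease_groups = list(c(1, 2), c(3, 4),
                                                c(5, 6), c(7, 8)),
                          genes_per_group = 30,
                          shared_fraction = 0.5,
                          n_background_genes = 100,
                          n_drugs = 20,
                          n_planted_candidates = 3,
                          n_decoys_per_type = 2,
                          evidence_noise = 0.1,
                          dialect = c("literature", "score"),
                          seed = 1L) {
  dialect <- match.arg(dialect)
  idx <- unlist(disease_groups)
  if (anyDuplicated(idx)) abort("Disease groups must be disjoint.")
  if (length(idx) > 0 && (max(idx) > n_diseases || min(idx) < 1)) {
    abort("Disease group indices out of range.")
  }
  if (shared_fraction < 0 || shared_fraction > 1) {
    abort("shared_fraction must lie in [0, 1].")
  }
  if (evidence_noise < 0 || evidence_noise >= 1) {
    abort("evidence_noise must lie in [0, 1).")
  }
  n_excl <- genes_per_group - round(shared_fraction * genes_per_group)
  if (n_excl < 1) {
    abort("Config leaves no exclusive genes per disease; lower shared_fraction or raise genes_per_group.")
  }
  structure(
    list(
      n_diseases = n_diseases, disease_groups = disease_groups,
      genes_per_group = genes_per_group,
      shared_fraction = shared_fraction,
      n_background_genes = n_background_genes, n_drugs = n_drugs,
      n_planted_candidates = n_planted_candidates,
      n_decoys_per_type = n_decoys_per_type,
      evidence_noise = evidence_noise, dialect = dialect,
      seed = as.integer(seed)
    ),
    class = "reponet_corpus_config"
  )
}

# Evidence samplers. Passing literature records draw confidence on
# (51, 100] and 2-10 documents; failing records sit just below a
# threshold (confidence exactly 50, or a single document) to pin filter
# strictness. Score dialect: passing on (0.51, 1], failing exactly 0.5.
sample_evidence <- function(n, dialect, passing) {
  if (dialect == "literature") {
    if (passing) {
      tibble(n_documents = sample(2:10, n, replace = TRUE),
             confidence = runif(n, 51, 100))
    } else {
      fail_doc <- seq_len(n) %% 2 == 0
      tibble(
        n_documents = ifelse(fail_doc, 1L,
                             sample(2:10, n, replace = TRUE)),
        confidence = ifelse(fail_doc, runif(n, 51, 100), 50)
      )
    }
  } else {
    tibble(score = if (passing) runif(n, 0.51, 1) else rep(0.5, n))
  }
}

assoc_rows <- function(subject, subject_kind, object, object_kind,
                       evidence, source) {
  dplyr::bind_cols(
    tibble(subject = subject, subject_kind = subject_kind,
           object = object, object_kind = object_kind),
    evidence,
    tibble(source = source)
  )
}

#' Generate a synthetic knowledge corpus with planted ground truth
#'
#' Produces gene--disease, drug--disease and drug--gene association
#' tables plus a `GroundTruth` object. Diseases in the same planted
#' group share `shared_fraction` of their gene pools and carry their own
#' exclusive genes; a fraction `evidence_noise` of records is generated
#' with sub-threshold evidence (cross-group gene--disease pairs and
#' spurious drug links) and must be removed by the retention filter for
#' the planted structure to be recovered. Planted candidate drugs link
#' only to a single exclusive co-expressed gene with passing evidence;
#' decoy drugs each violate exactly one cascade filter.
#'
#' @param config A [corpus_config()].
#' @return A list of class `reponet_corpus` with elements
#'   `gene_disease`, `drug_disease`, `drug_gene` (association tibbles)
#'   and `truth` (class `reponet_ground_truth`): `disease_genes`,
#'   `gene_modules` (exclusive genes to their disease module),
#'   `true_partition`, `planted` (drug, gene, disease), `decoys`
#'   (drug, reason), `background_genes`.
#' @export
generate_knowledge_corpus <- function(config) {
  stopifnot(inherits(config, "reponet_corpus_config"))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(split_seed(config$seed, "corpus"))

  dialect <- config$dialect
  diseases <- sprintf("Disease %02d", seq_len(config$n_diseases))
  groups <- config$disease_groups
  singletons <- setdiff(seq_len(config$n_diseases), unlist(groups))
  groups <- c(groups, as.list(singletons))

  P <- config$genes_per_group
  s <- round(config$shared_fraction * P)
  gene_counter <- 0
  next_genes <- function(n) {
    out <- sprintf("G%05d", gene_counter + seq_len(n))
    gene_counter <<- gene_counter + n
    out
  }

  disease_genes <- list()
  exclusive_genes <- list()
  partition_rows <- list()
  for (gi in seq_along(groups)) {
    members <- groups[[gi]]
    shared <- next_genes(s)
    if (length(shared) > 0 && length(members) > 1) {
      partition_rows[[length(partition_rows) + 1]] <-
        tibble(node = shared, community = gi)
    } else if (length(shared) > 0) {
      partition_rows[[length(partition_rows) + 1]] <-
        tibble(node = shared, community = gi)
    }
    for (d in members) {
      excl <- next_genes(P - s)
      disease_genes[[diseases[d]]] <- c(shared, excl)
      exclusive_genes[[diseases[d]]] <- excl
      partition_rows[[length(partition_rows) + 1]] <- bind_rows(
        tibble(node = diseases[d], community = gi),
        tibble(node = excl, community = gi)
      )
    }
  }
  background <- next_genes(config$n_background_genes)

  # gene-disease records: one passing record per membership
  gd_pairs <- tibble(
    gene = unlist(disease_genes, use.names = FALSE),
    disease = rep(names(disease_genes), lengths(disease_genes))
  )
  gd <- assoc_rows(gd_pairs$gene, "gene", gd_pairs$disease, "disease",
                   sample_evidence(nrow(gd_pairs), dialect, TRUE),
                   "synthetic")

  # known drugs with 1-3 disease links each (passing evidence)
  drugs <- sprintf("Drug %03d", seq_len(config$n_drugs))
  dd_list <- lapply(drugs, function(dr) {
    k <- sample(1:3, 1)
    tibble(drug = dr, disease = sample(diseases, k))
  })
  dd_pairs <- bind_rows(dd_list)
  dd <- assoc_rows(dd_pairs$drug, "drug", dd_pairs$disease, "disease",
                   sample_evidence(nrow(dd_pairs), dialect, TRUE),
                   "synthetic")

  # target pool: exclusive co-expressed genes (all exclusive genes are
  # planted as co-expression module members of their disease)
  target_pool <- tibble(
    gene = unlist(exclusive_genes, use.names = FALSE),
    disease = rep(names(exclusive_genes), lengths(exclusive_genes))
  )

  planted <- tibble(drug = character(0), gene = character(0),
                    disease = character(0))
  dg_rows <- list()
  if (config$n_planted_candidates > 0) {
    pick <- target_pool[sample.int(nrow(target_pool),
                                   config$n_planted_candidates), ]
    planted <- tibble(
      drug = sprintf("Candidate %02d",
                     seq_len(config$n_planted_candidates)),
      gene = pick$gene, disease = pick$disease
    )
    dg_rows[["planted"]] <- assoc_rows(
      planted$drug, "drug", planted$gene, "gene",
      sample_evidence(nrow(planted), dialect, TRUE), "synthetic")
  }

  decoys <- list()
  nd <- config$n_decoys_per_type
  if (nd > 0) {
    # (i) multi-gene decoys: two distinct target-pool genes, passing
    multi <- sprintf("DecoyMulti %02d", seq_len(nd))
    mg <- lapply(seq_len(nd), function(i) {
      rows <- target_pool[sample.int(nrow(target_pool), 2), ]
      assoc_rows(multi[i], "drug", rows$gene, "gene",
                 sample_evidence(2, dialect, TRUE), "synthetic")
    })
    dg_rows[["multi"]] <- bind_rows(mg)
    decoys[["multi"]] <- tibble(drug = multi, reason = "multi_gene")

    # (ii) prior-disease-link decoys: one target gene, passing, but the
    # drug is also linked to a disease in the drug-disease table
    known <- sprintf("DecoyKnown %02d", seq_len(nd))
    kb <- target_pool[sample.int(nrow(target_pool), nd), ]
    dg_rows[["known"]] <- assoc_rows(
      known, "drug", kb$gene, "gene",
      sample_evidence(nd, dialect, TRUE), "synthetic")
    dd_extra <- assoc_rows(known, "drug", sample(diseases, nd,
                                                 replace = TRUE),
                           "disease",
                           sample_evidence(nd, dialect, TRUE),
                           "synthetic")
    dd <- bind_rows(dd, dd_extra)
    decoys[["known"]] <- tibble(drug = known, reason = "known_pnd_drug")

    # (iii) sub-threshold decoys: one target gene, failing evidence
    sub <- sprintf("DecoySub %02d", seq_len(nd))
    sb <- target_pool[sample.int(nrow(target_pool), nd), ]
    dg_rows[["sub"]] <- assoc_rows(
      sub, "drug", sb$gene, "gene",
      sample_evidence(nd, dialect, FALSE), "synthetic")
    decoys[["sub"]] <- tibble(drug = sub,
                              reason = "below_evidence_threshold")

    # (iv) non-target decoys: passing evidence on a background gene
    nt <- sprintf("DecoyNonTarget %02d", seq_len(nd))
    dg_rows[["nontarget"]] <- assoc_rows(
      nt, "drug", sample(background, nd, replace = FALSE), "gene",
      sample_evidence(nd, dialect, TRUE), "synthetic")
    decoys[["nontarget"]] <- tibble(drug = nt,
                                    reason = "gene_not_target")
  }
  dg <- bind_rows(dg_rows)
  decoys <- bind_rows(decoys)

  # evidence noise: cross-group gene-disease pairs plus spurious drug
  # links, all with sub-threshold evidence
  if (config$evidence_noise > 0) {
    frac <- config$evidence_noise
    n_noise_gd <- round(frac * nrow(gd) / (1 - frac))
    if (n_noise_gd > 0) {
      noise_gene <- sample(c(background,
                             unlist(exclusive_genes, use.names = FALSE)),
                           n_noise_gd, replace = TRUE)
      noise_dis <- vapply(noise_gene, function(g) {
        owner <- target_pool$disease[match(g, target_pool$gene)]
        pool <- setdiff(diseases, owner)
        sample(pool, 1)
      }, "")
      gd <- bind_rows(gd, assoc_rows(
        noise_gene, "gene", unname(noise_dis), "disease",
        sample_evidence(n_noise_gd, dialect, FALSE), "synthetic-noise"))
    }
    n_noise_dd <- round(frac * nrow(dd) / (1 - frac))
    if (n_noise_dd > 0) {
      dd <- bind_rows(dd, assoc_rows(
        sample(drugs, n_noise_dd, replace = TRUE), "drug",
        sample(diseases, n_noise_dd, replace = TRUE), "disease",
        sample_evidence(n_noise_dd, dialect, FALSE), "synthetic-noise"))
    }
  }

  gene_modules <- tibble(
    gene = target_pool$gene,
    module = paste0("M_", gsub(" ", "", target_pool$disease))
  )
  truth <- structure(
    list(
      disease_genes = tibble(
        disease = names(disease_genes),
        genes = unname(lapply(disease_genes, sort))
      ),
      exclusive_genes = tibble(
        disease = names(exclusive_genes),
        genes = unname(lapply(exclusive_genes, sort))
      ),
      gene_modules = gene_modules,
      true_partition = bind_rows(partition_rows),
      planted = planted,
      decoys = decoys,
      background_genes = background
    ),
    class = "reponet_ground_truth"
  )

  structure(
    list(
      gene_disease = as_associations(gd, dialect, quiet = TRUE),
      drug_disease = as_associations(dd, dialect, quiet = TRUE),
      drug_gene = as_associations(dg, dialect, quiet = TRUE),
      truth = truth,
      config = config
    ),
    class = "reponet_corpus"
  )
}

#' @export
print.reponet_corpus <- function(x, ...) {
  cat("<synthetic corpus> ", x$config$n_diseases, " diseases, ",
      nrow(x$gene_disease), " gene-disease, ",
      nrow(x$drug_disease), " drug-disease, ",
      nrow(x$drug_gene), " drug-gene records; ",
      nrow(x$truth$planted), " planted candidate(s)\n", sep = "")
  invisible(x)
}

#' Serialize a ground-truth object to JSON
#'
#' @param truth A `reponet_ground_truth` from
#'   [generate_knowledge_corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "reponet_ground_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Generate block-correlated expression with planted modules
#'
#' Each module m receives a latent standard-normal sample vector
#' \eqn{f_m}; member genes are \eqn{g = \lambda f_m + \sigma \epsilon}
#' with \eqn{\epsilon} iid standard normal, so the expected correlation
#' of a member with its latent factor is
#' \eqn{\lambda / \sqrt{\lambda^2 + \sigma^2}}. Background genes are
#' pure unit-variance noise.
#'
#' @param n_samples Number of samples (>= 3).
#' @param module_sizes Integer vector of module sizes (all >= 1).
#' @param factor_loading \eqn{\lambda}, in (0, 1].
#' @param noise_sd \eqn{\sigma}, >= 0.
#' @param seed Integer seed.
#' @param n_background Number of pure-noise genes appended. Default 0.
#' @param gene_names Optional gene labels for module members (in module
#'   order); generated when `NULL`.
#' @param module_names Optional module labels; default `"M1"`, ...
#' @param background_names Optional labels for background genes.
#' @return List with `matrix` (genes x samples) and `assignment`
#'   (tibble gene/module; background genes are not assigned).
#' @export
generate_expression <- function(n_samples, module_sizes,
                                factor_loading = 0.8, noise_sd = 0.6,
                                seed = 1L, n_background = 0,
                                gene_names = NULL, module_names = NULL,
                                background_names = NULL) {
  if (n_samples < 3) abort("Need n_samples >= 3.")
  if (any(module_sizes < 1)) abort("Module sizes must be >= 1.")
  if (factor_loading <= 0 || factor_loading > 1) {
    abort("factor_loading must lie in (0, 1].")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0.")
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(split_seed(seed, "expression"))

  n_mod_genes <- sum(module_sizes)
  module_names <- module_names %||%
    paste0("M", seq_along(module_sizes))
  gene_names <- gene_names %||% sprintf("G%05d", seq_len(n_mod_genes))
  stopifnot(length(gene_names) == n_mod_genes,
            length(module_names) == length(module_sizes))
  assignment <- tibble(
    gene = gene_names,
    module = rep(module_names, module_sizes)
  )

  rows <- matrix(0, n_mod_genes + n_background, n_samples)
  r0 <- 0
  for (m in seq_along(module_sizes)) {
    f <- rnorm(n_samples)
    for (j in seq_len(module_sizes[m])) {
      rows[r0 + j, ] <- factor_loading * f +
        noise_sd * rnorm(n_samples)
    }
    r0 <- r0 + module_sizes[m]
  }
  if (n_background > 0) {
    background_names <- background_names %||%
      sprintf("BG%05d", seq_len(n_background))
    stopifnot(length(background_names) == n_background)
    rows[n_mod_genes + seq_len(n_background), ] <-
      matrix(rnorm(n_background * n_samples), n_background)
  } else {
    background_names <- character(0)
  }
  rownames(rows) <- c(gene_names, background_names)
  colnames(rows) <- sprintf("S%03d", seq_len(n_samples))
  list(matrix = rows, assignment = assignment)
}

#' Expression matrix matching a synthetic corpus's planted modules
#'
#' Convenience wrapper around [generate_expression()] that uses the
#' corpus ground truth: each disease's exclusive genes form one planted
#' co-expression module and the corpus background genes are pure noise.
#'
#' @param corpus A `reponet_corpus` from [generate_knowledge_corpus()].
#' @param n_samples,factor_loading,noise_sd,seed Passed through.
#' @return As [generate_expression()].
#' @export
generate_corpus_expression <- function(corpus, n_samples = 50,
                                       factor_loading = 0.8,
                                       noise_sd = 0.6, seed = 1L) {
  stopifnot(inherits(corpus, "reponet_corpus"))
  gm <- corpus$truth$gene_modules
  gm <- arrange(gm, .data$module, .data$gene)
  sizes <- table(gm$module)
  generate_expression(
    n_samples = n_samples,
    module_sizes = as.integer(sizes),
    factor_loading = factor_loading, noise_sd = noise_sd, seed = seed,
    n_background = length(corpus$truth$background_genes),
    gene_names = gm$gene, module_names = names(sizes),
    background_names = corpus$truth$background_genes
  )
}
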