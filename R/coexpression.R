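#' Standardize an expression matrix gene-wise
#'
#' Centers and scales each gene row to mean 0, sd 1 across samples,
#' using the sample (n-1) standard deviation. Zero-variance genes are
#' dropped with a warning naming them.
#'
#' @param mat Numeric matrix, genes in rows, >= 2 samples in columns.
#' @return The standardized matrix (possibly with fewer rows).
#' @export
standardize <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2)
  sds <- apply(mat, 1, sd)
  zero <- which(sds == 0 | is.na(sds))
  if (length(zero) == nrow(mat)) {
    abort("All genes have zero variance; nothing to standardize.")
  }
  if (length(zero) > 0) {
    warn(paste0("Dropping zero-variance gene(s): ",
                paste(head(rownames(mat)[zero], 10), collapse = ", ")))
    mat <- mat[-zero, , drop = FALSE]
    sds <- sds[-zero]
  }
  sweep(sweep(mat, 1, rowMeans(mat)), 1, sds, "/")
}

#' Module eigengene (first principal component across samples)
#'
#' The eigengene is the first right-singular vector of the standardized
#' member-gene submatrix: a unit-norm sample-indexed summary of the
#' module's expression. Its sign is aligned so that the mean Pearson
#' correlation with the member genes is non-negative (singular-vector
#' sign is otherwise arbitrary).
#'
#' @param mat Expression matrix (genes x samples).
#' @param module_genes Character vector of member gene labels. Members
#'   absent from `mat` are skipped with a warning.
#' @param module Optional module label stored on the result.
#' @return A `reponet_eigengene`: list with `module`, `vector`
#'   (named by sample, unit Euclidean norm), `var_explained` and
#'   `n_genes`.
#' @export
eigengene <- function(mat, module_genes, module = NA_character_) {
  present <- intersect(module_genes, rownames(mat))
  missing_genes <- setdiff(module_genes, rownames(mat))
  if (length(missing_genes) > 0) {
    warn(paste0("Module gene(s) absent from matrix, skipped: ",
                paste(head(missing_genes, 10), collapse = ", ")))
  }
  if (length(present) == 0) {
    abort("No module gene is present in the expression matrix.")
  }
  sub <- mat[present, , drop = FALSE]
  sub_std <- suppressWarnings(standardize(sub))
  if (nrow(sub_std) == 0) {
    abort("All module genes have zero variance.")
  }
  sv <- svd(sub_std)
  v <- sv$v[, 1]
  # sign convention: positive mean correlation with raw member profiles
  mean_cor <- mean(apply(sub[rownames(sub_std), , drop = FALSE], 1,
                         function(g) cor(g, v)))
  if (!is.na(mean_cor) && mean_cor < 0) v <- -v
  v <- v / sqrt(sum(v^2))
  names(v) <- colnames(mat)
  structure(
    list(module = module, vector = v,
         var_explained = sv$d[1]^2 / sum(sv$d^2),
         n_genes = nrow(sub_std)),
    class = "reponet_eigengene"
  )
}

#' @export
print.reponet_eigengene <- function(x, ...) {
  cat("<module eigengene> ", x$module, ": ", x$n_genes, " genes, ",
      length(x$vector), " samples, ",
      round(100 * x$var_explained, 1), "% variance explained\n",
      sep = "")
  invisible(x)
}

#' Module membership (kME) table with hub calls
#'
#' For each gene, kME is the Pearson correlation between the gene's raw
#' expression profile and the eigengene of its assigned module. Hubs are
#' genes with kME strictly greater than `hub_cutoff` in their own
#' module.
#'
#' @param mat Expression matrix (genes x samples).
#' @param assignment Data frame with columns `gene` and `module`, or a
#'   named character vector (gene -> module).
#' @param hub_cutoff Strict kME threshold for hub status. Default 0.5.
#' @return A tibble of class `reponet_kme` with columns `gene`,
#'   `module`, `kme`, `is_hub`; eigengenes are attached as attribute
#'   `eigengenes`. Zero-variance genes are excluded with a warning.
#' @export
kme_table <- function(mat, assignment, hub_cutoff = 0.5) {
  if (is.data.frame(assignment)) {
    assignment <- setNames(as.character(assignment$module),
                           assignment$gene)
  }
  assignment <- assignment[names(assignment) %in% rownames(mat)]
  if (length(assignment) == 0) {
    abort("No assigned gene is present in the expression matrix.")
  }
  sds <- apply(mat[names(assignment), , drop = FALSE], 1, sd)
  degenerate <- names(assignment)[sds == 0]
  if (length(degenerate) > 0) {
    warn(paste0("kME undefined for zero-variance gene(s), excluded: ",
                paste(head(degenerate, 10), collapse = ", ")))
    assignment <- assignment[sds > 0]
  }
  modules <- sort(unique(assignment))
  egs <- lapply(modules, function(m) {
    eigengene(mat, names(assignment)[assignment == m], module = m)
  })
  names(egs) <- modules
  kme <- vapply(names(assignment), function(g) {
    cor(mat[g, ], egs[[assignment[[g]]]]$vector)
  }, 0)
  out <- tibble(
    gene = names(assignment),
    module = unname(assignment),
    kme = unname(kme),
    is_hub = unname(kme) > hub_cutoff
  )
  structure(out, class = c("reponet_kme", class(out)),
            eigengenes = egs, hub_cutoff = hub_cutoff)
}

#' Hub genes of a kME table
#'
#' @param kme A `reponet_kme` tibble from [kme_table()].
#' @return Character vector of genes with kME above the cutoff in their
#'   own module (strict inequality).
#' @export
module_hubs <- function(kme) {
  if (nrow(kme) == 0) return(character(0))
  sort(kme$gene[kme$is_hub])
}
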