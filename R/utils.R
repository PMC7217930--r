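#' Derive a stage-specific random seed from a master seed
#'
#' All stochastic steps in the package draw their seed from a single master
#' integer through this splitting scheme, so that changing the master seed
#' changes every stage coherently while two different stages never share a
#' random stream.
#'
#' @param seed Master integer seed.
#' @param stage Character stage name (e.g. `"louvain"`, `"corpus"`).
#' @return An integer seed below 2^31.
#' @export
#' @examples
#' split_seed(1, "louvain")
split_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) + h * 10007) %% 2147483629L)
}

# Normalize entity labels: genes upper-cased, other kinds trimmed only.
normalize_label <- function(x, kind) {
  x <- stringr::str_squish(x)
  ifelse(kind == "gene", toupper(x), x)
}

# Apply an optional old->canonical synonym map (two-column data frame).
apply_synonyms <- function(x, synonyms) {
  if (is.null(synonyms)) return(x)
  stopifnot(ncol(synonyms) >= 2)
  idx <- match(x, synonyms[[1]])
  ifelse(is.na(idx), x, synonyms[[2]][idx])
}

# Shared validator for the (subject_kind, object_kind) pairs the pipeline
# understands.
VALID_KIND_PAIRS <- c("gene->disease", "drug->disease", "drug->gene")

check_kind_pairs <- function(subject_kind, object_kind) {
  if (length(subject_kind) == 0) return(invisible(TRUE))
  pairs <- paste0(subject_kind, "->", object_kind)
  bad <- setdiff(unique(pairs), VALID_KIND_PAIRS)
  if (length(bad) > 0) {
    abort(paste0(
      "Unsupported (subject_kind, object_kind) pair(s): ",
      paste(bad, collapse = ", "),
      ". Allowed: ", paste(VALID_KIND_PAIRS, collapse = ", ")
    ))
  }
  invisible(TRUE)
}

`%||%` <- rlang::`%||%`
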