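## Single-sample pathway activity: z-score the omics matrix on features,
## treat each sample's z-scores as a ranked signature, and run the signed +
## absolute composite enrichment of every candidate pathway against it.

#' Z-score a matrix on features
#'
#' Per feature: (x - mean)/sd across samples, sample sd (n-1 denominator).
#' Zero-variance features are dropped with a warning.
#'
#' @param matrix an [omics_matrix()] (or plain named matrix).
#' @return an [omics_matrix()] in expression space with row means 0 and
#'   sds 1.
#' @export
zscore_rows <- function(matrix) {
  x <- unclass(matrix)
  if (ncol(x) < 2) pc_stop("z-scoring needs >= 2 samples")
  v <- row_vars(x)
  if (any(v == 0)) {
    pc_warn(sum(v == 0), " constant feature(s) dropped before z-scoring")
    x <- x[v > 0, , drop = FALSE]
    v <- v[v > 0]
  }
  z <- (x - rowMeans(x)) / sqrt(v)
  omics_matrix(z, "expression")
}

## candidate pathway gene sets as a plain named list
candidate_gene_sets <- function(pathways) {
  if (inherits(pathways, "candidate_set"))
    lapply(pathways$leading_edge_genes, names)
  else if (inherits(pathways, "pathway_collection"))
    unclass(pathways)
  else if (is.list(pathways)) pathways
  else pc_stop("'pathways' must be a candidate_set, pathway_collection or list")
}

#' Per-sample composite pathway activity
#'
#' Each sample's z-score profile is ranked as a single-sample signature and
#' every candidate pathway is enriched against it in signed and
#' absolute-valued mode; the activity cell is the composite NES (lowest-p
#' rule, as at cohort level). Pathways with no gene in the matrix yield a
#' row of missing values with a warning.
#'
#' @param zscored z-scored [omics_matrix()] (see [zscore_rows()]).
#' @param pathways a `candidate_set` (its leading-edge genes are used), a
#'   `pathway_collection`, or a named list of gene vectors.
#' @param n_perm gene permutations per sample and pathway (default 1000).
#' @param seed master seed; per-sample seeds derive from it.
#' @param level omics level label carried on the result.
#' @return an `activity_matrix`: pathway x sample matrix of composite NES,
#'   with `mode` attribute holding the source mode per cell.
#' @export
sample_activity <- function(zscored, pathways, n_perm = 1000, seed = 1,
                            level = c("expression", "methylation")) {
  level <- match.arg(level)
  sets <- candidate_gene_sets(pathways)
  x <- unclass(zscored)
  feats <- rownames(x)
  present <- lapply(sets, intersect, x = feats)
  empty <- lengths(present) == 0
  if (any(empty))
    pc_warn("pathway(s) with no gene in the matrix: ",
            paste(names(sets)[empty], collapse = ", "))
  act <- matrix(NA_real_, nrow = length(sets), ncol = ncol(x),
                dimnames = list(names(sets), colnames(x)))
  mode_src <- act
  mode_src[] <- NA_character_
  storage.mode(mode_src) <- "character"
  ## seeds are derived per pathway/mode but shared across samples, so two
  ## samples with identical profiles get identical activities
  for (j in seq_len(ncol(x))) {
    sig <- ranked_signature(feats, x[, j], method = "single_sample_z")
    for (i in seq_along(sets)) {
      if (empty[i]) next
      gs <- sets[[i]]
      s <- nes_pvalue(sig, gs, pathway = names(sets)[i], n_perm = n_perm,
                      seed = derive_seed(seed, 2 * i), mode = "signed")
      a <- nes_pvalue(absolute_signature(sig), gs, pathway = names(sets)[i],
                      n_perm = n_perm, seed = derive_seed(seed, 2 * i + 1),
                      mode = "absolute")
      comp <- suppressWarnings(composite_integration(s, a))
      act[i, j] <- comp$nes
      mode_src[i, j] <- comp$source_mode
    }
  }
  structure(act, mode = mode_src, level = level,
            class = c("activity_matrix", "matrix", "array"))
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat(sprintf("activity_matrix [%s]: %d pathways x %d samples\n",
              attr(x, "level"), nrow(x), ncol(x)))
  invisible(x)
}

#' Write an activity matrix as TSV
#'
#' @param activity an `activity_matrix`.
#' @param path output path.
#' @export
write_activity <- function(activity, path) {
  write_matrix(activity, path, feature_col = "pathway")
}
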