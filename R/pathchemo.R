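## Top-level fitting function: the full discovery pipeline from omics
## matrices and response groups to the pruned set of pathways altered on
## both molecular levels.

#' Fit the integrative pathway model of chemotherapy response
#'
#' Runs the discovery pipeline end to end: differential expression and
#' methylation signatures between the extreme-responder groups, signed and
#' absolute-valued pathway enrichment with permutation NES on each omics
#' level, min-p composite integration, pathway-level enrichment of the
#' methylation-significant pathways against the |NES|-ranked expression
#' composite with query-threshold optimization, and Fisher-exact redundancy
#' pruning of the resulting candidates.
#'
#' @param expr an [omics_matrix()] of normalized expression, genes x
#'   samples.
#' @param meth an [omics_matrix()] of methylation beta values, CpG sites x
#'   samples.
#' @param map a [site_gene_map()].
#' @param collection a `pathway_collection`.
#' @param groups a `response_groups` object (e.g. from
#'   [define_response_groups()]).
#' @param method differential statistic: `"welch_t"` (default) or
#'   `"fold_change"`.
#' @param meth_mode `"one_site_per_gene"` (default) or `"all_sites"`.
#' @param n_perm gene/site/pathway permutations (default 1000).
#' @param scan_grid query p-value threshold grid.
#' @param scan_runs repeated pathway-GSEA runs per threshold (default 100).
#' @param prune prune redundant pathways (default TRUE).
#' @param seed master seed for all permutation steps.
#' @return a `pathchemo` object: list with the signatures, per-mode
#'   enrichment tables, composites, threshold scan, candidate set (pre- and
#'   post-pruning) and the call. Methods: [print.pathchemo()],
#'   [summary.pathchemo()], [plot.pathchemo()], [predict.pathchemo()].
#' @seealso [sample_activity()], [stratify()], [cox_model()] for validating
#'   the fitted pathways in an independent cohort.
#' @export
pathchemo <- function(expr, meth, map, collection, groups,
                      method = c("welch_t", "fold_change"),
                      meth_mode = c("one_site_per_gene", "all_sites"),
                      n_perm = 1000,
                      scan_grid = seq(0.001, 0.05, by = 0.005),
                      scan_runs = 100, prune = TRUE, seed = 1) {
  method <- match.arg(method)
  meth_mode <- match.arg(meth_mode)
  expr_sig <- if (method == "welch_t") welch_signature(expr, groups)
              else foldchange_signature(expr, groups)
  meth_sig <- methylation_signature(meth, map, groups, mode = meth_mode,
                                    method = method)
  enr <- list(
    expr_signed = enrich_collection(expr_sig, collection, "signed",
                                    n_perm = n_perm,
                                    seed = derive_seed(seed, 11)),
    expr_absolute = enrich_collection(expr_sig, collection, "absolute",
                                      n_perm = n_perm,
                                      seed = derive_seed(seed, 12)),
    meth_signed = enrich_collection(meth_sig, collection, "signed",
                                    n_perm = n_perm,
                                    seed = derive_seed(seed, 13)),
    meth_absolute = enrich_collection(meth_sig, collection, "absolute",
                                      n_perm = n_perm,
                                      seed = derive_seed(seed, 14)))
  expr_comp <- suppressWarnings(
    composite_integration(enr$expr_signed, enr$expr_absolute))
  meth_comp <- suppressWarnings(
    composite_integration(enr$meth_signed, enr$meth_absolute))
  scan <- threshold_scan(expr_comp, meth_comp, grid = scan_grid,
                         runs = scan_runs, n_perm = n_perm,
                         seed = derive_seed(seed, 21))
  cand <- candidate_pathways(expr_comp, meth_comp, scan = scan,
                             n_perm = n_perm, seed = derive_seed(seed, 22))
  attr(cand, "signature_genes") <- union(collapse_to_genes(expr_sig)$feature,
                                         collapse_to_genes(meth_sig)$feature)
  pruned <- if (prune && nrow(cand$pathways) > 0) prune_redundant(cand)
            else cand
  structure(list(expr_signature = expr_sig, meth_signature = meth_sig,
                 enrichment = enr, expr_composite = expr_comp,
                 meth_composite = meth_comp, scan = scan,
                 candidates_raw = cand, candidates = pruned,
                 method = method, meth_mode = meth_mode, n_perm = n_perm,
                 seed = seed, call = match.call()),
            class = "pathchemo")
}

#' @export
print.pathchemo <- function(x, ...) {
  cat("Integrative expression-methylation pathway model\n")
  cat(sprintf("  signatures: %s on %d genes / %d methylation features\n",
              x$method, nrow(x$expr_signature), nrow(x$meth_signature)))
  cat(sprintf("  optimal query threshold: %.3f\n", x$scan$optimal))
  cat(sprintf("  pathway-level enrichment: NES %.2f, p %.4g%s\n",
              x$candidates_raw$enrichment$nes, x$candidates_raw$enrichment$p,
              if (!x$candidates_raw$dual_level_signal)
                " [no dual-level signal]" else ""))
  cat(sprintf("  candidate pathways: %d before / %d after pruning\n",
              nrow(x$candidates_raw$pathways), nrow(x$candidates$pathways)))
  print.data.frame(x$candidates$pathways, digits = 3)
  invisible(x)
}

#' Summary of a fitted pathway model
#'
#' @param object a `pathchemo` fit.
#' @param ... unused.
#' @return invisibly, a list with the candidate table, scan table and
#'   top-of-list composites.
#' @export
summary.pathchemo <- function(object, ...) {
  print(object)
  cat("\nThreshold scan:\n")
  print.data.frame(object$scan$table, digits = 3)
  cat("\nTop expression composite pathways (|NES|):\n")
  print.data.frame(utils::head(
    rank_by_abs_nes(object$expr_composite)[, c("pathway", "nes", "p",
                                               "source_mode")], 5),
    digits = 3)
  invisible(list(candidates = object$candidates$pathways,
                 scan = object$scan$table))
}

#' Plot the threshold scan of a fitted model
#'
#' Mean pathway-level NES against the query p-value threshold, with the
#' optimal threshold marked.
#'
#' @param x a `pathchemo` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pathchemo <- function(x, ...) {
  tb <- x$scan$table
  graphics::plot(tb$threshold, tb$mean_nes, type = "b", pch = 19,
                 xlab = "query p-value threshold",
                 ylab = "mean pathway-level NES", ...)
  graphics::abline(v = x$scan$optimal, lty = 2)
  invisible(x)
}

#' Score new samples on the fitted candidate pathways
#'
#' Computes single-sample composite pathway activity of the (pruned)
#' candidate pathways for a new expression or methylation cohort — the
#' risk read-out applied to incoming patients.
#'
#' @param object a `pathchemo` fit.
#' @param newdata an [omics_matrix()] (genes x samples; beta matrices
#'   should be reduced to genes and converted upstream).
#' @param n_perm permutations per sample/pathway (default: the fit's).
#' @param seed integer seed.
#' @param level omics level label for the result.
#' @param ... unused.
#' @return an `activity_matrix` for the new samples.
#' @export
predict.pathchemo <- function(object, newdata, n_perm = NULL, seed = 1,
                              level = "expression", ...) {
  if (is.null(n_perm)) n_perm <- object$n_perm
  z <- zscore_rows(newdata)
  sample_activity(z, object$candidates, n_perm = n_perm, seed = seed,
                  level = level)
}
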