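## Pathway-of-pathways integration: rank the expression composite by |NES|,
## enrich the methylation-significant pathway set against it with pathway
## permutations, optimize the query p-value threshold, and prune redundant
## parent-child pathways by Fisher exact overlap tests.

#' Rank a composite signature by absolute NES
#'
#' Descending by |NES| so pathways altered in either direction rise to the
#' top; ties break by smaller p, then pathway name.
#'
#' @param composite a `composite_signature`.
#' @return the same data.frame, reordered.
#' @export
rank_by_abs_nes <- function(composite) {
  if (nrow(composite) == 0) pc_stop("empty composite signature")
  ord <- order(-abs(composite$nes), composite$p, composite$pathway)
  out <- composite[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pathway-level GSEA (pathway-of-pathways enrichment)
#'
#' The ranked "signature" items are pathways scored by the absolute
#' composite NES of the reference omics level; the query set is a group of
#' pathway names from the other level. The running-sum machinery and the
#' permutation null are identical to the gene-level engine, with pathway
#' labels permuted instead of gene labels.
#'
#' @param reference a `composite_signature` (reference omics level).
#' @param query character vector of pathway names (query set).
#' @param n_perm pathway permutations (default 1000).
#' @param seed integer seed.
#' @return one-row `enrichment_table`; its `leading_edge` holds the query
#'   pathways at or before the enrichment peak.
#' @export
pathway_gsea <- function(reference, query, n_perm = 1000, seed = 1) {
  if (length(query) == 0) pc_stop("empty query pathway set")
  ranked <- rank_by_abs_nes(reference)
  # built directly (not via ranked_signature()) to preserve the
  # rank_by_abs_nes tie order: |NES| desc, then p, then name
  sig <- structure(data.frame(feature = ranked$pathway,
                              score = abs(ranked$nes),
                              stringsAsFactors = FALSE),
                   method = "abs_nes", keyed_by = "gene",
                   class = c("ranked_signature", "data.frame"))
  bad <- setdiff(query, sig$feature)
  if (length(bad) == length(query))
    pc_stop("query pathways absent from the reference universe")
  nes_pvalue(sig, intersect(query, sig$feature), pathway = "query_set",
             n_perm = n_perm, seed = seed, mode = "signed")
}

#' Scan the query p-value threshold for the strongest pathway enrichment
#'
#' For each threshold in the grid the query set is the pathways whose
#' methylation composite p-value passes it; the pathway-level GSEA is run
#' `runs` times under derived seeds and the mean NES recorded. The optimal
#' threshold maximizes mean NES (ties resolve to the smallest threshold).
#'
#' @param expr_composite expression-level `composite_signature` (reference).
#' @param meth_composite methylation-level `composite_signature` (query
#'   source).
#' @param grid threshold grid (default 0.001 to 0.05 in steps of 0.005).
#' @param runs repeated GSEA runs per threshold (default 100).
#' @param n_perm pathway permutations per run.
#' @param seed master seed; run seeds derive deterministically from it.
#' @return a `threshold_scan` list: `table` (threshold, n_query, mean_nes),
#'   `optimal`, `runs`.
#' @export
threshold_scan <- function(expr_composite, meth_composite,
                           grid = seq(0.001, 0.05, by = 0.005),
                           runs = 100, n_perm = 1000, seed = 1) {
  if (any(grid <= 0 | grid > 0.05))
    pc_stop("thresholds must lie in (0, 0.05]")
  mean_nes <- rep(NA_real_, length(grid))
  n_query <- integer(length(grid))
  for (i in seq_along(grid)) {
    q <- meth_composite$pathway[meth_composite$p <= grid[i]]
    q <- intersect(q, expr_composite$pathway)
    n_query[i] <- length(q)
    if (length(q) == 0) next
    nes_i <- vapply(seq_len(runs), function(r) {
      pathway_gsea(expr_composite, q, n_perm = n_perm,
                   seed = derive_seed(seed, i * 1000 + r))$nes
    }, numeric(1))
    mean_nes[i] <- mean(nes_i)
  }
  if (all(is.na(mean_nes)))
    pc_stop("query set empty at every threshold")
  optimal <- grid[which.max(mean_nes)]   # first max -> smallest threshold
  structure(list(table = data.frame(threshold = grid, n_query = n_query,
                                    mean_nes = mean_nes),
                 optimal = optimal, runs = runs, n_perm = n_perm),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("threshold_scan: optimal threshold %.3f (%d runs/threshold)\n",
              x$optimal, x$runs))
  print.data.frame(x$table)
  invisible(x)
}

## tag leading-edge genes by the omics level(s) supporting them
tag_levels <- function(expr_genes, meth_genes) {
  all <- union(expr_genes, meth_genes)
  lvl <- ifelse(all %in% expr_genes & all %in% meth_genes, "both",
                ifelse(all %in% expr_genes, "expression-only",
                       "methylation-only"))
  names(lvl) <- all
  lvl
}

#' Identify candidate pathways altered on both molecular levels
#'
#' Runs the pathway-level GSEA at the optimal (or supplied) threshold; the
#' candidates are the leading-edge pathways of that enrichment. Each
#' candidate carries its expression and methylation leading-edge genes,
#' tagged `expression-only` / `methylation-only` / `both`. When the
#' pathway-level enrichment itself is not significant (p > 0.05) the set is
#' flagged as carrying no dual-level signal.
#'
#' @param expr_composite expression-level `composite_signature`.
#' @param meth_composite methylation-level `composite_signature`.
#' @param scan a `threshold_scan`, or `NULL` to use `threshold`.
#' @param threshold query p threshold used when `scan` is `NULL`.
#' @param n_perm pathway permutations.
#' @param seed integer seed.
#' @return a `candidate_set` list: `pathways` data.frame (pathway, expr_nes,
#'   expr_p, meth_nes, meth_p), `leading_edge_genes` (named list of tagged
#'   gene vectors), `enrichment` (the pathway-level result), `threshold`,
#'   `dual_level_signal`.
#' @export
candidate_pathways <- function(expr_composite, meth_composite, scan = NULL,
                               threshold = NULL, n_perm = 1000, seed = 1) {
  if (is.null(threshold)) {
    if (is.null(scan)) pc_stop("supply either a threshold_scan or a threshold")
    threshold <- scan$optimal
  }
  query <- intersect(meth_composite$pathway[meth_composite$p <= threshold],
                     expr_composite$pathway)
  if (length(query) == 0) pc_stop("no query pathway passes the threshold")
  enr <- pathway_gsea(expr_composite, query, n_perm = n_perm, seed = seed)
  cand <- enr$leading_edge[[1]]
  if (length(cand) == 0) pc_stop("empty leading edge at the optimal threshold")
  ie <- match(cand, expr_composite$pathway)
  im <- match(cand, meth_composite$pathway)
  tab <- data.frame(pathway = cand,
                    expr_nes = expr_composite$nes[ie],
                    expr_p = expr_composite$p[ie],
                    meth_nes = meth_composite$nes[im],
                    meth_p = meth_composite$p[im],
                    stringsAsFactors = FALSE)
  le <- lapply(seq_along(cand), function(j) {
    eg <- expr_composite$leading_edge[[ie[j]]]
    mg <- if (is.na(im[j])) character(0) else meth_composite$leading_edge[[im[j]]]
    tag_levels(eg, mg)
  })
  names(le) <- cand
  structure(list(pathways = tab, leading_edge_genes = le, enrichment = enr,
                 threshold = threshold,
                 dual_level_signal = enr$p <= 0.05),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf(paste0("candidate_set: %d pathway(s) at query threshold %.3f ",
                     "(pathway-level NES %.2f, p %.4g)%s\n"),
              nrow(x$pathways), x$threshold, x$enrichment$nes,
              x$enrichment$p,
              if (!x$dual_level_signal) " [no dual-level signal]" else ""))
  print.data.frame(x$pathways)
  invisible(x)
}

## union-find over candidate indices
uf_components <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (length(pairs) > 0) for (pr in pairs) {
    a <- find(pr[1]); b <- find(pr[2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  vapply(seq_len(n), find, integer(1))
}

#' Prune redundant parent-child pathways
#'
#' C2-style collections contain parent pathways that encompass their
#' children's genes; fitting such overlapping pathways jointly is redundant.
#' All pairwise Fisher exact tests on the candidates' leading-edge gene
#' overlaps are computed against a gene universe, p-values are BH-adjusted,
#' pairs with q below `q_cut` are linked, and each connected component keeps
#' one representative: the pathway whose composite NES has the lowest
#' p-value (`rep_p = "expression"` uses the expression composite p;
#' `"min"` uses the smaller of the two omics p-values).
#'
#' @param candidates a `candidate_set`.
#' @param universe gene universe for the 2x2 margins: a character vector of
#'   genes, or `NULL` to use the union of all candidate leading-edge genes
#'   plus any `signature_genes` attribute.
#' @param q_cut BH-adjusted significance cut for linking a pair.
#' @param rep_p rule for the representative's p-value.
#' @return the pruned `candidate_set`; the pairwise test table is attached
#'   as `$overlap_tests`.
#' @export
prune_redundant <- function(candidates, universe = NULL, q_cut = 0.05,
                            rep_p = c("expression", "min")) {
  rep_p <- match.arg(rep_p)
  le <- lapply(candidates$leading_edge_genes, names)
  n <- length(le)
  if (n == 0) pc_stop("no candidates to prune")
  if (is.null(universe))
    universe <- union(unlist(le),
                      attr(candidates, "signature_genes") %||% character(0))
  U <- length(unique(universe))
  if (n == 1) { candidates$overlap_tests <- NULL; return(candidates) }
  pairs <- utils::combn(n, 2)
  tests <- data.frame(a = names(le)[pairs[1, ]], b = names(le)[pairs[2, ]],
                      overlap = NA_integer_, p = NA_real_,
                      stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pairs))) {
    A <- le[[pairs[1, j]]]; B <- le[[pairs[2, j]]]
    ab <- length(intersect(A, B))
    tab <- matrix(c(ab, length(A) - ab, length(B) - ab,
                    U - length(union(A, B))), nrow = 2)
    tests$overlap[j] <- ab
    tests$p[j] <- stats::fisher.test(tab)$p.value
  }
  tests$q <- stats::p.adjust(tests$p, method = "BH")
  linked <- which(tests$q < q_cut)
  comp <- uf_components(n, lapply(linked, function(j) pairs[, j]))
  ptab <- candidates$pathways
  pval <- if (rep_p == "expression") ptab$expr_p
          else pmin(ptab$expr_p, ptab$meth_p, na.rm = TRUE)
  keep <- vapply(split(seq_len(n), comp), function(idx)
    idx[which.min(pval[idx])], integer(1))
  keep <- sort(unname(keep))
  out <- candidates
  out$pathways <- ptab[keep, , drop = FALSE]
  rownames(out$pathways) <- NULL
  out$leading_edge_genes <- candidates$leading_edge_genes[keep]
  out$overlap_tests <- tests
  out
}

#' Write a candidate pathway set as TSV
#'
#' @param candidates a `candidate_set`.
#' @param path output path.
#' @export
write_candidates <- function(candidates, path) {
  df <- candidates$pathways
  df$leading_edge <- vapply(candidates$leading_edge_genes[df$pathway],
                            function(tags)
                              paste(paste0(names(tags), "[", tags, "]"),
                                    collapse = ";"),
                            character(1))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
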