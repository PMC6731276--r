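## Read-out gene selection: for each candidate pathway, combine each
## leading-edge gene's correlation with pathway activity and its survival
## association (Cox likelihood-ratio test) via Fisher's method, and pick the
## gene with the smallest combined p-value.

#' Leading-edge candidate genes of a pathway
#'
#' The union of the expression and methylation leading-edge genes attached
#' to a candidate pathway.
#'
#' @param candidates a `candidate_set`.
#' @param pathway pathway name.
#' @return character vector of genes.
#' @export
candidate_genes <- function(candidates, pathway) {
  tags <- candidates$leading_edge_genes[[pathway]]
  if (is.null(tags) || length(tags) == 0)
    pc_stop("pathway '", pathway, "' has no leading-edge genes")
  names(tags)
}

#' Pearson correlation of a gene with pathway activity
#'
#' @param gene_values per-sample gene values.
#' @param pathway_activity per-sample pathway activity (composite NES).
#' @return list with `r` and two-sided `p` (t transform, n-2 df).
#' @export
correlate_with_activity <- function(gene_values, pathway_activity) {
  if (length(gene_values) != length(pathway_activity))
    pc_stop("vectors must have equal length")
  if (length(gene_values) < 3) pc_stop("correlation needs >= 3 samples")
  if (stats::var(gene_values) == 0 || stats::var(pathway_activity) == 0)
    pc_stop("constant vector; correlation undefined")
  ct <- stats::cor.test(gene_values, pathway_activity, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Cox likelihood-ratio p-value for a single continuous gene covariate
#'
#' @param gene_values named per-sample values.
#' @param clinical a `clinical_table`.
#' @return the LR test p-value; non-convergence is flagged as a warning and
#'   yields `NA`.
#' @export
cox_lr_gene <- function(gene_values, clinical) {
  if (stats::var(gene_values) == 0) pc_stop("constant gene; Cox undefined")
  ids <- names(gene_values)
  if (is.null(ids)) pc_stop("gene values must be named by sample id")
  idx <- match(ids, clinical$sample_id)
  if (anyNA(idx)) pc_stop("sample(s) missing from clinical table")
  cl <- clinical[idx, , drop = FALSE]
  fit <- tryCatch(
    survival::coxph(survival::Surv(cl$time_to_event, cl$event) ~ gene_values),
    warning = function(w) {
      pc_warn("Cox fit did not converge cleanly: ", conditionMessage(w))
      suppressWarnings(
        survival::coxph(survival::Surv(cl$time_to_event, cl$event) ~ gene_values))
    })
  unname(summary(fit)$logtest["pvalue"])
}

#' Combine p-values by Fisher's method
#'
#' X = -2 * sum(ln p); combined p is the upper tail of a chi-square with
#' 2k degrees of freedom.
#'
#' @param pvalues numeric vector of p-values in (0, 1\].
#' @return list with `statistic` (X) and `p`.
#' @export
fisher_combine <- function(pvalues) {
  if (length(pvalues) == 0) pc_stop("no p-values to combine")
  if (any(pvalues <= 0 | pvalues > 1)) pc_stop("p-values must lie in (0,1]")
  X <- -2 * sum(log(pvalues))
  list(statistic = X,
       p = stats::pchisq(X, df = 2 * length(pvalues), lower.tail = FALSE))
}

#' Score read-out candidates for every pathway
#'
#' For each candidate pathway and each of its leading-edge genes, computes
#' the Pearson correlation with the pathway's activity and the Cox LR
#' p-value, and combines the two p-values by Fisher's method. Expression
#' values are used for genes on the expression leading edge; M-values for
#' methylation-only genes when a methylation matrix is supplied.
#'
#' @param candidates a `candidate_set`.
#' @param activity an `activity_matrix` covering the candidate pathways.
#' @param expr an [omics_matrix()] of expression values (genes x samples).
#' @param clinical a `clinical_table`.
#' @param meth_m optional gene-keyed [omics_matrix()] of M-values for
#'   methylation-only genes.
#' @return data.frame of `readout_candidate` rows: pathway, gene, level,
#'   pearson_r, p_corr, p_lr, p_combined.
#' @export
score_readout_candidates <- function(candidates, activity, expr, clinical,
                                     meth_m = NULL) {
  samples <- colnames(activity)
  rows <- list()
  for (pw in names(candidates$leading_edge_genes)) {
    if (!pw %in% rownames(activity)) next
    act <- unclass(activity)[pw, samples]
    tags <- candidates$leading_edge_genes[[pw]]
    for (g in names(tags)) {
      src <- if (tags[[g]] == "methylation-only" && !is.null(meth_m)) meth_m
             else expr
      if (!g %in% rownames(src)) next
      vals <- unclass(src)[g, samples]
      if (stats::var(vals) == 0) next
      cr <- correlate_with_activity(vals, act)
      plr <- tryCatch(cox_lr_gene(stats::setNames(vals, samples), clinical),
                      warning = function(w) NA_real_)
      pc <- if (is.finite(plr)) fisher_combine(c(cr$p, plr))$p else NA_real_
      rows[[length(rows) + 1]] <-
        data.frame(pathway = pw, gene = g, level = tags[[g]],
                   pearson_r = cr$r, p_corr = cr$p, p_lr = plr,
                   p_combined = pc, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) pc_stop("no scoreable read-out candidate")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select one read-out gene per pathway
#'
#' Per pathway the gene with the smallest finite combined p-value wins;
#' ties break toward the larger |r|, then the gene name. Pathways with no
#' viable candidate are reported without a read-out and flagged.
#'
#' @param scored data.frame from [score_readout_candidates()].
#' @return data.frame with one row per pathway (gene `NA` when none viable).
#' @export
select_readouts <- function(scored) {
  out <- lapply(split(scored, scored$pathway), function(df) {
    ok <- is.finite(df$p_combined)
    if (!any(ok))
      return(data.frame(pathway = df$pathway[1], gene = NA_character_,
                        level = NA_character_, pearson_r = NA_real_,
                        p_corr = NA_real_, p_lr = NA_real_,
                        p_combined = NA_real_, viable = FALSE,
                        stringsAsFactors = FALSE))
    df <- df[ok, , drop = FALSE]
    df <- df[order(df$p_combined, -abs(df$pearson_r), df$gene), , drop = FALSE]
    cbind(df[1, , drop = FALSE], viable = TRUE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (any(!res$viable))
    pc_warn("pathway(s) without a viable read-out: ",
            paste(res$pathway[!res$viable], collapse = ", "))
  res
}
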