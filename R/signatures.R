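## Extreme-responder group definition and differential expression/methylation
## signatures (Welch t or fold change), the ranked inputs to enrichment.

#' Construct a ranked differential signature
#'
#' @param feature feature ids (genes, or CpG sites in all-sites mode).
#' @param score per-feature differential statistic.
#' @param method scoring method label.
#' @param keyed_by `"gene"` or `"site"`.
#' @param site_gene named character vector mapping site ids to gene symbols
#'   (required when `keyed_by = "site"`).
#' @return a `ranked_signature` data.frame sorted descending by score.
#' @export
ranked_signature <- function(feature, score, method = "welch_t",
                             keyed_by = c("gene", "site"), site_gene = NULL) {
  keyed_by <- match.arg(keyed_by)
  feature <- as.character(feature)
  if (anyDuplicated(feature)) pc_stop("duplicate features in signature")
  if (any(!is.finite(score))) pc_stop("non-finite signature scores")
  ord <- order(-score)                       # stable: ties keep input order
  df <- data.frame(feature = feature[ord], score = score[ord],
                   stringsAsFactors = FALSE)
  structure(df, method = method, keyed_by = keyed_by, site_gene = site_gene,
            class = c("ranked_signature", "data.frame"))
}

#' @export
print.ranked_signature <- function(x, n = 6, ...) {
  cat(sprintf("ranked_signature (%s, keyed by %s): %d features\n",
              attr(x, "method"), attr(x, "keyed_by"), nrow(x)))
  print.data.frame(utils::head(x, n))
  invisible(x)
}

#' Write a ranked signature as two-column TSV
#'
#' @param signature a `ranked_signature`.
#' @param path output path.
#' @export
write_signature <- function(signature, path) {
  utils::write.table(as.data.frame(signature), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Define extreme-responder groups from clinical follow-up
#'
#' Restricted to patients on the given therapy without neoadjuvant treatment:
#' poor responders relapse within `poor_window` days of therapy start;
#' favorable responders remain event-free for more than `favorable_min` days.
#' Everyone else (event in the gap, or censored with short follow-up) is
#' excluded from the contrast.
#'
#' @param clinical a `clinical_table`.
#' @param therapy therapy label to select on (exact match).
#' @param poor_window days within which an event marks poor response
#'   (default 365).
#' @param favorable_min minimum event-free follow-up, in days, for favorable
#'   response (default 730).
#' @return a `response_groups` list with `poor`, `favorable`, `excluded`
#'   sample-id sets and the thresholds.
#' @export
define_response_groups <- function(clinical, therapy = NULL,
                                   poor_window = 365, favorable_min = 730) {
  cl <- clinical
  if (!is.null(therapy)) cl <- cl[cl$therapy == therapy, , drop = FALSE]
  cl <- cl[cl$neoadjuvant == 0, , drop = FALSE]
  if (nrow(cl) == 0) pc_stop("no samples match therapy/neoadjuvant filter")
  poor <- cl$sample_id[cl$event == 1 & cl$time_to_event <= poor_window]
  fav <- cl$sample_id[cl$event == 0 & cl$time_to_event > favorable_min]
  excl <- setdiff(cl$sample_id, c(poor, fav))
  if (length(poor) == 0 || length(fav) == 0)
    pc_stop("empty response group (poor: ", length(poor), ", favorable: ",
            length(fav), "); review the poor_window/favorable_min thresholds")
  structure(list(poor = poor, favorable = fav, excluded = excl,
                 thresholds = c(poor_window = poor_window,
                                favorable_min = favorable_min)),
            class = "response_groups")
}

#' Construct response groups directly from sample-id sets
#'
#' @param poor,favorable,excluded disjoint sample-id vectors.
#' @return a `response_groups` object.
#' @export
response_groups <- function(poor, favorable, excluded = character(0)) {
  if (length(intersect(poor, favorable)) > 0)
    pc_stop("poor and favorable groups overlap")
  structure(list(poor = as.character(poor),
                 favorable = as.character(favorable),
                 excluded = as.character(excluded),
                 thresholds = c(poor_window = NA, favorable_min = NA)),
            class = "response_groups")
}

#' @export
print.response_groups <- function(x, ...) {
  cat(sprintf("response_groups: %d poor, %d favorable, %d excluded\n",
              length(x$poor), length(x$favorable), length(x$excluded)))
  invisible(x)
}

#' Check covariate balance between response groups
#'
#' Numeric covariates are compared with a two-sided Welch t-test, categorical
#' ones with a Fisher exact test; covariates with p < `alpha` are flagged so
#' the caller can rebalance by exclusion (stratified sub-sampling).
#'
#' @param groups a `response_groups` object.
#' @param clinical a `clinical_table`.
#' @param covariates covariate column names (default age, gender, stage).
#' @param alpha flag threshold (default 0.05).
#' @return data.frame with covariate, test, p, flagged, note.
#' @export
balance_check <- function(groups, clinical,
                          covariates = c("age", "gender", "stage"),
                          alpha = 0.05) {
  miss <- setdiff(covariates, names(clinical))
  if (length(miss) > 0)
    pc_stop("covariate(s) missing from clinical table: ",
            paste(miss, collapse = ", "))
  gp <- clinical[match(groups$poor, clinical$sample_id), , drop = FALSE]
  gf <- clinical[match(groups$favorable, clinical$sample_id), , drop = FALSE]
  res <- lapply(covariates, function(cv) {
    vp <- gp[[cv]]; vf <- gf[[cv]]
    if (is.numeric(vp)) {
      if (stats::var(c(vp, vf)) == 0)
        return(data.frame(covariate = cv, test = "welch_t", p = 1,
                          note = "constant covariate"))
      p <- tryCatch(stats::t.test(vp, vf)$p.value, error = function(e) 1)
      data.frame(covariate = cv, test = "welch_t", p = p, note = "")
    } else {
      tab <- table(factor(c(rep("poor", length(vp)), rep("favorable", length(vf))),
                          levels = c("poor", "favorable")),
                   c(as.character(vp), as.character(vf)))
      if (ncol(tab) < 2)
        return(data.frame(covariate = cv, test = "fisher_exact", p = 1,
                          note = "constant covariate"))
      data.frame(covariate = cv, test = "fisher_exact",
                 p = stats::fisher.test(tab)$p.value, note = "")
    }
  })
  out <- do.call(rbind, res)
  out$flagged <- out$p < alpha
  rownames(out) <- NULL
  out[, c("covariate", "test", "p", "flagged", "note")]
}

## vectorized two-sample Welch t with Welch-Satterthwaite df
welch_rows <- function(x_poor, x_fav) {
  n1 <- ncol(x_poor); n2 <- ncol(x_fav)
  m1 <- rowMeans(x_poor); m2 <- rowMeans(x_fav)
  v1 <- row_vars(x_poor); v2 <- row_vars(x_fav)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, zero_var = se2 == 0)
}

split_groups <- function(matrix, groups) {
  sp <- intersect(groups$poor, colnames(matrix))
  sf <- intersect(groups$favorable, colnames(matrix))
  if (length(sp) < 2 || length(sf) < 2)
    pc_stop("each response group needs >= 2 samples in the matrix (poor: ",
            length(sp), ", favorable: ", length(sf), ")")
  list(poor = unclass(matrix)[, sp, drop = FALSE],
       favorable = unclass(matrix)[, sf, drop = FALSE])
}

#' Welch t differential signature
#'
#' Per-feature two-sample two-tailed Welch t statistic oriented as
#' poor minus favorable; features with zero variance in both groups are
#' dropped with a warning. The result is sorted descending by t.
#'
#' @param matrix an [omics_matrix()] (expression or M-values).
#' @param groups a `response_groups` object.
#' @return a `ranked_signature` with `method = "welch_t"`.
#' @export
welch_signature <- function(matrix, groups) {
  g <- split_groups(matrix, groups)
  w <- welch_rows(g$poor, g$favorable)
  if (any(w$zero_var)) {
    pc_warn(sum(w$zero_var), " feature(s) with zero variance in both groups dropped")
  }
  keep <- !w$zero_var
  ranked_signature(rownames(g$poor)[keep], w$t[keep], method = "welch_t")
}

#' Fold-change differential signature
#'
#' Score = mean(poor) - mean(favorable) on the already log-scale values,
#' i.e. a log2 fold change.
#'
#' @inheritParams welch_signature
#' @return a `ranked_signature` with `method = "fold_change"`.
#' @export
foldchange_signature <- function(matrix, groups) {
  g <- split_groups(matrix, groups)
  fc <- rowMeans(g$poor) - rowMeans(g$favorable)
  ranked_signature(rownames(g$poor), fc, method = "fold_change")
}

#' Differential methylation signature
#'
#' Two modes: `one_site_per_gene` reduces the site matrix to one site per
#' gene by the coefficient-of-variation rule before scoring, giving a
#' gene-keyed signature; `all_sites` scores every site and keeps the
#' site-to-gene map attached for enrichment. Welch t is computed on M-values
#' (parametric), fold change on beta values.
#'
#' @param meth an [omics_matrix()] in beta space, sites in rows.
#' @param map a [site_gene_map()].
#' @param groups a `response_groups` object.
#' @param mode `"one_site_per_gene"` or `"all_sites"`.
#' @param method `"welch_t"` or `"fold_change"`.
#' @param epsilon clip bound for the beta-to-M transform.
#' @return a `ranked_signature`.
#' @export
methylation_signature <- function(meth, map, groups,
                                  mode = c("one_site_per_gene", "all_sites"),
                                  method = c("welch_t", "fold_change"),
                                  epsilon = 1e-6) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (omics_space(meth) != "beta")
    pc_stop("methylation_signature expects a beta-space matrix")
  present <- intersect(map$site_id, rownames(meth))
  if (length(present) == 0)
    pc_stop("no overlap between site-gene map and methylation matrix")
  if (mode == "one_site_per_gene") {
    x <- select_site_per_gene(meth, map)
    vals <- if (method == "welch_t")
      omics_matrix(beta_to_m(unclass(x), epsilon), "mvalue") else x
    sig <- if (method == "welch_t") welch_signature(vals, groups)
           else foldchange_signature(vals, groups)
    attr(sig, "keyed_by") <- "gene"
    sig
  } else {
    x <- unclass(meth)[present, , drop = FALSE]
    vals <- omics_matrix(if (method == "welch_t") beta_to_m(x, epsilon) else x,
                         if (method == "welch_t") "mvalue" else "beta")
    sig <- if (method == "welch_t") welch_signature(vals, groups)
           else foldchange_signature(vals, groups)
    sg <- map$gene[match(sig$feature, map$site_id)]
    names(sg) <- sig$feature
    attr(sig, "keyed_by") <- "site"
    attr(sig, "site_gene") <- sg
    sig
  }
}

#' Collapse a site-keyed signature to gene level
#'
#' When a gene has several CpG sites, the site with the largest absolute
#' score represents it (the strongest differential signal).
#'
#' @param signature a site-keyed `ranked_signature` carrying a `site_gene`
#'   attribute.
#' @return a gene-keyed `ranked_signature`.
#' @export
collapse_to_genes <- function(signature) {
  if (identical(attr(signature, "keyed_by"), "gene")) return(signature)
  sg <- attr(signature, "site_gene")
  if (is.null(sg)) pc_stop("site-keyed signature without a site_gene map")
  gene <- unname(sg[signature$feature])
  keep <- !is.na(gene)
  df <- data.frame(gene = gene[keep], score = signature$score[keep],
                   stringsAsFactors = FALSE)
  # signature rows are |score|-agnostic rank order; pick max |score| per gene
  df <- df[order(-abs(df$score)), , drop = FALSE]
  df <- df[!duplicated(df$gene), , drop = FALSE]
  ranked_signature(df$gene, df$score, method = attr(signature, "method"))
}
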