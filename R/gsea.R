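## Weighted running-sum gene set enrichment with gene-permutation NES and
## empirical p-values, in signed and absolute-valued modes, and the min-p
## composite integration of the two modes.
##
## Running-sum statistic: walking down the ranked signature, each gene in the
## set ("hit") increments the sum by |score|^weight_exp normalized by the sum
## of those weights over the set; each miss decrements by 1/(N - N_hits).
## ES is the extremum of largest absolute deviation; at an exact tie between
## the positive and negative extremum the positive one is taken.

## O(k) ES from sorted hit positions; w = |score|^p at those positions.
## Returns es and the extremum hit index (leading edge boundary).
es_from_hits <- function(pos, w, N) {
  k <- length(pos)
  sw <- sum(w)
  if (sw <= 0) pc_stop("all hit scores are zero; weighting undefined")
  cw <- cumsum(w) / sw
  nm <- N - k
  miss <- if (nm == 0) rep(0, k) else (pos - seq_len(k)) / nm
  top <- cw - miss                # running sum just after each hit
  bot <- c(0, cw[-k]) - miss      # running sum just before each hit
  maxdev <- max(top)
  mindev <- min(bot)
  if (maxdev >= -mindev) {
    i <- which.max(top)
    list(es = maxdev, peak = i, positive = TRUE)
  } else {
    i <- which.min(bot)
    list(es = mindev, peak = i, positive = FALSE)
  }
}

#' Running-sum enrichment score for one gene set
#'
#' @param signature a `ranked_signature`.
#' @param gene_set character vector of member features.
#' @param weight_exp exponent on |score| for hit increments (default 1,
#'   classic weighted GSEA).
#' @return list with `es`, the full `running_sum` vector over the ranked
#'   list, and the `leading_edge` feature vector (hits at or before a
#'   positive extremum; at or after a negative one).
#' @export
enrichment_score <- function(signature, gene_set, weight_exp = 1) {
  if (nrow(signature) < 2) pc_stop("signature needs >= 2 features")
  hit <- signature$feature %in% gene_set
  k <- sum(hit)
  if (k == 0) pc_stop("gene set has no overlap with the signature")
  N <- nrow(signature)
  pos <- which(hit)
  w <- abs(signature$score[pos])^weight_exp
  core <- es_from_hits(pos, w, N)
  # full running sum for inspection/plotting
  step <- rep(if (N == k) 0 else -1 / (N - k), N)
  sw <- sum(w)
  step[pos] <- w / sw
  rs <- cumsum(step)
  le <- if (core$positive) signature$feature[pos[seq_len(core$peak)]]
        else signature$feature[pos[seq(core$peak, k)]]
  list(es = core$es, running_sum = rs, leading_edge = le)
}

#' Absolute-valued signature
#'
#' Replaces scores by their absolute values and re-sorts descending,
#' collapsing the positive and negative signature tails; ties keep the
#' original rank order.
#'
#' @param signature a `ranked_signature`.
#' @return a `ranked_signature` with non-negative scores.
#' @export
absolute_signature <- function(signature) {
  ord <- order(-abs(signature$score))   # stable sort: ties by original rank
  out <- signature
  out$feature <- signature$feature[ord]
  out$score <- abs(signature$score[ord])
  attr(out, "method") <- paste0("abs_", attr(signature, "method"))
  out
}

## Null ES distribution: permuting gene labels of the signature is equivalent
## to drawing the k hit positions uniformly without replacement.
null_es <- function(weights, k, n_perm, seed) {
  N <- length(weights)
  set.seed(seed)
  out <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    pos <- sort.int(sample.int(N, k))
    w <- weights[pos]
    sw <- sum(w)
    if (sw <= 0) { out[i] <- 0; next }
    cw <- cumsum(w) / sw
    nm <- N - k
    miss <- if (nm == 0) 0 else (pos - seq_len(k)) / nm
    top <- cw - miss
    bot <- c(0, cw[-k]) - miss
    maxdev <- max(top)
    mindev <- min(bot)
    out[i] <- if (maxdev >= -mindev) maxdev else mindev
  }
  out
}

#' Permutation-normalized enrichment for one gene set
#'
#' The null ES distribution comes from `n_perm` gene-label permutations of
#' the signature. NES = ES divided by the mean null ES of matching sign;
#' the empirical p-value conditions on matching-sign permutations and uses
#' the add-one estimator (r+1)/(m+1) so p >= 1/(n_perm+1).
#'
#' @inheritParams enrichment_score
#' @param pathway pathway name to record.
#' @param n_perm number of gene permutations (default 1000).
#' @param seed integer seed; identical seeds give identical results.
#' @param mode label recorded in the result (`"signed"` or `"absolute"`).
#' @return one-row `enrichment_table` data.frame with columns pathway, es,
#'   nes, p, size, mode, n_perm and list-column leading_edge.
#' @export
nes_pvalue <- function(signature, gene_set, pathway = "set",
                       n_perm = 1000, seed = 1, weight_exp = 1,
                       mode = "signed") {
  if (n_perm < 100) pc_stop("n_perm must be >= 100")
  obs <- enrichment_score(signature, gene_set, weight_exp)
  k <- sum(signature$feature %in% gene_set)
  weights <- abs(signature$score)^weight_exp
  nulls <- null_es(weights, k, n_perm, seed)
  es <- obs$es
  same <- if (es >= 0) nulls[nulls > 0] else nulls[nulls < 0]
  if (length(same) == 0) {
    pc_warn("no matching-sign null draws for '", pathway,
            "'; p set to 1/(n_perm+1)")
    p <- 1 / (n_perm + 1)
    nes <- es / mean(abs(nulls[nulls != 0]), na.rm = TRUE)
    if (!is.finite(nes)) nes <- 0
  } else {
    p <- (sum(abs(same) >= abs(es)) + 1) / (length(same) + 1)
    nes <- es / abs(mean(same))
  }
  res <- data.frame(pathway = pathway, es = es, nes = nes, p = p,
                    size = k, mode = mode, n_perm = n_perm,
                    stringsAsFactors = FALSE)
  res$leading_edge <- list(obs$leading_edge)
  class(res) <- c("enrichment_table", "data.frame")
  res
}

#' Enrich a pathway collection against a signature
#'
#' Runs [nes_pvalue()] for every pathway with at least one signature gene.
#' In absolute mode the signature is absolute-valued first and negative-NES
#' results are flagged ineligible (they reflect enrichment in the
#' non-changed part of the signature). Site-keyed signatures are collapsed
#' to gene level first (strongest site per gene).
#'
#' @param signature a `ranked_signature`.
#' @param collection a `pathway_collection`.
#' @param mode `"signed"` or `"absolute"`.
#' @param n_perm permutations per pathway.
#' @param seed master seed; per-pathway seeds are derived from it.
#' @param weight_exp hit-weight exponent.
#' @return an `enrichment_table` with one row per overlapping pathway and an
#'   `eligible` column; skipped (non-overlapping) pathway names are attached
#'   as attribute `skipped`.
#' @export
enrich_collection <- function(signature, collection,
                              mode = c("signed", "absolute"),
                              n_perm = 1000, seed = 1, weight_exp = 1) {
  mode <- match.arg(mode)
  if (length(collection) == 0) pc_stop("empty pathway collection")
  signature <- collapse_to_genes(signature)
  sig <- if (mode == "absolute") absolute_signature(signature) else signature
  weights <- abs(sig$score)^weight_exp
  feats <- sig$feature
  rows <- vector("list", length(collection))
  skipped <- character(0)
  for (i in seq_along(collection)) {
    nm <- names(collection)[i]
    gs <- collection[[i]]
    if (!any(feats %in% gs)) { skipped <- c(skipped, nm); next }
    rows[[i]] <- nes_pvalue(sig, gs, pathway = nm, n_perm = n_perm,
                            seed = derive_seed(seed, i),
                            weight_exp = weight_exp, mode = mode)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) pc_stop("no pathway overlaps the signature")
  out <- do.call(rbind, rows)
  out$eligible <- mode == "signed" | out$nes > 0
  attr(out, "skipped") <- skipped
  attr(out, "mode") <- mode
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Integrate signed and absolute-valued enrichment per pathway
#'
#' The composite NES of a pathway is the NES with the lowest p-value between
#' the signed result and the absolute-valued result, where absolute-valued
#' results with negative NES are never considered. At an exact p tie the
#' signed result is preferred (directional information retained). Pathways
#' with no eligible result are dropped with a warning.
#'
#' @param signed `enrichment_table` from signed-mode [enrich_collection()].
#' @param absolute `enrichment_table` from absolute mode.
#' @return a `composite_signature` data.frame: pathway, nes, p, es,
#'   source_mode, leading_edge (list).
#' @export
composite_integration <- function(signed, absolute) {
  univ <- union(signed$pathway, absolute$pathway)
  is_row <- match(univ, signed$pathway)
  ia_row <- match(univ, absolute$pathway)
  rows <- vector("list", length(univ))
  dropped <- character(0)
  for (j in seq_along(univ)) {
    s <- if (!is.na(is_row[j])) signed[is_row[j], ] else NULL
    a <- if (!is.na(ia_row[j])) absolute[ia_row[j], ] else NULL
    if (!is.null(a) && a$nes <= 0) a <- NULL    # negative-abs exclusion
    pick <- if (is.null(s) && is.null(a)) NULL
            else if (is.null(a)) s
            else if (is.null(s)) a
            else if (a$p < s$p) a else s        # tie -> signed
    if (is.null(pick)) { dropped <- c(dropped, univ[j]); next }
    rows[[j]] <- data.frame(pathway = univ[j], nes = pick$nes, p = pick$p,
                            es = pick$es, source_mode = pick$mode,
                            stringsAsFactors = FALSE)
    rows[[j]]$leading_edge <- pick$leading_edge
  }
  if (length(dropped) > 0)
    pc_warn(length(dropped), " pathway(s) with no eligible result dropped: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) pc_stop("no pathway has an eligible result")
  out <- do.call(rbind, rows)
  class(out) <- c("composite_signature", "data.frame")
  out
}

#' @export
print.composite_signature <- function(x, n = 6, ...) {
  cat(sprintf("composite_signature: %d pathways\n", nrow(x)))
  print.data.frame(utils::head(x[, c("pathway", "nes", "p", "source_mode")], n))
  invisible(x)
}

#' Write per-pathway enrichment results as TSV
#'
#' @param results an `enrichment_table` or `composite_signature`.
#' @param path output path.
#' @export
write_enrichment <- function(results, path) {
  df <- as.data.frame(results)
  if (!is.null(df$leading_edge))
    df$leading_edge <- vapply(df$leading_edge, paste, character(1),
                              collapse = ";")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
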