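## Validation layer: t-SNE two-group stratification of pathway activity,
## Kaplan-Meier/log-rank and Cox proportional-hazards comparison, random
## pathway/group null models, LOOCV risk prediction and ROC.

#' Stratify patients into high/low activity groups
#'
#' Embeds the pathway-activity profiles into two dimensions with t-SNE and
#' cuts the embedding with 2-means (multiple restarts under a derived
#' seed). The group with the larger mean composite activity across pathways
#' is labeled `high`.
#'
#' @param activity an `activity_matrix` (pathways x samples).
#' @param seed integer seed controlling both embedding and clustering.
#' @param perplexity t-SNE perplexity; default `min(10, floor((n-1)/3))`.
#' @param scale_activity z-score each pathway across samples before
#'   embedding (default FALSE: raw NES).
#' @param max_iter t-SNE iterations.
#' @return a `stratification` list: `embedding` (n x 2), `group` (named
#'   factor high/low), `perplexity`, `seed`.
#' @export
stratify <- function(activity, seed = 1, perplexity = NULL,
                     scale_activity = FALSE, max_iter = 500) {
  x <- t(unclass(activity))
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]
  n <- nrow(x)
  if (n < 6) pc_stop("stratification needs >= 6 samples")
  if (is.null(perplexity)) {
    cap <- (n - 1) / 3   # hard upper bound, exclusive
    perplexity <- min(10, if (floor(cap) < cap) floor(cap) else cap - 1)
  }
  if (perplexity >= (n - 1) / 3)
    pc_stop("perplexity must be < (n-1)/3; try ", floor((n - 1) / 3) - 1)
  if (scale_activity) x <- scale(x)
  emb <- tsne_embed(x, dims = 2, perplexity = perplexity,
                    max_iter = max_iter, seed = derive_seed(seed, 1))
  rownames(emb) <- rownames(x)
  set.seed(derive_seed(seed, 2))
  km <- stats::kmeans(emb, centers = 2, nstart = 10)
  mean_act <- colMeans(unclass(activity)[, rownames(x), drop = FALSE],
                       na.rm = TRUE)
  g1 <- mean(mean_act[km$cluster == 1])
  g2 <- mean(mean_act[km$cluster == 2])
  lab <- if (g1 >= g2) c("high", "low") else c("low", "high")
  group <- factor(lab[km$cluster], levels = c("low", "high"))
  names(group) <- rownames(x)
  if (length(unique(group)) < 2) pc_stop("degenerate stratification: one group")
  structure(list(embedding = emb, group = group, perplexity = perplexity,
                 seed = seed),
            class = "stratification")
}

#' @export
print.stratification <- function(x, ...) {
  cat(sprintf("stratification: %d high / %d low (perplexity %s)\n",
              sum(x$group == "high"), sum(x$group == "low"), x$perplexity))
  invisible(x)
}

## align a clinical table with a label vector
align_clinical <- function(group, clinical) {
  ids <- names(group)
  if (is.null(ids)) pc_stop("group labels must be named by sample id")
  idx <- match(ids, clinical$sample_id)
  if (anyNA(idx)) pc_stop("sample(s) missing from clinical table: ",
                          paste(ids[is.na(idx)], collapse = ", "))
  clinical[idx, , drop = FALSE]
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square with 1 df comparing the survival curves of
#' the two groups.
#'
#' @param group named two-level factor/character of group labels.
#' @param clinical a `clinical_table` covering the named samples.
#' @return list with `statistic`, `p`, `n_per_group`, `observed`,
#'   `expected`.
#' @export
km_logrank <- function(group, clinical) {
  cl <- align_clinical(group, clinical)
  g <- factor(group)
  if (nlevels(g) != 2 || any(table(g) == 0))
    pc_stop("log-rank requires two non-empty groups")
  if (sum(cl$event) == 0)
    return(list(statistic = 0, p = 1, n_per_group = table(g),
                observed = c(0, 0), expected = c(0, 0),
                note = "no events in either group"))
  sd <- survival::survdiff(
    survival::Surv(cl$time_to_event, cl$event) ~ g)
  list(statistic = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       n_per_group = table(g), observed = sd$obs, expected = sd$exp)
}

#' Cox proportional-hazards comparison
#'
#' Fits a (multivariable) Cox model of time-to-event on the supplied
#' covariates; reports per-covariate hazard ratios with 95% intervals and
#' the likelihood-ratio test against the null model (preferred over Wald
#' for small samples). When a `group` column is present, a univariable
#' group-only fit provides the headline hazard ratio.
#'
#' @param design data.frame of covariates, one row per sample, rownames or
#'   `sample_id` column identifying samples; a two-level `group` column is
#'   treated as the stratification of interest.
#' @param clinical a `clinical_table`.
#' @return a `survival_comparison` list: `coefficients` data.frame
#'   (term, hr, hr_lo, hr_hi, p), `lr_stat`, `lr_p`, `hr` (headline),
#'   `hr_ci`, `n`, `flags`.
#' @export
cox_model <- function(design, clinical) {
  ids <- if (!is.null(design$sample_id)) design$sample_id else rownames(design)
  if (is.null(ids)) pc_stop("design must carry sample ids")
  design <- design[, setdiff(names(design), "sample_id"), drop = FALSE]
  const <- vapply(design, function(v) length(unique(v)) < 2, logical(1))
  if (any(const)) pc_stop("constant covariate(s): ",
                          paste(names(design)[const], collapse = ", "))
  idx <- match(ids, clinical$sample_id)
  if (anyNA(idx)) pc_stop("design samples missing from clinical table")
  cl <- clinical[idx, , drop = FALSE]
  if (sum(cl$event) < 1) pc_stop("no events; Cox model undefined")
  dat <- cbind(data.frame(.time = cl$time_to_event, .event = cl$event),
               design)
  fit <- tryCatch(
    survival::coxph(survival::Surv(.time, .event) ~ ., data = dat),
    warning = function(w) {
      f <- suppressWarnings(
        survival::coxph(survival::Surv(.time, .event) ~ ., data = dat))
      attr(f, "flag") <- conditionMessage(w)
      f
    },
    error = function(e) pc_stop("Cox fit failed: ", conditionMessage(e)))
  flags <- attr(fit, "flag")
  if (any(abs(stats::coef(fit)) > 15))
    flags <- c(flags, "possible complete separation (|coef| > 15)")
  s <- summary(fit)
  co <- data.frame(term = rownames(s$coefficients),
                   hr = s$conf.int[, "exp(coef)"],
                   hr_lo = s$conf.int[, "lower .95"],
                   hr_hi = s$conf.int[, "upper .95"],
                   p = s$coefficients[, "Pr(>|z|)"],
                   stringsAsFactors = FALSE, row.names = NULL)
  lr_stat <- unname(s$logtest["test"])
  lr_p <- unname(s$logtest["pvalue"])
  hr <- NA_real_; hr_ci <- c(NA_real_, NA_real_)
  if ("group" %in% names(design)) {
    uf <- summary(survival::coxph(
      survival::Surv(.time, .event) ~ group,
      data = dat))
    hr <- unname(uf$conf.int[1, "exp(coef)"])
    hr_ci <- unname(uf$conf.int[1, c("lower .95", "upper .95")])
  }
  structure(list(coefficients = co, lr_stat = lr_stat, lr_p = lr_p,
                 hr = hr, hr_ci = hr_ci, n = nrow(dat), fit = fit,
                 flags = flags),
            class = "survival_comparison")
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat(sprintf("survival_comparison: n = %d, LR p = %.4g\n", x$n, x$lr_p))
  if (!is.na(x$hr))
    cat(sprintf("  headline group HR = %.3f [%.3f, %.3f]\n",
                x$hr, x$hr_ci[1], x$hr_ci[2]))
  print.data.frame(x$coefficients, digits = 3)
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Per-sample score of a published gene signature
#'
#' The mean of per-gene z-scores across the signature genes present in the
#' matrix; used to adjust survival models for known aggressiveness
#' signatures.
#'
#' @param expr an [omics_matrix()] of expression values.
#' @param gene_list character vector of signature genes.
#' @return named numeric vector of per-sample scores.
#' @export
signature_covariate <- function(expr, gene_list) {
  genes <- intersect(toupper(gene_list), rownames(expr))
  if (length(genes) == 0) pc_stop("no signature gene present in the matrix")
  z <- unclass(zscore_rows(unclass(expr)[genes, , drop = FALSE]))
  colMeans(z)
}

empirical_p <- function(observed, nulls) {
  (sum(nulls <= observed) + 1) / (length(nulls) + 1)
}

#' Random pathway null model (random model 1)
#'
#' Draws `n_draws` random sets of `k` pathways from the collection,
#' recomputes single-sample activity, stratifies and runs the log-rank
#' test; the empirical p-value is the add-one fraction of null log-rank
#' p-values at or below the observed one.
#'
#' @param observed_p log-rank p of the real candidate-pathway model.
#' @param zscored z-scored [omics_matrix()] of the validation cohort.
#' @param collection a `pathway_collection` to draw from.
#' @param clinical a `clinical_table`.
#' @param k pathways per draw (default 7).
#' @param n_draws number of random draws (default 10000).
#' @param n_perm permutations inside [sample_activity()] per draw.
#' @param seed master seed.
#' @param stratify_args extra arguments passed to [stratify()].
#' @return a `random_model` list: `observed_p`, `null_ps`, `empirical_p`,
#'   `n_resampled` (infeasible draws that were redrawn).
#' @export
random_pathway_model <- function(observed_p, zscored, collection, clinical,
                                 k = 7, n_draws = 10000, n_perm = 1000,
                                 seed = 1, stratify_args = list()) {
  if (length(collection) <= k)
    pc_stop("collection must hold more than k pathways")
  null_ps <- numeric(n_draws)
  n_resampled <- 0L
  feats <- rownames(zscored)
  for (d in seq_len(n_draws)) {
    repeat {
      set.seed(derive_seed(seed, d + n_resampled * 104729))
      idx <- sample.int(length(collection), k)
      sets <- unclass(collection)[idx]
      if (any(vapply(sets, function(g) any(feats %in% g), logical(1)))) break
      n_resampled <- n_resampled + 1L
    }
    act <- suppressWarnings(
      sample_activity(zscored, sets, n_perm = n_perm,
                      seed = derive_seed(seed, 7919 + d)))
    st <- do.call(stratify, c(list(activity = act,
                                   seed = derive_seed(seed, 15485863 + d)),
                              stratify_args))
    null_ps[d] <- km_logrank(st$group, clinical)$p
  }
  structure(list(observed_p = observed_p, null_ps = null_ps,
                 empirical_p = empirical_p(observed_p, null_ps),
                 n_resampled = n_resampled, model = "random_pathways"),
            class = "random_model")
}

#' Random patient-group null model (random model 2)
#'
#' Repeatedly partitions the cohort into random groups of the observed
#' sizes and records the log-rank p of each partition.
#'
#' @param observed_p log-rank p of the real stratification.
#' @param n_per_group integer vector of the observed group sizes.
#' @param clinical a `clinical_table` for the cohort (its first
#'   `sum(n_per_group)` rows are used if larger).
#' @param n_draws number of random partitions (default 10000).
#' @param seed integer seed.
#' @return a `random_model` list as in [random_pathway_model()].
#' @export
random_group_model <- function(observed_p, n_per_group, clinical,
                               n_draws = 10000, seed = 1) {
  n <- sum(n_per_group)
  if (n > nrow(clinical)) pc_stop("group sizes exceed the cohort")
  ids <- clinical$sample_id[seq_len(n)]
  set.seed(seed)
  null_ps <- vapply(seq_len(n_draws), function(d) {
    lab <- rep("B", n)
    lab[sample.int(n, n_per_group[1])] <- "A"
    names(lab) <- ids
    km_logrank(lab, clinical)$p
  }, numeric(1))
  structure(list(observed_p = observed_p, null_ps = null_ps,
                 empirical_p = empirical_p(observed_p, null_ps),
                 n_resampled = 0L, model = "random_groups"),
            class = "random_model")
}

#' @export
print.random_model <- function(x, ...) {
  cat(sprintf("%s null model: observed p = %.4g, empirical p = %.4g (%d draws)\n",
              x$model, x$observed_p, x$empirical_p, length(x$null_ps)))
  invisible(x)
}

#' Leave-one-out cross-validated risk prediction
#'
#' For each sample a multivariable logistic regression of the binary
#' outcome on the pathway activities is fitted on the remaining samples and
#' the held-out sample's risk predicted. Folds with complete separation
#' fall back to a ridge-penalized fit and are flagged.
#'
#' @param activity an `activity_matrix` (pathways x samples).
#' @param outcome named binary vector (0/1) over the samples.
#' @return a `loocv_result` list: `risk` (per-sample probability),
#'   `predicted` (at 0.5), `accuracy`, `flagged_folds`.
#' @export
loocv_risk <- function(activity, outcome) {
  x <- t(unclass(activity))
  ids <- rownames(x)
  y <- outcome[ids]
  if (anyNA(y)) pc_stop("outcome missing for sample(s): ",
                        paste(ids[is.na(y)], collapse = ", "))
  n <- nrow(x)
  if (n < 8) pc_stop("LOOCV needs >= 8 samples")
  if (length(unique(y)) < 2) pc_stop("both outcome classes must be present")
  risk <- numeric(n)
  flagged <- character(0)
  for (i in seq_len(n)) {
    xi <- x[-i, , drop = FALSE]; yi <- y[-i]
    dat <- data.frame(y = yi, xi)
    fit <- withCallingHandlers(
      stats::glm(y ~ ., data = dat, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w)))
          flagged <<- union(flagged, ids[i])
        invokeRestart("muffleWarning")
      })
    if (ids[i] %in% flagged) {
      # ridge fallback for separated folds (glmnet's small-n warning is
      # expected here; the fold is already flagged)
      rf <- suppressWarnings(
        glmnet::glmnet(xi, yi, family = "binomial", alpha = 0, lambda = 0.1))
      risk[i] <- as.numeric(stats::predict(rf, newx = x[i, , drop = FALSE],
                                           type = "response"))
    } else {
      risk[i] <- as.numeric(stats::predict(fit,
                                           newdata = data.frame(x[i, , drop = FALSE]),
                                           type = "response"))
    }
  }
  names(risk) <- ids
  pred <- as.integer(risk > 0.5)
  structure(list(risk = risk, predicted = pred,
                 accuracy = mean(pred == y), flagged_folds = flagged),
            class = "loocv_result")
}

#' Area under the ROC curve
#'
#' Concordant-pair (Mann-Whitney) formulation via midranks; tied scores
#' count one half.
#'
#' @param scores per-sample risk scores.
#' @param labels binary labels (1 = positive class).
#' @return AUROC in \[0,1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) pc_stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
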