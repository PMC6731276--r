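## Synthetic multi-omics cohort generator: two response groups, planted
## expression and/or methylation shifts on a configurable subset of
## pathways, beta-distributed methylation with 1-3 CpG sites per gene, and
## exponential survival whose log-hazard is proportional to the sample's
## planted-pathway mean expression.

#' Configure a synthetic cohort
#'
#' @param n_genes total genes (must cover `n_pathways * genes_per_pathway`;
#'   the remainder are pathway-free background genes).
#' @param n_pathways number of disjoint pathways.
#' @param genes_per_pathway genes per pathway.
#' @param n_poor,n_favorable samples per response group.
#' @param n_planted number of planted pathways (the first `n_planted`
#'   pathways), used when `planted` is NULL.
#' @param planted named character vector: pathway name -> level
#'   (`"expression"`, `"methylation"`, `"both"`); overrides `n_planted`.
#' @param planted_level level applied to the `n_planted` default pathways.
#' @param expr_effect planted expression shift in units of the noise sd.
#' @param meth_effect planted methylation beta shift (absolute).
#' @param noise_sd Gaussian expression noise sd.
#' @param beta_base shape parameters `c(a, b)` of the baseline Beta
#'   distribution of methylation values.
#' @param sites_per_gene range of CpG sites per gene, drawn uniformly.
#' @param baseline_hazard exponential baseline hazard (events/day).
#' @param hazard_ratio target hazard ratio between the planted-activity
#'   groups; the activity log-hazard coefficient is
#'   `log(hazard_ratio) / (expr_effect * noise_sd)`. Set to 1 for no
#'   survival coupling.
#' @param censoring fraction of samples censored (uniformly before their
#'   event time).
#' @param seed integer seed; generation is fully reproducible.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 3000, n_pathways = 100,
                             genes_per_pathway = 30,
                             n_poor = 4, n_favorable = 4,
                             n_planted = 5, planted = NULL,
                             planted_level = "both",
                             expr_effect = 2, meth_effect = 0.2,
                             noise_sd = 1, beta_base = c(2, 2),
                             sites_per_gene = c(1, 3),
                             baseline_hazard = 1 / 400,
                             hazard_ratio = 4, censoring = 0.3,
                             seed = 1) {
  stopifnot(is_count(n_genes), is_count(n_pathways),
            is_count(genes_per_pathway), is_count(n_poor),
            is_count(n_favorable))
  if (n_genes < n_pathways * genes_per_pathway)
    pc_stop("n_genes must cover n_pathways * genes_per_pathway")
  if (noise_sd <= 0) pc_stop("noise_sd must be positive")
  if (meth_effect < 0 || meth_effect > 1)
    pc_stop("meth_effect must lie in [0,1]")
  if (censoring < 0 || censoring >= 1) pc_stop("censoring must lie in [0,1)")
  if (any(beta_base <= 0)) pc_stop("beta_base shapes must be positive")
  pw_names <- sprintf("PW%03d", seq_len(n_pathways))
  if (is.null(planted)) {
    if (n_planted > n_pathways) pc_stop("n_planted exceeds n_pathways")
    planted <- stats::setNames(rep(planted_level, n_planted),
                               pw_names[seq_len(n_planted)])
  }
  if (length(planted) > 0) {
    if (!all(names(planted) %in% pw_names))
      pc_stop("planted pathway name(s) outside the collection")
    if (!all(planted %in% c("expression", "methylation", "both")))
      pc_stop("planted levels must be expression/methylation/both")
  }
  structure(list(n_genes = n_genes, n_pathways = n_pathways,
                 genes_per_pathway = genes_per_pathway,
                 n_poor = n_poor, n_favorable = n_favorable,
                 planted = planted, expr_effect = expr_effect,
                 meth_effect = meth_effect, noise_sd = noise_sd,
                 beta_base = beta_base, sites_per_gene = sites_per_gene,
                 baseline_hazard = baseline_hazard,
                 hazard_ratio = hazard_ratio, censoring = censoring,
                 seed = seed),
            class = "synthetic_config")
}

#' Planted truth of a configuration
#'
#' @param config a `synthetic_config`.
#' @return data.frame (pathway, level); empty when nothing is planted.
#' @export
planted_truth <- function(config) {
  data.frame(pathway = names(config$planted),
             level = unname(config$planted),
             stringsAsFactors = FALSE)
}

## mean-shifted Beta draw keeping the baseline precision (a+b)
rbeta_shifted <- function(n, a, b, shift) {
  nu <- a + b
  m <- min(max(a / nu + shift, 0.02), 0.98)
  stats::rbeta(n, m * nu, (1 - m) * nu)
}

#' Generate a synthetic multi-omics cohort
#'
#' Background genes are Normal(0, sd) in both groups; planted
#' expression-level genes are shifted by `expr_effect * noise_sd` in the
#' poor group. Methylation beta values follow the baseline Beta
#' distribution, with planted sites mean-shifted by `meth_effect` (at fixed
#' precision) in the poor group. Survival times are exponential with
#' log-hazard proportional to the sample's planted-pathway mean expression;
#' a configured fraction of samples is censored uniformly before the event.
#'
#' @param config a `synthetic_config`.
#' @return a `synthetic_cohort` list: `expression` and `methylation`
#'   [omics_matrix()] objects, `map` ([site_gene_map()]), `clinical`
#'   (`clinical_table`), `collection` (`pathway_collection`), `groups`
#'   (`response_groups`), `truth` (planted table plus per-sample activity).
#' @export
generate_cohort <- function(config) {
  cf <- config
  set.seed(cf$seed)
  genes <- sprintf("GENE%04d", seq_len(cf$n_genes))
  pw_names <- sprintf("PW%03d", seq_len(cf$n_pathways))
  sets <- split(genes[seq_len(cf$n_pathways * cf$genes_per_pathway)],
                rep(seq_len(cf$n_pathways), each = cf$genes_per_pathway))
  names(sets) <- pw_names
  collection <- pathway_collection(sets)
  samples <- c(sprintf("POOR%02d", seq_len(cf$n_poor)),
               sprintf("FAV%02d", seq_len(cf$n_favorable)))
  poor_ids <- samples[seq_len(cf$n_poor)]
  fav_ids <- setdiff(samples, poor_ids)
  n <- length(samples)

  planted <- cf$planted
  expr_planted <- names(planted)[planted %in% c("expression", "both")]
  meth_planted <- names(planted)[planted %in% c("methylation", "both")]
  expr_genes <- unlist(sets[expr_planted], use.names = FALSE)
  meth_genes <- unlist(sets[meth_planted], use.names = FALSE)

  expr <- matrix(stats::rnorm(cf$n_genes * n, 0, cf$noise_sd),
                 nrow = cf$n_genes,
                 dimnames = list(genes, samples))
  if (length(expr_genes) > 0)
    expr[expr_genes, poor_ids] <- expr[expr_genes, poor_ids] +
      cf$expr_effect * cf$noise_sd

  n_sites <- sample(seq(cf$sites_per_gene[1], cf$sites_per_gene[2]),
                    cf$n_genes, replace = TRUE)
  site_gene <- rep(genes, n_sites)
  site_ids <- sprintf("cg%07d", seq_along(site_gene))
  map <- site_gene_map(site_ids, site_gene)
  a <- cf$beta_base[1]; b <- cf$beta_base[2]
  meth <- matrix(stats::rbeta(length(site_ids) * n, a, b),
                 nrow = length(site_ids),
                 dimnames = list(site_ids, samples))
  if (length(meth_genes) > 0) {
    pl_sites <- site_ids[site_gene %in% meth_genes]
    meth[pl_sites, poor_ids] <-
      rbeta_shifted(length(pl_sites) * length(poor_ids), a, b, cf$meth_effect)
  }

  activity <- if (length(expr_genes) > 0)
    colMeans(expr[expr_genes, , drop = FALSE]) else stats::setNames(rep(0, n), samples)
  coef <- if (cf$hazard_ratio == 1 || length(expr_genes) == 0) 0
          else log(cf$hazard_ratio) / (cf$expr_effect * cf$noise_sd)
  lambda <- cf$baseline_hazard * exp(coef * (activity - mean(activity)))
  t_event <- stats::rexp(n, rate = lambda)
  if (cf$censoring > 0) {
    # independent exponential censoring, rate calibrated so the expected
    # censored fraction over the cohort equals the configured one
    crate <- stats::uniroot(function(cr) mean(cr / (lambda + cr)) - cf$censoring,
                            interval = c(1e-12, 1e6 * max(lambda)))$root
    t_cens <- stats::rexp(n, rate = crate)
  } else t_cens <- rep(Inf, n)
  censored <- t_cens < t_event
  time <- pmin(t_event, t_cens)
  clinical <- clinical_table(data.frame(
    sample_id = samples,
    therapy = "carboplatin-paclitaxel",
    time_to_event = round(time, 2),
    event = as.integer(!censored),
    age = round(stats::rnorm(n, 65, 8)),
    gender = sample(c("male", "female"), n, replace = TRUE),
    stage = sample(c("I", "II", "III"), n, replace = TRUE),
    neoadjuvant = 0L,
    stringsAsFactors = FALSE))

  structure(list(expression = omics_matrix(expr, "expression"),
                 methylation = omics_matrix(meth, "beta"),
                 map = map, clinical = clinical, collection = collection,
                 groups = response_groups(poor_ids, fav_ids),
                 truth = list(planted = planted_truth(cf),
                              activity = activity,
                              activity_coef = coef),
                 config = cf),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cf <- x$config
  cat(sprintf(paste0("synthetic_cohort: %d genes, %d pathways (%d planted), ",
                     "%d poor + %d favorable samples\n"),
              cf$n_genes, cf$n_pathways, length(cf$planted), cf$n_poor,
              cf$n_favorable))
  invisible(x)
}

#' Write a synthetic cohort to a directory in the standard formats
#'
#' Emits expression.tsv, methylation.tsv, site_gene_map.tsv, clinical.tsv,
#' pathways.gmt and planted_truth.tsv.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(cohort$expression, file.path(dir, "expression.tsv"), "gene")
  write_matrix(cohort$methylation, file.path(dir, "methylation.tsv"), "site")
  utils::write.table(as.data.frame(cohort$map),
                     file.path(dir, "site_gene_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  g <- cohort$groups
  utils::write.table(
    data.frame(sample_id = c(g$poor, g$favorable, g$excluded),
               group = c(rep("poor", length(g$poor)),
                         rep("favorable", length(g$favorable)),
                         rep("excluded", length(g$excluded)))),
    file.path(dir, "groups.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_gmt(cohort$collection, file.path(dir, "pathways.gmt"))
  utils::write.table(cohort$truth$planted,
                     file.path(dir, "planted_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
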