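## Containers and readers/writers for the tab-separated formats the pipeline
## touches: feature x sample omics matrices, CpG site-to-gene maps, clinical
## tables and GMT pathway collections, plus the beta <-> M value conversion.

VALID_SPACES <- c("expression", "beta", "mvalue")
VALID_REGIONS <- c("TSS200", "TSS1500", "5'UTR", "1stExon", "Body", "3'UTR")

#' Construct a feature-by-sample omics matrix
#'
#' Thin wrapper around a numeric matrix that records which value space the
#' entries live in: `expression` (normalized, log-scale expression), `beta`
#' (methylation fractions in \[0,1\]) or `mvalue` (logit2-transformed beta).
#'
#' @param values numeric matrix, features in rows, samples in columns; must
#'   carry unique row and column names.
#' @param space one of `"expression"`, `"beta"`, `"mvalue"`.
#' @return an `omics_matrix`: the matrix with a `space` attribute.
#' @export
omics_matrix <- function(values, space = c("expression", "beta", "mvalue")) {
  space <- match.arg(space)
  if (!is.matrix(values) || !is.numeric(values))
    pc_stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    pc_stop("omics matrix requires row (feature) and column (sample) names")
  if (anyDuplicated(rownames(values)))
    pc_stop("duplicate feature ids: ",
            paste(unique(rownames(values)[duplicated(rownames(values))]),
                  collapse = ", "))
  if (anyDuplicated(colnames(values)))
    pc_stop("duplicate sample ids: ",
            paste(unique(colnames(values)[duplicated(colnames(values))]),
                  collapse = ", "))
  if (space == "beta") {
    bad <- which(values < 0 | values > 1, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      cells <- apply(utils::head(bad, 5), 1, function(ij)
        paste0(rownames(values)[ij[1]], "/", colnames(values)[ij[2]]))
      pc_stop("beta values outside [0,1] in ", nrow(bad), " cell(s): ",
              paste(cells, collapse = ", "),
              if (nrow(bad) > 5) ", ..." else "")
    }
  }
  structure(values, space = space, class = c("omics_matrix", "matrix", "array"))
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s]: %d features x %d samples\n",
              attr(x, "space"), nrow(x), ncol(x)))
  invisible(x)
}

omics_space <- function(x) attr(x, "space") %||% "expression"
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a feature-by-sample matrix from tab-separated text
#'
#' Expects the first row to hold sample ids and the first column feature ids.
#' Gene-symbol feature ids are uppercased for `expression` space so joins
#' against GMT collections are deterministic.
#'
#' @param path file path.
#' @param space value space declared for the file; beta files are validated
#'   to \[0,1\].
#' @param uppercase_features uppercase feature ids (default: TRUE for
#'   expression space, FALSE otherwise — CpG ids are case-sensitive).
#' @return an [omics_matrix()].
#' @export
read_matrix <- function(path, space = c("expression", "beta", "mvalue"),
                        uppercase_features = NULL) {
  space <- match.arg(space)
  if (!file.exists(path)) pc_stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE)
  feats <- as.character(df[[1]])
  if (anyDuplicated(feats))
    pc_stop("duplicate feature ids in ", path, ": ",
            paste(unique(feats[duplicated(feats)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (is.null(uppercase_features)) uppercase_features <- space == "expression"
  rownames(m) <- if (uppercase_features) toupper(feats) else feats
  omics_matrix(m, space)
}

#' Write an omics matrix as tab-separated text
#'
#' Emits the same dialect [read_matrix()] reads, so matrices round-trip.
#'
#' @param x an [omics_matrix()] or plain named matrix.
#' @param path output path.
#' @param feature_col header for the feature-id column.
#' @export
write_matrix <- function(x, path, feature_col = "feature") {
  df <- data.frame(feature = rownames(x), as.data.frame(unclass(x)[, , drop = FALSE]),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- feature_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert methylation beta values to M-values
#'
#' M = log2(beta / (1 - beta)); beta is clipped to
#' \[epsilon, 1 - epsilon\] first so boundary values stay finite while the
#' ordering of values is preserved.
#'
#' @param beta numeric vector/matrix of methylation fractions in \[0,1\].
#' @param epsilon clip bound in (0, 0.5).
#' @return M-values with the shape of the input.
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 ||
      epsilon <= 0 || epsilon >= 0.5)
    pc_stop("'epsilon' must lie in (0, 0.5)")
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    pc_stop("beta values must lie in [0,1]")
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  log2(b / (1 - b))
}

#' Convert M-values back to beta values
#'
#' Inverse of [beta_to_m()]: beta = 2^M / (1 + 2^M).
#'
#' @param m numeric vector/matrix of M-values.
#' @return beta values in (0,1).
#' @export
m_to_beta <- function(m) {
  p <- 2^m
  p / (1 + p)
}

#' Construct a CpG site-to-gene map
#'
#' @param site_id CpG site identifiers.
#' @param gene gene symbols (uppercased); a site may map to several genes via
#'   repeated rows.
#' @param region optional CpG region labels (TSS200, TSS1500, 5'UTR, 1stExon,
#'   Body, 3'UTR).
#' @return a `site_gene_map` data.frame.
#' @export
site_gene_map <- function(site_id, gene, region = NULL) {
  site_id <- as.character(site_id)
  gene <- toupper(as.character(gene))
  if (length(site_id) != length(gene))
    pc_stop("'site_id' and 'gene' must have equal length")
  if (!is.null(region)) {
    region <- as.character(region)
    bad <- stats::na.omit(setdiff(unique(region), VALID_REGIONS))
    if (length(bad) > 0)
      pc_stop("invalid region label(s): ", paste(bad, collapse = ", "))
  } else region <- rep(NA_character_, length(site_id))
  df <- data.frame(site_id = site_id, gene = gene, region = region,
                   stringsAsFactors = FALSE)
  df <- unique(df)
  class(df) <- c("site_gene_map", "data.frame")
  df
}

#' Select one CpG site per gene by coefficient of variation
#'
#' For each gene, the mapped site whose beta values have the highest
#' coefficient of variation (sd/mean across all cohort samples) is retained;
#' ties break toward the lexicographically smallest site id. Genes whose
#' mapped sites are all absent from the matrix are dropped with a warning.
#'
#' @param meth an [omics_matrix()] in beta space, sites in rows.
#' @param map a [site_gene_map()].
#' @return an [omics_matrix()] in beta space keyed by gene symbol.
#' @export
select_site_per_gene <- function(meth, map) {
  if (omics_space(meth) != "beta")
    pc_stop("select_site_per_gene expects a beta-space matrix")
  all_genes <- unique(toupper(map$gene))
  map <- map[map$site_id %in% rownames(meth), , drop = FALSE]
  if (nrow(map) == 0) pc_stop("no mapped site present in the matrix")
  mu <- rowMeans(meth)
  sdv <- sqrt(row_vars(unclass(meth)))
  cv <- ifelse(mu == 0, 0, sdv / mu)
  names(cv) <- rownames(meth)
  picked <- vapply(split(map$site_id, toupper(map$gene)), function(sites) {
    sites <- sort(sites)               # lexicographic tie-break
    sites[which.max(cv[sites])]
  }, character(1))
  out <- unclass(meth)[picked, , drop = FALSE]
  rownames(out) <- names(picked)
  dropped <- setdiff(all_genes, names(picked))
  if (length(dropped) > 0)
    pc_warn(length(dropped), " gene(s) had no mapped site in the matrix")
  omics_matrix(out, "beta")
}

#' Read a GMT pathway collection
#'
#' One pathway per line: name, description, then member genes, tab-separated.
#' Genes are uppercased and deduplicated within each set.
#'
#' @param path GMT file path.
#' @return a `pathway_collection`: named list of unique gene-symbol vectors
#'   with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) pc_stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    pc_warn("empty GMT file: ", path)
    return(pathway_collection(list()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3))
    pc_stop("malformed GMT line(s) with fewer than 3 fields at line ",
            paste(which(nf < 3), collapse = ", "))
  nm <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nm))
    pc_stop("duplicate pathway name(s): ",
            paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(parts, function(p) unique(toupper(p[-(1:2)])))
  names(sets) <- nm
  pathway_collection(sets, vapply(parts, `[[`, character(1), 2))
}

#' Construct a pathway collection
#'
#' @param sets named list of gene-symbol character vectors.
#' @param descriptions optional character vector of descriptions.
#' @return a `pathway_collection`.
#' @export
pathway_collection <- function(sets, descriptions = NULL) {
  if (length(sets) > 0) {
    if (is.null(names(sets)) || anyDuplicated(names(sets)))
      pc_stop("pathway names must be present and unique")
    if (any(lengths(sets) == 0)) pc_stop("empty gene set(s) not allowed")
    sets <- lapply(sets, function(g) unique(toupper(g)))
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  structure(sets, descriptions = descriptions,
            class = c("pathway_collection", "list"))
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("pathway_collection: %d pathways, median size %s\n", length(x),
              if (length(x)) stats::median(lengths(x)) else NA))
  invisible(x)
}

#' Write a pathway collection as GMT
#'
#' @param collection a `pathway_collection`.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  desc <- attr(collection, "descriptions") %||% rep("", length(collection))
  lines <- vapply(seq_along(collection), function(i)
    paste(c(names(collection)[i], desc[i], collection[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

CLINICAL_COLS <- c("sample_id", "therapy", "time_to_event", "event",
                   "age", "gender", "stage", "neoadjuvant")

#' Read a clinical/treatment table
#'
#' Tab-separated with the header
#' `sample_id therapy time_to_event event age gender stage neoadjuvant`;
#' one row per sample, `time_to_event` in days >= 0, `event` in \{0,1\}.
#'
#' @param path file path.
#' @return a `clinical_table` data.frame.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) pc_stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  clinical_table(df)
}

#' Validate a clinical table
#'
#' @param df data.frame with the columns listed under [read_clinical()].
#' @return a validated `clinical_table`.
#' @export
clinical_table <- function(df) {
  miss <- setdiff(CLINICAL_COLS, names(df))
  if (length(miss) > 0)
    pc_stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    pc_stop("duplicate sample_id in clinical table")
  if (any(df$time_to_event < 0)) pc_stop("time_to_event must be >= 0")
  if (!all(df$event %in% c(0, 1))) pc_stop("event must be 0 or 1")
  if (!all(df$neoadjuvant %in% c(0, 1))) pc_stop("neoadjuvant must be 0 or 1")
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Write a clinical table as tab-separated text
#'
#' @param clinical a `clinical_table`.
#' @param path output path.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
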