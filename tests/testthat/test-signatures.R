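make_groups_matrix <- function(n_genes = 50, n_poor = 3, n_fav = 3, seed = 1,
                               shift_genes = integer(0), shift = 0) {
  set.seed(seed)
  samples <- c(paste0("P", seq_len(n_poor)), paste0("F", seq_len(n_fav)))
  x <- matrix(rnorm(n_genes * length(samples)), n_genes,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)), samples))
  x[shift_genes, seq_len(n_poor)] <- x[shift_genes, seq_len(n_poor)] + shift
  list(mat = omics_matrix(x, "expression"),
       groups = response_groups(samples[seq_len(n_poor)],
                                samples[-seq_len(n_poor)]))
}

test_that("response groups follow the relapse-window rules", {
  cl <- make_clinical(paste0("S", 1:6),
                      time = c(200, 800, 400, 365, 731, 500),
                      event = c(1, 0, 0, 1, 0, 1))
  g <- define_response_groups(cl, "carboplatin-paclitaxel")
  expect_setequal(g$poor, c("S1", "S4"))        # events within 1 year
  expect_setequal(g$favorable, c("S2", "S5"))   # event-free > 2 years
  expect_setequal(g$excluded, c("S3", "S6"))    # short censor / late event

  # neoadjuvant patients are excluded up front
  cl2 <- cl; cl2$neoadjuvant[1] <- 1L
  g2 <- define_response_groups(cl2)
  expect_false("S1" %in% g2$poor)

  cl3 <- make_clinical(c("A", "B"), c(400, 500), c(0, 1))
  expect_error(define_response_groups(cl3), "threshold")
})

test_that("balance check flags imbalanced covariates only", {
  cl <- make_clinical(paste0("S", 1:8), time = rep(100, 8), event = rep(1, 8))
  cl$gender <- rep(c("male", "female"), each = 4)
  cl$age <- c(60, 62, 64, 66, 61, 63, 65, 67)
  g <- response_groups(paste0("S", 1:4), paste0("S", 5:8))
  rep <- balance_check(g, cl, c("age", "gender", "stage"))
  # all-male vs all-female: Fisher exact on 2x2 with empty off-diagonals
  expect_true(rep$flagged[rep$covariate == "gender"])
  expect_equal(rep$p[rep$covariate == "gender"],
               fisher.test(matrix(c(4, 0, 0, 4), 2))$p.value)
  expect_false(rep$flagged[rep$covariate == "age"])
  # constant covariate reported degenerate with p = 1
  expect_equal(rep$p[rep$covariate == "stage"], 1)
  expect_match(rep$note[rep$covariate == "stage"], "constant")
  expect_error(balance_check(g, cl, "smoking"), "missing")
})

test_that("Welch signature matches the closed form and t.test", {
  x <- rbind(G1 = c(2, 4, 6, 1, 2, 3), G2 = c(1, 1, 1, 5, 5, 5.5))
  colnames(x) <- c("P1", "P2", "P3", "F1", "F2", "F3")
  g <- response_groups(c("P1", "P2", "P3"), c("F1", "F2", "F3"))
  sig <- welch_signature(omics_matrix(x, "expression"), g)
  t1 <- sig$score[sig$feature == "G1"]
  expect_equal(t1, 2 / sqrt(4 / 3 + 1 / 3), tolerance = 1e-12)
  # dual route: stats::t.test per gene
  expect_equal(t1, unname(t.test(c(2, 4, 6), c(1, 2, 3))$statistic),
               tolerance = 1e-12)
  expect_equal(sig$score[sig$feature == "G2"],
               unname(t.test(c(1, 1, 1), c(5, 5, 5.5))$statistic),
               tolerance = 1e-12)
  # sorted descending
  expect_true(all(diff(sig$score) <= 0))
})

test_that("Welch signature is antisymmetric under group swap and drops
           zero-variance features", {
  d <- make_groups_matrix(seed = 42)
  sig <- welch_signature(d$mat, d$groups)
  swapped <- response_groups(d$groups$favorable, d$groups$poor)
  sig2 <- welch_signature(d$mat, swapped)
  expect_equal(sig$score[order(sig$feature)],
               -sig2$score[order(sig2$feature)])

  x <- unclass(d$mat)
  x[1, ] <- 7  # constant everywhere
  expect_warning(s3 <- welch_signature(omics_matrix(x, "expression"), d$groups),
                 "zero variance")
  expect_false("G001" %in% s3$feature)
  expect_error(welch_signature(d$mat, response_groups("P1", c("F1", "F2"))),
               ">= 2 samples")
})

test_that("null Welch t statistics hit the nominal two-sided 5% rate", {
  set.seed(2024)
  n_feat <- 3000
  x <- matrix(rnorm(n_feat * 8), n_feat,
              dimnames = list(sprintf("G%04d", 1:n_feat),
                              c(paste0("P", 1:4), paste0("F", 1:4))))
  g <- response_groups(paste0("P", 1:4), paste0("F", 1:4))
  w <- pathchemo:::welch_rows(x[, 1:4], x[, 5:8])
  crit <- qt(0.975, w$df)
  expect_lt(abs(mean(abs(w$t) > crit) - 0.05), 0.02)
})

test_that("fold-change signature is the group mean difference", {
  x <- rbind(G1 = c(5, 5, 3, 3), G2 = c(1, 3, 4, 6))
  colnames(x) <- c("P1", "P2", "F1", "F2")
  g <- response_groups(c("P1", "P2"), c("F1", "F2"))
  sig <- foldchange_signature(omics_matrix(x, "expression"), g)
  expect_equal(sig$score[sig$feature == "G1"], 2)
  expect_equal(sig$score[sig$feature == "G2"], -3)
  swapped <- foldchange_signature(omics_matrix(x, "expression"),
                                  response_groups(c("F1", "F2"), c("P1", "P2")))
  expect_equal(sort(swapped$score), sort(-sig$score))
})

test_that("methylation signature composes beta->M with Welch t", {
  set.seed(9)
  b <- matrix(rbeta(4 * 6, 2, 2), 4,
              dimnames = list(paste0("cg", 1:4),
                              c("P1", "P2", "P3", "F1", "F2", "F3")))
  g <- response_groups(c("P1", "P2", "P3"), c("F1", "F2", "F3"))
  map <- site_gene_map(paste0("cg", 1:4), c("GA", "GA", "GB", "GC"))
  meth <- omics_matrix(b, "beta")

  sig <- methylation_signature(meth, map, g, mode = "all_sites")
  expect_equal(attr(sig, "keyed_by"), "site")
  expect_equal(nrow(sig), 4)
  # beta -> M applied before Welch: match a hand-computed t for cg4
  mv <- beta_to_m(b["cg4", ])
  expect_equal(sig$score[sig$feature == "cg4"],
               unname(t.test(mv[1:3], mv[4:6])$statistic), tolerance = 1e-12)

  # single-site genes agree exactly between the two modes
  sig1 <- methylation_signature(meth, map, g, mode = "one_site_per_gene")
  expect_equal(sig1$score[sig1$feature == "GC"],
               sig$score[sig$feature == "cg4"])

  # collapse keeps the strongest site per gene
  genes <- collapse_to_genes(sig)
  ga_sites <- sig$score[sig$feature %in% c("cg1", "cg2")]
  expect_equal(genes$score[genes$feature == "GA"],
               ga_sites[which.max(abs(ga_sites))])

  expect_error(methylation_signature(meth, site_gene_map("cgX", "GX"), g),
               "no overlap")
})
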